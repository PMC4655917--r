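#' Tabulate posterior summaries across a cohort
#'
#' Builds the subject-session table of posterior means and standard
#' deviations for the six parameters of interest, carrying the full
#' posterior covariances as an attribute for the outlier screen.
#'
#' @param fits list of [dcm_fit()] objects (one per session).
#' @param meta list (same length) of lists with `subject`, `session`,
#'   `group`.
#' @return A `data.frame` of class `"parameter_table"` with columns
#'   `subject`, `session`, `group`, then `<param>_mean` and `<param>_sd`
#'   for each parameter of interest; attribute `covariances` holds each
#'   session's full posterior covariance.
#' @export
parameter_table <- function(fits, meta) {
  stopifnot(length(fits) == length(meta))
  nm <- param_names_interest()
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    out <- data.frame(subject = meta[[i]]$subject, session = meta[[i]]$session,
                      group = meta[[i]]$group)
    for (p in nm) {
      out[[paste0(p, "_mean")]] <- unname(f$theta[p])
      out[[paste0(p, "_sd")]] <- unname(f$sd[p])
    }
    out
  })
  tab <- do.call(rbind, rows)
  if (any(vapply(nm, function(p) any(tab[[paste0(p, "_sd")]] <= 0), TRUE)))
    stop("posterior SDs must be positive", call. = FALSE)
  attr(tab, "covariances") <- lapply(fits, `[[`, "Sigma")
  class(tab) <- c("parameter_table", "data.frame")
  tab
}

#' Posterior-covariance outlier screen
#'
#' For each parameter of interest, scores every session by the maximum
#' absolute posterior correlation between that parameter and all remaining
#' fitted parameters, summarises each subject by the worst of its sessions,
#' and marks the highest-scoring subjects as excluded until
#' `retain_fraction` of subjects remain. Adds one logical `keep_<param>`
#' column per parameter; patients are never screened out.
#'
#' @param table a [parameter_table()] (with its `covariances` attribute).
#' @param retain_fraction fraction of control subjects retained (default
#'   0.90).
#' @return The table with `keep_*` columns added.
#' @export
screen_outliers <- function(table, retain_fraction = 0.90) {
  covs <- attr(table, "covariances")
  if (is.null(covs)) stop("table lacks posterior covariances", call. = FALSE)
  stopifnot(retain_fraction > 0, retain_fraction <= 1)
  nm <- param_names_interest()
  for (p in nm) {
    score <- vapply(covs, function(S) {
      R <- stats::cov2cor(S)
      others <- setdiff(colnames(R), nm)
      max(abs(R[p, others]))
    }, 0)
    ctrl <- unique(table$subject[table$group == "control"])
    sub_score <- vapply(ctrl, function(s) max(score[table$subject == s]), 0)
    n_drop <- ceiling((1 - retain_fraction) * length(ctrl))
    drop <- if (n_drop > 0) ctrl[order(sub_score, decreasing = TRUE)[seq_len(n_drop)]]
            else integer()
    table[[paste0("keep_", p)]] <- !(table$subject %in% drop)
  }
  table
}

#' Between-session intraclass correlation
#'
#' One-way random-effects ICC(1,1) of the session-1 versus session-2
#' posterior means, per parameter of interest, with the one-way ANOVA F test
#' against ICC = 0. Honors `keep_<param>` columns if present (see
#' [screen_outliers()]); only control subjects enter.
#'
#' @param table a [parameter_table()].
#' @return A `data.frame` with one row per parameter: `icc`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
icc_between_sessions <- function(table) {
  nm <- param_names_interest()
  out <- lapply(nm, function(p) {
    tb <- table[table$group == "control", ]
    kc <- paste0("keep_", p)
    if (kc %in% names(tb)) tb <- tb[tb[[kc]], ]
    wide <- split(tb[[paste0(p, "_mean")]], tb$subject)
    wide <- wide[lengths(wide) >= 2]
    y <- t(vapply(wide, function(v) v[1:2], numeric(2)))
    n <- nrow(y); k <- 2
    grand <- mean(y)
    msb <- k * sum((rowMeans(y) - grand)^2) / (n - 1)
    msw <- sum((y - rowMeans(y))^2) / (n * (k - 1))
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    Fv <- msb / msw
    data.frame(parameter = p, icc = icc, F = Fv, df1 = n - 1, df2 = n * (k - 1),
               p = stats::pf(Fv, n - 1, n * (k - 1), lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Canonical variates analysis with Wilks' lambda
#'
#' Canonical correlations between a multivariate response `Y` and a design
#' matrix `X` (typically a patient indicator plus a mean column), with the
#' likelihood-ratio test of independence: Wilks
#' \eqn{\Lambda = \prod_i (1 - r_i^2)} and Bartlett's chi-square
#' approximation \eqn{-(n - 1 - (p + q + 1)/2)\log\Lambda} on `p * q`
#' degrees of freedom. Constant columns of `X` (after centring) are dropped.
#'
#' @param Y n-by-p response matrix (e.g. session-averaged posterior means of
#'   the six parameters).
#' @param X n-by-q design matrix.
#' @return A list: `cor` (canonical correlations), `wilks`, `chisq`, `df`,
#'   `p`.
#' @export
cva_wilks <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  keep <- apply(Xc, 2, function(v) stats::sd(v) > 0)
  if (!any(keep)) stop("design matrix has no non-constant columns", call. = FALSE)
  cc <- stats::cancor(Xc[, keep, drop = FALSE], scale(Y, center = TRUE, scale = FALSE),
                      xcenter = FALSE, ycenter = FALSE)
  r <- cc$cor
  n <- nrow(Y); p <- ncol(Y); q <- sum(keep)
  lambda <- prod(1 - r^2)
  chisq <- -(n - 1 - (p + q + 1) / 2) * log(lambda)
  df <- p * q
  list(cor = r, wilks = lambda, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' One-dimensional Gaussian density
#'
#' @param mean,variance moments of the density (variance > 0).
#' @return A list of class `"gaussian_density"`.
#' @export
gaussian_density <- function(mean, variance) {
  if (!is.finite(variance) || variance <= 0)
    stop("variance must be positive", call. = FALSE)
  structure(list(mean = mean, variance = variance), class = "gaussian_density")
}

#' Non-overlapping probability density
#'
#' One minus the overlapping coefficient of two Gaussian densities,
#' \eqn{1 - \int \min(p(x), q(x)) dx}, computed by adaptive quadrature.
#' Symmetric in its arguments, 0 for identical densities and approaching 1
#' as the means separate.
#'
#' @param p,q [gaussian_density()] objects.
#' @return A value in [0, 1].
#' @examples
#' difference_probability(gaussian_density(0, 1), gaussian_density(2, 1))
#' @export
difference_probability <- function(p, q) {
  s1 <- sqrt(p$variance); s2 <- sqrt(q$variance)
  lo <- min(p$mean - 12 * s1, q$mean - 12 * s2)
  hi <- max(p$mean + 12 * s1, q$mean + 12 * s2)
  ovl <- stats::integrate(function(x)
    pmin(stats::dnorm(x, p$mean, s1), stats::dnorm(x, q$mean, s2)),
    lo, hi, rel.tol = 1e-9, subdivisions = 500L)$value
  min(max(1 - ovl, 0), 1)
}

#' Leave-one-out specificity of the control cohort
#'
#' For each control subject and parameter: build the held-out subject's
#' density (its session-averaged mean, with the remaining controls' average
#' within-subject variance) and the remaining cohort's average density
#' (mean and between-subject variance of their session-averaged means),
#' flag the subject as abnormal when the non-overlapping probability
#' exceeds the threshold, and report the true-negative rate.
#'
#' @param table a [parameter_table()].
#' @param threshold probable-difference level (default 0.90).
#' @return A list: `tnr` (named per-parameter true-negative rate), `flags`
#'   (subjects by parameters logical matrix).
#' @export
loo_specificity <- function(table, threshold = 0.90) {
  nm <- param_names_interest()
  ctrl <- table[table$group == "control", ]
  subs <- unique(ctrl$subject)
  if (length(subs) < 3) stop("need at least 3 control subjects", call. = FALSE)
  flags <- matrix(FALSE, length(subs), length(nm),
                  dimnames = list(subs, nm))
  for (p in nm) {
    mc <- paste0(p, "_mean")
    sub_mean <- vapply(subs, function(s) mean(ctrl[[mc]][ctrl$subject == s]), 0)
    sub_wvar <- vapply(subs, function(s) {
      v <- ctrl[[mc]][ctrl$subject == s]
      if (length(v) < 2) NA_real_ else stats::var(v)
    }, 0)
    for (i in seq_along(subs)) {
      rest_mean <- sub_mean[-i]
      held <- gaussian_density(sub_mean[i], mean(sub_wvar[-i], na.rm = TRUE))
      cohort <- gaussian_density(mean(rest_mean), stats::var(rest_mean))
      flags[i, p] <- difference_probability(held, cohort) > threshold
    }
  }
  list(tnr = 1 - colMeans(flags), flags = flags)
}

#' Patient-versus-cohort density comparison
#'
#' Convenience wrapper constructing, for one parameter, the control-average
#' density (mean and between-subject variance of the controls'
#' session-averaged posterior means) and the patient density (patient
#' session-averaged mean; controls' average within-subject variance), and
#' returning both with their non-overlap probability.
#'
#' @param table a [parameter_table()].
#' @param parameter one of the six parameters of interest.
#' @param patient_subject subject ID of the patient row(s).
#' @return A list: `control`, `patient` ([gaussian_density()] objects),
#'   `difference` (non-overlap probability).
#' @export
patient_densities <- function(table, parameter, patient_subject) {
  stopifnot(parameter %in% param_names_interest())
  mc <- paste0(parameter, "_mean")
  ctrl <- table[table$group == "control", ]
  subs <- unique(ctrl$subject)
  sub_mean <- vapply(subs, function(s) mean(ctrl[[mc]][ctrl$subject == s]), 0)
  sub_wvar <- vapply(subs, function(s) {
    v <- ctrl[[mc]][ctrl$subject == s]
    if (length(v) < 2) NA_real_ else stats::var(v)
  }, 0)
  pat <- table[table$subject == patient_subject, ]
  if (!nrow(pat)) stop("unknown patient subject", call. = FALSE)
  control <- gaussian_density(mean(sub_mean), stats::var(sub_mean))
  patient <- gaussian_density(mean(pat[[mc]]), mean(sub_wvar, na.rm = TRUE))
  list(control = control, patient = patient,
       difference = difference_probability(control, patient))
}

#' ROC curve and AUC from two Gaussian densities
#'
#' Sweeps a decision threshold from one tenth to twice the midpoint of the
#' two means, computing sensitivity and specificity from the Gaussian tail
#' probabilities on the loss-of-function side, and summarises the curve by
#' the trapezoidal area under it with endpoints clamped to (0,0) and (1,1).
#'
#' @param control,patient [gaussian_density()] objects.
#' @param n_thresholds number of thresholds swept (default 50).
#' @return A list: `curve` (data.frame with `threshold`, `sensitivity`,
#'   `specificity`), `auc`.
#' @export
roc_auc <- function(control, patient, n_thresholds = 50) {
  m <- (control$mean + patient$mean) / 2
  thr <- seq(0.1 * m, 2 * m, length.out = n_thresholds)
  lower <- patient$mean <= control$mean
  sens <- if (lower) stats::pnorm(thr, patient$mean, sqrt(patient$variance))
          else stats::pnorm(thr, patient$mean, sqrt(patient$variance), lower.tail = FALSE)
  spec <- if (lower) stats::pnorm(thr, control$mean, sqrt(control$variance), lower.tail = FALSE)
          else stats::pnorm(thr, control$mean, sqrt(control$variance))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  x <- c(0, fpr[ord], 1)
  y <- c(0, sens[ord], 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(curve = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec), auc = auc)
}

#' Posterior confidence ellipsoids
#'
#' Axis-aligned ellipsoid per session over three named parameters: centre at
#' the posterior means, semi-axes of one posterior standard deviation.
#'
#' @param table a [parameter_table()].
#' @param parameters character vector of three parameter names.
#' @return A `data.frame` with one row per session: subject, session, group,
#'   `center_*` and `semi_*` columns.
#' @export
ellipsoid_region <- function(table, parameters) {
  if (length(parameters) != 3 || !all(parameters %in% param_names_interest()))
    stop("parameters must name three of the six parameters of interest",
         call. = FALSE)
  out <- table[, c("subject", "session", "group")]
  for (p in parameters) {
    out[[paste0("center_", p)]] <- table[[paste0(p, "_mean")]]
    out[[paste0("semi_", p)]] <- table[[paste0(p, "_sd")]]
  }
  out
}
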