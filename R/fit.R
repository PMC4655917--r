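#' Bundle reduced-mode evoked data for model inversion
#'
#' Takes per-condition event-related fields, removes the first discrete
#' cosine component (the temporal mean) per sensor, projects onto the
#' leading left-singular modes of the condition-concatenated data, slices
#' the fit window and mean-corrects each mode within the window. The stored
#' projection is applied identically to model predictions during fitting.
#'
#' @param erf_standard,erf_deviant sensors-by-time matrices on a common grid.
#' @param time sample times in peristimulus ms.
#' @param net network template used for predictions; a
#'   [assemble_network()] object.
#' @param gain sensor gain matrix matching the rows of the ERFs.
#' @param n_modes number of SVD modes retained (default 8).
#' @param fit_window half-open peristimulus interval fitted, ms.
#' @param preproc_map optional [preproc_response_map()]: when the ERFs come
#'   from the filtering/epoching pipeline, predictions are pushed through
#'   the same linear observation map so that model and data see identical
#'   preprocessing.
#' @return An object of class `"dcm_data"`.
#' @export
dcm_data <- function(erf_standard, erf_deviant, time, net = assemble_network(),
                     gain, n_modes = 8, fit_window = c(1, 250),
                     preproc_map = NULL) {
  stopifnot(nrow(erf_standard) == nrow(erf_deviant),
            ncol(erf_standard) == length(time))
  if (nrow(erf_standard) != nrow(gain))
    stop("gain matrix rows must match ERF sensors", call. = FALSE)
  es <- dct_detrend(erf_standard)
  ed <- dct_detrend(erf_deviant)
  red <- svd_reduce(cbind(es, ed), n_modes = n_modes)
  keep <- time >= fit_window[1] & time < fit_window[2]
  if (!any(keep)) stop("fit window contains no samples", call. = FALSE)
  P <- red$projection
  Y <- array(NA_real_, c(n_modes, sum(keep), 2),
             dimnames = list(NULL, NULL, c("standard", "deviant")))
  Y[, , 1] <- .mean_correct(P %*% erf_standard[, keep, drop = FALSE])
  Y[, , 2] <- .mean_correct(P %*% erf_deviant[, keep, drop = FALSE])
  if (!is.null(preproc_map) &&
      !isTRUE(all.equal(preproc_map$time, time)))
    stop("preproc_map epoch grid does not match the ERF time grid", call. = FALSE)
  structure(list(Y = Y, projection = P, fit_times = time[keep], keep = keep,
                 var_retained = red$var_retained, net = net, gain = gain,
                 n_modes = n_modes, fit_window = fit_window,
                 preproc_map = preproc_map),
            class = "dcm_data")
}

.mean_correct <- function(m) m - rowMeans(m)

#' Model prediction in reduced-mode space
#'
#' Simulates both conditions at the log-scale parameters `theta`, samples
#' the sensor output on the data's fit grid, applies the stored projection
#' and mean-corrects each mode, mirroring the preparation of the data.
#'
#' @param theta named log-scale parameter vector (see [dcm_priors()]).
#' @param data a [dcm_data()] object.
#' @param dt integration step, ms (must divide the fit-grid spacing).
#' @return modes by time by condition array matching `data$Y`.
#' @export
predict_response <- function(theta, data, dt = 0.5) {
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  net <- apply_theta(data$net, theta)
  out <- array(NA_real_, dim(data$Y), dimnames = dimnames(data$Y))
  map <- data$preproc_map
  if (is.null(map)) {
    tmax <- max(data$fit_times)
    idx <- round(data$fit_times / dt) + 1L
    if (max(abs(data$fit_times - (idx - 1L) * dt)) > 1e-9)
      stop("dt does not divide the fit grid", call. = FALSE)
    for (cond in c("standard", "deviant")) {
      sim <- simulate_erp(net, data$gain, cond, dt = dt, duration = tmax + 2 * dt)
      out[, , cond] <- .mean_correct(data$projection %*% sim$sensors[, idx, drop = FALSE])
    }
  } else {
    idx <- round(map$template_time / dt) + 1L
    dur <- max(map$template_time) + 2 * dt
    V <- lapply(c(standard = "standard", deviant = "deviant"), function(cond) {
      sim <- simulate_erp(net, data$gain, cond, dt = dt, duration = dur)
      data$projection %*% sim$sensors[, idx, drop = FALSE]
    })
    # centre trial's own template plus filter tails of (standard) neighbours
    ep_std <- tcrossprod(V$standard, map$Mc) + tcrossprod(V$standard, map$Mn)
    ep_dev <- tcrossprod(V$deviant, map$Mc) + tcrossprod(V$standard, map$Mn)
    out[, , "standard"] <- .mean_correct(ep_std[, data$keep, drop = FALSE])
    out[, , "deviant"] <- .mean_correct(ep_dev[, data$keep, drop = FALSE])
  }
  out
}

#' Laplace free energy of a parameter/hyperparameter point
#'
#' Evaluates the variational-Laplace objective: Gaussian log-likelihood of
#' the reduced-mode residuals under precision `exp(h)`, plus the log prior
#' density of `theta` and the log hyperprior density of `h`. When a
#' posterior covariance `Sigma` is supplied its Gaussian entropy is added,
#' giving the full Laplace free-energy bound; without it the joint log
#' density is returned (a delta-function posterior).
#'
#' @param theta named log-scale parameter vector.
#' @param h log-precision of the residuals.
#' @param data a [dcm_data()] object.
#' @param priors a [dcm_priors()] object.
#' @param Sigma optional posterior covariance over `theta`.
#' @param pred optional precomputed prediction (as from
#'   [predict_response()]), to avoid re-simulation.
#' @param dt integration step passed to [predict_response()].
#' @return Free energy in nats.
#' @export
free_energy <- function(theta, h, data, priors, Sigma = NULL, pred = NULL,
                        dt = 0.5) {
  if (is.null(pred)) pred <- predict_response(theta, data, dt = dt)
  r <- as.numeric(data$Y) - as.numeric(pred)
  n <- length(r)
  d <- theta[names(priors$mean)] - priors$mean
  F <- -0.5 * exp(h) * sum(r^2) + 0.5 * n * h - 0.5 * n * log(2 * pi) -
    0.5 * sum(d^2 / priors$var) - 0.5 * sum(log(2 * pi * priors$var)) -
    0.5 * (h - priors$hyper$mean)^2 / priors$hyper$var -
    0.5 * log(2 * pi * priors$hyper$var)
  if (!is.null(Sigma)) {
    ld <- determinant(Sigma, logarithm = TRUE)$modulus
    F <- F + 0.5 * as.numeric(ld) + 0.5 * nrow(Sigma) * log(2 * pi * exp(1))
  }
  unname(F)
}

#' Inversion settings
#'
#' @param dt integration step for predictions, ms.
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol convergence tolerance on the free-energy increase, nats.
#' @param fd_step central finite-difference step in log-parameter space.
#' @param max_retries damping escalations allowed per iteration.
#' @param lambda0 initial Levenberg damping factor.
#' @return A list of settings.
#' @export
dcm_settings <- function(dt = 0.5, max_iter = 64, tol = 1e-2, fd_step = 1e-3,
                         max_retries = 4, lambda0 = 0.25) {
  list(dt = dt, max_iter = max_iter, tol = tol, fd_step = fd_step,
       max_retries = max_retries, lambda0 = lambda0)
}

# maximize F over h at fixed residual sum of squares (Newton; concave in h)
.update_h <- function(h, rss, n, hyper) {
  for (i in 1:50) {
    g <- -0.5 * exp(h) * rss + 0.5 * n - (h - hyper$mean) / hyper$var
    H <- -0.5 * exp(h) * rss - 1 / hyper$var
    step <- g / H
    h <- h - step
    if (abs(step) < 1e-10) break
  }
  h
}

# central finite-difference Jacobian of the stacked prediction vector
.fd_jacobian <- function(theta, data, dt, step) {
  p <- length(theta)
  cols <- vector("list", p)
  for (k in seq_len(p)) {
    tp <- theta; tp[k] <- tp[k] + step
    tm <- theta; tm[k] <- tm[k] - step
    cols[[k]] <- (as.numeric(predict_response(tp, data, dt = dt)) -
                  as.numeric(predict_response(tm, data, dt = dt))) / (2 * step)
  }
  J <- do.call(cbind, cols)
  colnames(J) <- names(theta)
  J
}

#' Fit the conductance-based DCM by variational Laplace
#'
#' Gauss-Newton / expectation-maximisation ascent on the Laplace free
#' energy with Levenberg trust-region damping: at each iteration the
#' prediction Jacobian is computed by central finite differences, the
#' residual log-precision is optimised under its Gaussian hyperprior, and a
#' damped Gauss-Newton step is accepted only if it increases the free
#' energy (with up to `max_retries` damping escalations otherwise).
#' Convergence is declared when the free-energy gain falls below `tol`.
#'
#' @param data a [dcm_data()] object.
#' @param priors a [dcm_priors()] object (defaults to priors for
#'   `data$net`).
#' @param init optional named initial parameter vector (defaults to the
#'   prior mean; used by the two-stage cohort scheme).
#' @param settings a [dcm_settings()] list.
#' @return An object of class `"dcm"`: posterior mean (`theta`), posterior
#'   covariance (`Sigma`), log-precision `h`, free energy and its trace,
#'   percent variance explained (`pve`), convergence info.
#' @seealso [cohort_two_stage_fit()], [free_energy()], [predict_response()]
#' @export
dcm_fit <- function(data, priors = NULL, init = NULL, settings = dcm_settings()) {
  stopifnot(inherits(data, "dcm_data"))
  if (is.null(priors)) priors <- dcm_priors(data$net)
  theta <- priors$mean
  if (!is.null(init)) {
    if (!all(names(init) %in% names(theta)))
      stop("init names unknown to the prior", call. = FALSE)
    theta[names(init)] <- init
  }
  Pi0 <- diag(1 / priors$var)
  y <- as.numeric(data$Y)
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  h <- priors$hyper$mean
  lambda <- settings$lambda0
  pred <- predict_response(theta, data, dt = settings$dt)
  r <- y - as.numeric(pred)
  h <- .update_h(h, sum(r^2), n, priors$hyper)
  trace <- data.frame(iteration = integer(), F = numeric(),
                      lambda = numeric(), accepted = logical())
  F_cur <- NA_real_
  converged <- FALSE
  J <- NULL
  # iterations ascend the joint log density of data, parameters and
  # hyperparameter (the free energy with the posterior entropy held fixed):
  # every accepted Gauss-Newton step and every conditional update of h
  # increases this one objective, so its trace is monotone by construction.
  # The Gaussian entropy is added once at convergence to report the full
  # Laplace free energy.
  F_cur <- free_energy(theta, h, data, priors, pred = pred, dt = settings$dt)
  for (it in seq_len(settings$max_iter)) {
    J <- .fd_jacobian(theta, data, settings$dt, settings$fd_step)
    tau <- exp(h)
    Hm <- tau * crossprod(J) + Pi0
    g <- tau * crossprod(J, r) - Pi0 %*% (theta - priors$mean)
    accepted <- FALSE
    for (try in seq_len(settings$max_retries + 1)) {
      step <- tryCatch(
        solve(Hm + lambda * diag(diag(Hm), nrow(Hm)), g),
        error = function(e) NULL)
      cand <- if (is.null(step)) NULL else theta + as.numeric(step)
      if (!is.null(cand)) names(cand) <- names(theta)
      F_new <- -Inf
      pred_new <- NULL
      if (!is.null(cand)) {
        pred_new <- tryCatch(predict_response(cand, data, dt = settings$dt),
                             error = function(e) NULL)
        if (!is.null(pred_new) && all(is.finite(pred_new))) {
          r_new <- y - as.numeric(pred_new)
          h_new <- .update_h(h, sum(r_new^2), n, priors$hyper)
          F_new <- free_energy(cand, h_new, data, priors,
                               pred = pred_new, dt = settings$dt)
        }
      }
      if (is.finite(F_new) && F_new > F_cur) {
        theta <- cand; pred <- pred_new; r <- y - as.numeric(pred)
        h <- h_new
        dF <- F_new - F_cur
        F_cur <- F_new
        lambda <- max(lambda / 2, 1e-8)
        accepted <- TRUE
        trace <- rbind(trace, data.frame(iteration = it, F = F_cur,
                                         lambda = lambda, accepted = TRUE))
        break
      }
      lambda <- lambda * 8
    }
    if (!accepted) {
      trace <- rbind(trace, data.frame(iteration = it, F = F_cur,
                                       lambda = lambda, accepted = FALSE))
      if (all(is.finite(pred))) { converged <- TRUE; break }
      stop("dcm_fit: persistent step failure; iteration trace attached in ",
           "the error condition", call. = FALSE)
    }
    if (accepted && it > 1 && dF < settings$tol) { converged <- TRUE; break }
  }
  tau <- exp(h)
  Sigma <- solve(tau * crossprod(J) + Pi0)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(names(theta), names(theta))
  rss <- sum(r^2)
  F_full <- free_energy(theta, h, data, priors, Sigma = Sigma, pred = pred,
                        dt = settings$dt)
  structure(
    list(theta = theta, Sigma = Sigma, sd = sqrt(diag(Sigma)), h = h,
         free_energy = F_full, trace = trace, pve = 100 * (1 - rss / tss),
         rss = rss, n = n, converged = converged,
         iterations = if (nrow(trace)) max(trace$iteration) else 0L,
         priors = priors, settings = settings, data = data),
    class = "dcm")
}

#' Two-stage cohort inversion
#'
#' Stage 1 fits every session starting from the prior mean. Stage 2 refits
#' every session initialised at the elementwise average of the stage-1
#' posterior means, so that all subjects (patients included) begin the
#' final optimisation in the same region of parameter space.
#'
#' @param sessions list of [dcm_data()] objects (at least two).
#' @param priors shared [dcm_priors()]; defaults to priors of the first
#'   session's network.
#' @param settings a [dcm_settings()] list.
#' @param average_over optional integer/logical index of sessions whose
#'   stage-1 posteriors form the initialisation average (e.g. controls
#'   only); defaults to all sessions.
#' @return A list of class `"dcm_cohort"`: `fits` (stage-2 [dcm_fit()]
#'   objects), `stage1`, and `init` (the shared initialisation).
#' @export
cohort_two_stage_fit <- function(sessions, priors = NULL,
                                 settings = dcm_settings(),
                                 average_over = NULL) {
  if (length(sessions) < 2)
    stop("cohort fitting needs at least 2 sessions", call. = FALSE)
  if (is.null(priors)) priors <- dcm_priors(sessions[[1]]$net)
  stage1 <- lapply(sessions, dcm_fit, priors = priors, settings = settings)
  if (is.null(average_over)) average_over <- seq_along(sessions)
  init <- rowMeans(vapply(stage1[average_over], `[[`, priors$mean, "theta"))
  fits <- lapply(sessions, dcm_fit, priors = priors, init = init,
                 settings = settings)
  structure(list(fits = fits, stage1 = stage1, init = init), class = "dcm_cohort")
}
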