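#' @export
print.dcm <- function(x, ...) {
  cat("Conductance-based DCM (variational Laplace)\n")
  cat(sprintf("  %d parameters, %d data points; %d iterations (%s)\n",
              length(x$theta), x$n, x$iterations,
              if (x$converged) "converged" else "iteration limit"))
  cat(sprintf("  free energy %.2f, variance explained %.1f%%\n",
              x$free_energy, x$pve))
  cat("  parameters of interest (posterior mean +/- sd):\n")
  nm <- param_names_interest()
  for (p in nm)
    cat(sprintf("    %-12s %+.3f +/- %.3f\n", p, x$theta[p], x$sd[p]))
  invisible(x)
}

#' @export
coef.dcm <- function(object, ...) object$theta

#' @export
vcov.dcm <- function(object, ...) object$Sigma

#' @export
fitted.dcm <- function(object, ...) {
  predict_response(object$theta, object$data, dt = object$settings$dt)
}

#' @export
residuals.dcm <- function(object, ...) {
  object$data$Y - fitted(object)
}

#' Predict reduced-mode responses from a fitted DCM
#'
#' @param object a [dcm_fit()] object.
#' @param theta optional alternative parameter vector (defaults to the
#'   posterior mean).
#' @param ... unused.
#' @return modes by time by condition array.
#' @export
predict.dcm <- function(object, theta = NULL, ...) {
  predict_response(theta %||% object$theta, object$data,
                   dt = object$settings$dt)
}

#' Simulate responses from the posterior of a fitted DCM
#'
#' Draws parameter vectors from the Gaussian posterior and returns the
#' corresponding reduced-mode predictions.
#'
#' @param object a [dcm_fit()] object.
#' @param nsim number of posterior draws.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` prediction arrays; the draws are attached as
#'   attribute `"theta"`.
#' @export
simulate.dcm <- function(object, nsim = 1, seed = 1, ...) {
  p <- length(object$theta)
  R <- chol(object$Sigma)
  draws <- with_seed(seed,
    matrix(stats::rnorm(nsim * p), nsim, p) %*% R +
      matrix(object$theta, nsim, p, byrow = TRUE))
  colnames(draws) <- names(object$theta)
  sims <- lapply(seq_len(nsim), function(i) {
    th <- draws[i, ]
    predict_response(th, object$data, dt = object$settings$dt)
  })
  attr(sims, "theta") <- draws
  sims
}

#' @export
summary.dcm <- function(object, ...) {
  z <- object$theta / object$sd
  tab <- data.frame(estimate = object$theta, sd = object$sd,
                    ci_lo = object$theta - 1.96 * object$sd,
                    ci_hi = object$theta + 1.96 * object$sd)
  structure(list(coefficients = tab, free_energy = object$free_energy,
                 pve = object$pve, h = object$h, converged = object$converged,
                 iterations = object$iterations),
            class = "summary.dcm")
}

#' @export
print.summary.dcm <- function(x, ...) {
  cat("Conductance-based DCM posterior (log-scale parameters)\n")
  printCoefmat(as.matrix(x$coefficients), digits = 3)
  cat(sprintf("free energy %.2f | variance explained %.1f%% | log-precision %.2f\n",
              x$free_energy, x$pve, x$h))
  invisible(x)
}

#' Plot observed and fitted reduced-mode responses
#'
#' @param x a [dcm_fit()] object.
#' @param condition `"standard"` or `"deviant"`.
#' @param modes which modes to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dcm <- function(x, condition = "standard", modes = 1:4, ...) {
  Y <- x$data$Y[, , condition, drop = FALSE]
  P <- fitted(x)[, , condition, drop = FALSE]
  tt <- x$data$fit_times
  graphics::matplot(tt, t(Y[modes, , 1]), type = "p", pch = 1, cex = 0.5,
                    xlab = "peristimulus time (ms)", ylab = "mode amplitude",
                    ...)
  graphics::matlines(tt, t(P[modes, , 1]), lty = 1)
  invisible(x)
}

#' @export
print.virtual_study <- function(x, ...) {
  n_ctrl <- length(unique(x$table$subject[x$table$group == "control"]))
  n_pat <- length(unique(x$table$subject[x$table$group == "patient"]))
  cat(sprintf("<virtual_study> %d controls + %d patients, %d fitted sessions\n",
              n_ctrl, n_pat, nrow(x$table)))
  invisible(x)
}
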