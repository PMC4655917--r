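#' Log-scale parameterisation and priors
#'
#' Every fitted quantity is a log-scale multiplier on its prior (network
#' template) value: a parameter value of 0 leaves the template unchanged and
#' a value of -1 scales the corresponding quantity by `exp(-1)`. The fitted
#' set comprises the six parameters of interest (`alpha_NA`, `alpha_Cl`,
#' `alpha_CA_NA`, `alpha_KL`, `alpha_KIR`, `omega`), one gain per extrinsic
#' forward (`fwd1..`) and backward (`bwd1..`) edge, one modulatory gain per
#' edge (`modf1..`, `modb1..`, additive in log space on the deviant
#' condition), the input timing (`onset`, `duration`) and a global
#' observation gain (`obs`).
#'
#' Prior means are zero. Prior variances default to 1/16 for channel gains,
#' firing precision, extrinsic/modulatory gains and the observation gain, and
#' 1/32 for the input timing. The noise hyperprior is a Gaussian over the
#' log-precision of the sensor/mode residuals.
#'
#' @param net a [assemble_network()] template.
#' @param variances optional named overrides of prior variances.
#' @param hyper list with `mean` and `var` of the log-precision hyperprior.
#' @return A list of class `"dcm_priors"` with `mean`, `var` (named vectors)
#'   and `hyper`.
#' @export
dcm_priors <- function(net = assemble_network(), variances = NULL,
                       hyper = list(mean = 4, var = 1)) {
  nm <- c(param_names_interest(),
          paste0("fwd", seq_along(net$forward)),
          paste0("bwd", seq_along(net$backward)),
          paste0("modf", seq_along(net$forward)),
          paste0("modb", seq_along(net$backward)),
          "onset", "duration", "obs")
  v <- stats::setNames(rep(1 / 16, length(nm)), nm)
  v[c("onset", "duration")] <- 1 / 32
  if (!is.null(variances)) {
    bad <- setdiff(names(variances), nm)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    v[names(variances)] <- variances
  }
  if (any(v <= 0)) stop("prior variances must be positive", call. = FALSE)
  structure(list(mean = stats::setNames(rep(0, length(nm)), nm), var = v,
                 hyper = hyper),
            class = "dcm_priors")
}

#' @rdname dcm_priors
#' @export
param_names_interest <- function() {
  c("alpha_NA", "alpha_Cl", "alpha_CA_NA", "alpha_KL", "alpha_KIR", "omega")
}

#' Apply log-scale parameters to a network template
#'
#' Returns a copy of `net` with each template quantity scaled by the
#' exponential of the corresponding component of `theta` (modulatory gains
#' are additive in log space). `theta` may name any subset of the full
#' parameter set.
#'
#' @param net a [assemble_network()] template.
#' @param theta named numeric vector of log-scale parameters.
#' @return A modified `"dcm_network"`.
#' @export
apply_theta <- function(net, theta) {
  nm <- names(theta)
  if (is.null(nm) && length(theta))
    stop("theta must be a named vector", call. = FALSE)
  ch_map <- c(alpha_NA = "NA", alpha_Cl = "CL", alpha_CA_NA = "CA_NA",
              alpha_KL = "KL", alpha_KIR = "KIR")
  for (tn in intersect(nm, names(ch_map))) {
    cn <- ch_map[[tn]]
    net$params$channels[[cn]]$gain_scale <-
      net$params$channels[[cn]]$gain_scale * exp(theta[[tn]])
  }
  if ("omega" %in% nm)
    net$params$firing$precision <- net$params$firing$precision * exp(theta[["omega"]])
  for (i in seq_along(net$forward)) {
    if (paste0("fwd", i) %in% nm)
      net$forward[[i]]$weight <- net$forward[[i]]$weight * exp(theta[[paste0("fwd", i)]])
    if (paste0("modf", i) %in% nm)
      net$forward[[i]]$modulation <- net$forward[[i]]$modulation + theta[[paste0("modf", i)]]
  }
  for (i in seq_along(net$backward)) {
    if (paste0("bwd", i) %in% nm)
      net$backward[[i]]$weight <- net$backward[[i]]$weight * exp(theta[[paste0("bwd", i)]])
    if (paste0("modb", i) %in% nm)
      net$backward[[i]]$modulation <- net$backward[[i]]$modulation + theta[[paste0("modb", i)]]
  }
  if ("onset" %in% nm) net$input$onset_mean <- net$input$onset_mean * exp(theta[["onset"]])
  if ("duration" %in% nm) net$input$duration <- net$input$duration * exp(theta[["duration"]])
  if ("obs" %in% nm) net$observation_gain <- net$observation_gain * exp(theta[["obs"]])
  unknown <- setdiff(nm, c(names(ch_map), "omega", "onset", "duration", "obs",
                           paste0("fwd", seq_along(net$forward)),
                           paste0("bwd", seq_along(net$backward)),
                           paste0("modf", seq_along(net$forward)),
                           paste0("modb", seq_along(net$backward))))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  net
}
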