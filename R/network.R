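#' Assemble the six-source auditory network
#'
#' Builds the bilateral three-level auditory hierarchy used to model the
#' mismatch-negativity paradigm: Heschl's gyrus (HG, primary auditory
#' cortex), superior temporal gyrus (STG) and inferior frontal gyrus (IFG)
#' in each hemisphere. Thalamic input drives bilateral HG; forward
#' connections (targeting spiny stellate cells) run HG to STG to IFG and
#' backward connections (targeting pyramidal cells and interneurons) run the
#' reverse path. Condition-specific modulatory gains multiply every extrinsic
#' edge in the deviant condition.
#'
#' @param config optional nested list (e.g. read with [dcm_config()]) with
#'   `sources`, `forward`, `backward`, `input` and `model` entries overriding
#'   the defaults. Edges are lists with `from`, `to`, optional `weight` and
#'   optional `target` population (forward edges may only target
#'   `"spiny_stellate"`; backward edges target pyramidal cells and
#'   interneurons).
#' @return An object of class `"dcm_network"`.
#' @examples
#' net <- assemble_network()
#' net
#' @export
assemble_network <- function(config = NULL) {
  sources <- config$sources %||% default_sources()
  nm <- vapply(sources, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate source name", call. = FALSE)
  fwd <- config$forward %||% lapply(list(
    c("left_HG", "left_STG"), c("right_HG", "right_STG"),
    c("left_STG", "left_IFG"), c("right_STG", "right_IFG")),
    function(e) list(from = e[1], to = e[2], weight = 0.8))
  bwd <- config$backward
  if (is.null(bwd) && is.null(config$forward)) {
    bwd <- lapply(list(
      c("left_STG", "left_HG"), c("right_STG", "right_HG"),
      c("left_IFG", "left_STG"), c("right_IFG", "right_STG")),
      function(e) list(from = e[1], to = e[2], weight = 0.3))
  }
  check_edge <- function(e, kind) {
    if (!all(c(e$from, e$to) %in% nm))
      stop("unknown source name in ", kind, " edge ", e$from, " -> ", e$to,
           call. = FALSE)
    tgt <- e$target %||% if (kind == "forward") "spiny_stellate" else "pyramidal"
    ok <- if (kind == "forward") identical(tgt, "spiny_stellate")
          else tgt %in% c("pyramidal", "interneuron")
    if (!ok)
      stop(kind, " edge ", e$from, " -> ", e$to,
           " targets an invalid population (", tgt, ")", call. = FALSE)
    e$weight <- e$weight %||% if (kind == "forward") 0.8 else 0.3
    e$modulation <- e$modulation %||% 0
    e
  }
  fwd <- lapply(fwd, check_edge, kind = "forward")
  bwd <- lapply(bwd, check_edge, kind = "backward")
  if (!length(bwd))
    warning("network has no backward edges (feedforward only)", call. = FALSE)
  input <- config$input %||% list()
  spec <- do.call(input_spec, input[intersect(names(input),
                                              c("onset_mean", "duration", "amplitude"))])
  targets <- input$targets %||% c("left_HG", "right_HG")
  if (!all(targets %in% nm)) stop("unknown input target source", call. = FALSE)
  model <- config$model %||% list()
  src <- do.call(source_params, model[intersect(names(model), names(formals(source_params)))])
  structure(
    list(sources = sources, source_names = nm, params = src,
         forward = fwd, backward = bwd,
         input = spec, input_targets = targets,
         observation_gain = model$observation_gain %||% 1),
    class = "dcm_network")
}

default_sources <- function() {
  coords <- list(
    left_HG = c(-42, -22, 7), right_HG = c(46, -14, 8),
    left_STG = c(-61, -32, 8), right_STG = c(59, -25, 8),
    left_IFG = c(-46, 20, 8), right_IFG = c(46, 20, 8))
  mapply(function(n, xyz) list(name = n, mni = xyz), names(coords), coords,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @export
print.dcm_network <- function(x, ...) {
  cat(sprintf("<dcm_network> %d sources, %d forward + %d backward edges\n",
              length(x$sources), length(x$forward), length(x$backward)))
  cat("  input ->", paste(x$input_targets, collapse = ", "),
      sprintf("(onset %g ms, sd %g ms)\n", x$input$onset_mean, x$input$duration))
  invisible(x)
}

#' Synthetic sensor gain matrix
#'
#' A seeded stand-in for the MEG lead field: each source projects to the
#' sensor array with a smooth random spatial profile built from a few
#' low-order Fourier harmonics across the sensor index. The construction is
#' bit-reproducible under a given seed and the result always has full column
#' rank.
#'
#' @param n_sensors number of synthetic sensors.
#' @param n_sources number of sources (columns).
#' @param seed integer seed for the profile generator.
#' @return An `n_sensors` by `n_sources` matrix, class `"gain_matrix"`.
#' @export
sensor_gain <- function(n_sensors = 32, n_sources = 6, seed = 1) {
  L <- with_seed(seed, {
    idx <- seq_len(n_sensors) / n_sensors
    vapply(seq_len(n_sources), function(j) {
      prof <- rep(0, n_sensors)
      for (k in 1:4) {
        prof <- prof + stats::rnorm(1, sd = 1 / k) * cos(2 * pi * k * idx) +
          stats::rnorm(1, sd = 1 / k) * sin(2 * pi * k * idx)
      }
      prof
    }, numeric(n_sensors))
  })
  if (qr(L)$rank < n_sources) stop("gain matrix is rank deficient", call. = FALSE)
  colnames(L) <- paste0("src", seq_len(n_sources))
  structure(L, class = c("gain_matrix", "matrix"))
}

# Flatten a dcm_network into the parameter list consumed by the compiled
# integrator, with condition-specific extrinsic scaling.
.nmm_pars <- function(net, condition = c("standard", "deviant"),
                      clamp_nmda = FALSE) {
  condition <- match.arg(condition)
  S <- length(net$sources)
  p <- net$params
  ch <- p$channels
  adj <- function(edges) {
    A <- matrix(0, S, S)
    for (e in edges) {
      i <- match(e$to, net$source_names)
      j <- match(e$from, net$source_names)
      w <- e$weight
      if (condition == "deviant") w <- w * exp(e$modulation)
      A[i, j] <- A[i, j] + w
    }
    A
  }
  Cin <- as.numeric(net$source_names %in% net$input_targets)
  list(
    n_sources = S,
    rev_na = ch[["NA"]]$reversal_potential, rev_cl = ch[["CL"]]$reversal_potential,
    rev_k = ch[["KL"]]$reversal_potential,
    tau_a = ch[["NA"]]$time_constant, tau_n = ch[["CA_NA"]]$time_constant,
    tau_g = ch[["CL"]]$time_constant, tau_k = ch[["KIR"]]$time_constant,
    a_na = ch[["NA"]]$gain_scale, a_can = ch[["CA_NA"]]$gain_scale,
    a_cl = ch[["CL"]]$gain_scale, a_kl = ch[["KL"]]$gain_scale,
    a_kir = ch[["KIR"]]$gain_scale,
    omega = p$firing$precision, vthresh = p$firing$threshold,
    kir_half = -75, kir_slope = p$kir_slope,
    nmda_c1 = p$nmda_c1, nmda_c2 = p$nmda_c2,
    kappa = p$membrane_rate,
    gamma = as.numeric(p$intrinsic[c("sp", "si", "ip", "is", "ps")]),
    A_fwd = adj(net$forward), A_bwd = adj(net$backward),
    C_in = Cin,
    u_onset = net$input$onset_mean, u_sd = net$input$duration,
    u_amp = net$input$amplitude,
    clamp_nmda = clamp_nmda)
}

# initial state (tonic guess) for the network integrator
.nmm_init <- function(net) {
  rep(c(-70, 0, 0, 0, net$params$channels[["KIR"]]$gain_scale),
      3 * length(net$sources))
}

# settle to the no-input equilibrium; returns the state vector. A coarse
# step suffices here: the slowest kinetics (NMDA, 100 ms) dominate the
# approach and RK4 is stable at dt = 2 ms for the fastest (4 ms) channel.
.nmm_equilibrium <- function(net, condition = "standard", dt = 2,
                             settle = 600) {
  pars <- .nmm_pars(net, condition)
  pars$u_amp <- 0
  n <- ceiling(settle / dt)
  tr <- nmm_integrate_cpp(.nmm_init(net), pars, -settle, dt, n, n)
  tr[, ncol(tr)]
}

#' Simulate an evoked sensor-level response
#'
#' Integrates the full network from its no-input equilibrium under the
#' Gaussian thalamic input and maps pyramidal depolarisation (deviation from
#' equilibrium, the equivalent-current-dipole proxy) through the sensor gain
#' matrix. In the deviant condition every extrinsic edge weight is multiplied
#' by the exponential of its modulatory gain.
#'
#' @param net a [assemble_network()] object.
#' @param gain a [sensor_gain()] matrix (sensors by sources).
#' @param condition `"standard"` or `"deviant"`.
#' @param dt integration step, ms.
#' @param duration simulated peristimulus time, ms (samples at
#'   `0, dt, ..., duration - dt`; stimulus onset is t = 0).
#' @param settle equilibration time before t = 0, ms.
#' @return A list of class `"erp_sim"`: `sensors` (sensors by time),
#'   `pyramidal` (sources by time, deviation from equilibrium), `time` (ms).
#' @examples
#' net <- assemble_network()
#' L <- sensor_gain(seed = 1)
#' sim <- simulate_erp(net, L, "standard", duration = 100)
#' @export
simulate_erp <- function(net, gain, condition = c("standard", "deviant"),
                         dt = 0.5, duration = 350, settle = 600) {
  condition <- match.arg(condition)
  if (ncol(gain) != length(net$sources))
    stop("gain matrix columns must match the number of sources", call. = FALSE)
  pars <- .nmm_pars(net, condition)
  x0 <- .nmm_equilibrium(net, condition, settle = settle)
  n <- floor(duration / dt + 1e-9)
  tr <- nmm_integrate_cpp(x0, pars, 0, dt, n - 1, 1)
  S <- length(net$sources)
  py_idx <- ((seq_len(S) - 1) * 3 + 1) * 5 + 1  # V of pyramidal population
  py <- tr[py_idx, , drop = FALSE] - x0[py_idx]
  sens <- net$observation_gain * (unclass(gain) %*% py)
  structure(list(sensors = sens, pyramidal = py, time = (seq_len(n) - 1) * dt,
                 condition = condition, dt = dt),
            class = "erp_sim")
}

#' Read a model/network configuration file
#'
#' Reads a YAML (or JSON) configuration with `model:` and `network:` sections
#' into the nested list accepted by [assemble_network()].
#'
#' @param file path to a YAML file.
#' @return A nested list.
#' @export
dcm_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  out <- cfg$network %||% list()
  if (!is.null(cfg$model)) out$model <- cfg$model
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
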