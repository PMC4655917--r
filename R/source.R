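#' Parameterise one cortical source
#'
#' A source is a three-population motif (granular spiny stellate cells,
#' pyramidal cells, inhibitory interneurons) sharing one set of channel
#' kinetics. Intrinsic connectivity follows the canonical wiring: stellate
#' cells excite pyramidal cells and interneurons, interneurons inhibit
#' pyramidal and stellate cells, and pyramidal cells send a recurrent
#' excitatory collateral back to the stellates.
#'
#' @param channels named list of [channel_kinetics()] for `"NA"`, `"CA_NA"`,
#'   `"CL"`, `"KL"`, `"KIR"`. Each channel's `gain_scale` is its effective
#'   alpha weight.
#' @param intrinsic named weights for the five canonical intrinsic
#'   projections: `sp` (stellate to pyramidal), `si` (stellate to
#'   interneuron), `ip` (interneuron to pyramidal), `is` (interneuron to
#'   stellate), `ps` (pyramidal to stellate). Nonnegative.
#' @param membrane_rate membrane rate constant, 1/ms.
#' @param firing a [firing_function()].
#' @param kir_slope logistic slope (mV) of the KIR gate.
#' @param nmda_c1,nmda_c2 NMDA magnesium-block coefficients.
#' @return An object of class `"source_params"`.
#' @export
source_params <- function(channels = default_channels(),
                          intrinsic = c(sp = 0.5, si = 0.5, ip = 0.8,
                                        is = 0.4, ps = 0.3),
                          membrane_rate = 1 / 8,
                          firing = firing_function(),
                          kir_slope = 5, nmda_c1 = 0.2, nmda_c2 = 0.062) {
  need <- c("NA", "CA_NA", "CL", "KL", "KIR")
  if (!all(need %in% names(channels)))
    stop("channels must include: ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(c("sp", "si", "ip", "is", "ps") %in% names(intrinsic)))
    stop("intrinsic weights must be named sp, si, ip, is, ps", call. = FALSE)
  if (any(intrinsic < 0)) stop("intrinsic weights must be nonnegative", call. = FALSE)
  structure(
    list(channels = channels[need], intrinsic = intrinsic,
         membrane_rate = membrane_rate, firing = firing,
         kir_slope = kir_slope, nmda_c1 = nmda_c1, nmda_c2 = nmda_c2),
    class = "source_params")
}

#' @param gains named log-scale multipliers applied to the default channel
#'   gain weights (e.g. `c(alpha_KL = -1)` halves-ish the potassium leak).
#' @rdname source_params
#' @export
default_channels <- function(gains = NULL) {
  base <- c("NA" = 0.8, "CA_NA" = 0.15, "CL" = 1.2, "KL" = 0.4, "KIR" = 0.4)
  logmult <- c(alpha_NA = 0, alpha_CA_NA = 0, alpha_Cl = 0, alpha_KL = 0,
               alpha_KIR = 0)
  if (!is.null(gains)) {
    bad <- setdiff(names(gains), names(logmult))
    if (length(bad)) stop("unknown channel gain(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    logmult[names(gains)] <- gains
  }
  keymap <- c("NA" = "alpha_NA", "CA_NA" = "alpha_CA_NA", "CL" = "alpha_Cl",
              "KL" = "alpha_KL", "KIR" = "alpha_KIR")
  out <- lapply(names(base), function(nm)
    channel_kinetics(nm, gain_scale = base[[nm]] * exp(logmult[[keymap[[nm]]]])))
  names(out) <- names(base)
  out
}

#' Population state and its time derivatives
#'
#' `population_state()` bundles the membrane potential with the four kinetic
#' conductances of one population. `population_derivatives()` evaluates the
#' conductance-based dynamics for that population: each kinetic conductance
#' relaxes with first-order kinetics `dg/dt = (alpha * drive - g) / tau`
#' toward its gain-scaled afferent drive, and the membrane potential moves at
#' the membrane rate constant times the sum of gated channel currents
#' `g * gate(V) * (V_rev - V)`, plus the static potassium leak
#' `alpha_KL * (V_K - V)`. The KIR conductance relaxes toward its gain under
#' tonic unit drive and its current is scaled instantaneously by [kir_gate()].
#'
#' This R implementation is the reference form of the dynamics; the network
#' integrator evaluates the same equations in compiled code.
#'
#' @param membrane_potential V, mV.
#' @param conductance named nonnegative vector for `"NA"`, `"CA_NA"`, `"CL"`,
#'   `"KIR"` (the potassium leak has no kinetic state).
#' @return `population_state()`: an object of class `"population_state"`;
#'   `population_derivatives()`: a list with `dV` (mV/ms) and `dg` (per ms).
#' @export
population_state <- function(membrane_potential = -70,
                             conductance = c("NA" = 0, "CA_NA" = 0,
                                             "CL" = 0, "KIR" = 0)) {
  if (!all(is.finite(c(membrane_potential, conductance))))
    stop("population state must be finite", call. = FALSE)
  if (any(conductance < 0))
    stop("conductances must be nonnegative", call. = FALSE)
  structure(list(membrane_potential = membrane_potential,
                 conductance = conductance[c("NA", "CA_NA", "CL", "KIR")]),
            class = "population_state")
}

#' @param state a [population_state()].
#' @param afferent_rates named nonnegative drives for the kinetic channels
#'   (`"NA"`, `"CA_NA"`, `"CL"`, `"KIR"`); missing entries are 0, except
#'   `"KIR"` which defaults to tonic drive 1.
#' @param p a [source_params()].
#' @param clamp_nmda if `TRUE` the NMDA voltage gate is held fully open.
#' @rdname population_state
#' @export
population_derivatives <- function(state, afferent_rates = NULL, p = source_params(),
                                   clamp_nmda = FALSE) {
  if (!all(is.finite(c(state$membrane_potential, state$conductance))))
    stop("non-finite population state", call. = FALSE)
  drv <- c("NA" = 0, "CA_NA" = 0, "CL" = 0, "KIR" = 1)
  if (!is.null(afferent_rates)) {
    if (any(afferent_rates < 0)) stop("drives must be nonnegative", call. = FALSE)
    drv[names(afferent_rates)] <- afferent_rates
  }
  V <- state$membrane_potential
  g <- state$conductance
  ch <- p$channels
  alpha <- vapply(ch, function(x) x$gain_scale, 0)
  dg <- c(
    "NA"    = (alpha[["NA"]] * drv[["NA"]] - g[["NA"]]) / ch[["NA"]]$time_constant,
    "CA_NA" = (alpha[["CA_NA"]] * drv[["CA_NA"]] - g[["CA_NA"]]) / ch[["CA_NA"]]$time_constant,
    "CL"    = (alpha[["CL"]] * drv[["CL"]] - g[["CL"]]) / ch[["CL"]]$time_constant,
    "KIR"   = (alpha[["KIR"]] * drv[["KIR"]] - g[["KIR"]]) / ch[["KIR"]]$time_constant)
  mg <- if (clamp_nmda) 1 else nmda_gate(V, p$nmda_c1, p$nmda_c2)
  current <- g[["NA"]] * (ch[["NA"]]$reversal_potential - V) +
    g[["CA_NA"]] * mg * (ch[["CA_NA"]]$reversal_potential - V) +
    g[["CL"]] * (ch[["CL"]]$reversal_potential - V) +
    g[["KIR"]] * kir_gate(V, p$kir_slope) * (ch[["KIR"]]$reversal_potential - V) +
    alpha[["KL"]] * (ch[["KL"]]$reversal_potential - V)
  list(dV = p$membrane_rate * current, dg = dg)
}

#' Integrate one source with prescribed afferent drives
#'
#' Fixed-step fourth-order Runge-Kutta integration of the three populations
#' of one source. Afferent drives are prescribed per population and channel
#' on the integration grid (piecewise constant over each step); intrinsic
#' coupling between the populations is evaluated from the evolving firing
#' rates. Time grids are closed on the left and half-open on the right:
#' samples sit at `0, dt, ..., duration - dt`.
#'
#' @param p a [source_params()].
#' @param drives either `NULL` (no afferent drive), or a list with entries
#'   `spiny_stellate`, `pyramidal`, `interneuron`, each a matrix with
#'   `duration/dt` rows and columns among `"NA"`, `"CA_NA"`, `"CL"` giving
#'   the synaptic drive at each time step. Missing populations get zero
#'   drive.
#' @param dt integration step, ms.
#' @param duration total integration time, ms.
#' @param init optional initial state vector (length 15, states ordered
#'   V, g_NA, g_CA_NA, g_CL, g_KIR per population); default is the tonic
#'   equilibrium approximation.
#' @param clamp_nmda hold the NMDA voltage gate open (diagnostics).
#' @return A list with `time` (ms) and per-population matrices of `V` and
#'   conductances (`time` by state), class `"source_trajectory"`.
#' @examples
#' p <- source_params(intrinsic = c(sp = 0, si = 0, ip = 0, is = 0, ps = 0))
#' tr <- integrate_source(p, dt = 0.5, duration = 50)
#' @export
integrate_source <- function(p, drives = NULL, dt = 0.5, duration = 300,
                             init = NULL, clamp_nmda = FALSE) {
  if (dt <= 0 || duration < dt) stop("need dt > 0 and duration >= dt", call. = FALSE)
  n <- floor(duration / dt + 1e-9)
  times <- (seq_len(n) - 1) * dt
  pops <- c("spiny_stellate", "pyramidal", "interneuron")
  dmat <- lapply(pops, function(nm) {
    m <- matrix(0, n, 3, dimnames = list(NULL, c("NA", "CA_NA", "CL")))
    if (!is.null(drives[[nm]])) {
      d <- drives[[nm]]
      m[seq_len(min(nrow(d), n)), colnames(d)] <- d[seq_len(min(nrow(d), n)), ]
    }
    m
  })
  names(dmat) <- pops
  alpha <- vapply(p$channels, function(x) x$gain_scale, 0)
  if (is.null(init)) {
    init <- rep(c(-70, 0, 0, 0, alpha[["KIR"]]), 3)
  }
  x <- matrix(init, nrow = 5)  # states x populations
  out <- array(NA_real_, c(n, 5, 3))
  deriv <- function(x, drive_row) {
    H <- firing_rate(x[1, ], p$firing)
    # intrinsic afferents: columns = ss, py, in
    exc <- c(p$intrinsic[["ps"]] * H[2], p$intrinsic[["sp"]] * H[1],
             p$intrinsic[["si"]] * H[1])
    inh <- c(p$intrinsic[["is"]] * H[3], p$intrinsic[["ip"]] * H[3], 0)
    dx <- matrix(0, 5, 3)
    for (j in 1:3) {
      st <- population_state(x[1, j],
                             c("NA" = x[2, j], "CA_NA" = x[3, j],
                               "CL" = x[4, j], "KIR" = x[5, j]))
      dr <- c("NA" = drive_row[[j]][["NA"]] + exc[j],
              "CA_NA" = drive_row[[j]][["CA_NA"]] + exc[j],
              "CL" = drive_row[[j]][["CL"]] + inh[j],
              "KIR" = 1)
      d <- population_derivatives(st, dr, p, clamp_nmda = clamp_nmda)
      dx[, j] <- c(d$dV, d$dg)
    }
    dx
  }
  for (i in seq_len(n)) {
    out[i, , ] <- x
    if (i == n) break
    drow <- lapply(dmat, function(m) m[i, ])
    k1 <- deriv(x, drow)
    k2 <- deriv(x + dt / 2 * k1, drow)
    k3 <- deriv(x + dt / 2 * k2, drow)
    k4 <- deriv(x + dt * k3, drow)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(x)) || any(abs(x[1, ]) > 500))
      stop(sprintf("integration blow-up at step %d (t = %g ms)", i, times[i]),
           call. = FALSE)
  }
  traj <- lapply(1:3, function(j) {
    m <- out[, , j, drop = TRUE]
    colnames(m) <- c("V", "g_NA", "g_CA_NA", "g_CL", "g_KIR")
    m
  })
  names(traj) <- pops
  structure(c(list(time = times), traj), class = "source_trajectory")
}
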