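#' Ion-channel kinetics
#'
#' Construct the kinetic description of one ion-channel species used by the
#' neural mass model. Five species are recognised: `"NA"` (AMPA-mediated
#' sodium), `"CA_NA"` (NMDA-mediated sodium/calcium), `"CL"` (GABA-A-mediated
#' chloride), `"KL"` (leak potassium, instantaneous) and `"KIR"`
#' (inward-rectifying potassium).
#'
#' Prior reversal potentials are +60 mV for the two glutamatergic channels,
#' -90 mV for chloride and -70 mV for both potassium channels. Prior time
#' constants are 4 ms (AMPA), 100 ms (NMDA), 16 ms (GABA-A) and 18 ms (KIR);
#' the potassium leak has no kinetic state.
#'
#' @param name channel species, one of `"NA"`, `"CA_NA"`, `"CL"`, `"KL"`,
#'   `"KIR"`.
#' @param reversal_potential reversal potential in mV; defaults to the prior
#'   value for `name`.
#' @param time_constant conductance time constant in ms (ignored, and `NA`,
#'   for `"KL"`); defaults to the prior value.
#' @param gain_scale positive dimensionless conductance gain (the exponential
#'   of a log-scale parameter).
#' @param gating voltage gating applied to the channel current: `"none"`,
#'   `"nmda"` or `"kir"`; defaults to the canonical gating for `name`.
#' @return An object of class `"channel_kinetics"`.
#' @examples
#' channel_kinetics("KIR")
#' channel_kinetics("NA", gain_scale = exp(-0.5))
#' @export
channel_kinetics <- function(name, reversal_potential = NULL,
                             time_constant = NULL, gain_scale = 1,
                             gating = NULL) {
  name <- match.arg(name, c("NA", "CA_NA", "CL", "KL", "KIR"))
  defaults <- .channel_defaults[[name]]
  if (is.null(reversal_potential)) reversal_potential <- defaults$rev
  if (is.null(time_constant)) time_constant <- defaults$tau
  if (is.null(gating)) gating <- defaults$gating
  gating <- match.arg(gating, c("none", "nmda", "kir"))
  if (!is.finite(gain_scale) || gain_scale <= 0)
    stop("gain_scale must be a positive finite number", call. = FALSE)
  if (name != "KL" && (!is.finite(time_constant) || time_constant <= 0))
    stop("time_constant must be positive", call. = FALSE)
  structure(
    list(name = name, reversal_potential = reversal_potential,
         time_constant = if (name == "KL") NA_real_ else time_constant,
         gain_scale = gain_scale, gating = gating),
    class = "channel_kinetics")
}

# prior channel constants (mV, ms)
.channel_defaults <- list(
  "NA"    = list(rev =  60, tau =   4, gating = "none"),
  "CA_NA" = list(rev =  60, tau = 100, gating = "nmda"),
  "CL"    = list(rev = -90, tau =  16, gating = "none"),
  "KL"    = list(rev = -70, tau =  NA, gating = "none"),
  "KIR"   = list(rev = -70, tau =  18, gating = "kir")
)

#' @export
print.channel_kinetics <- function(x, ...) {
  cat(sprintf("<channel %s>  V_rev = %g mV, tau = %s ms, gain = %g, gating = %s\n",
              x$name, x$reversal_potential,
              if (is.na(x$time_constant)) "static" else format(x$time_constant),
              x$gain_scale, x$gating))
  invisible(x)
}

#' Presynaptic firing sigmoid
#'
#' Mean afferent firing rate as a function of presynaptic membrane potential:
#' a logistic sigmoid centred on the firing threshold with slope
#' `sqrt(precision)`, so that the precision parameter behaves as the inverse
#' variance of the population firing-threshold distribution. The precision is
#' the model's proxy for presynaptic calcium availability: large values mean
#' tightly synchronised afferent output.
#'
#' @param threshold firing threshold in mV (prior -40).
#' @param precision firing precision omega in 1/mV^2; must be positive.
#' @return An object of class `"firing_function"`.
#' @examples
#' f <- firing_function()
#' firing_rate(-40, f)  # 0.5 at threshold
#' @export
firing_function <- function(threshold = -40, precision = 1 / 16) {
  if (!is.finite(precision) || precision <= 0)
    stop("firing precision must be positive", call. = FALSE)
  structure(list(threshold = threshold, precision = precision),
            class = "firing_function")
}

#' @param V_pre presynaptic membrane potential(s), mV.
#' @param f a [firing_function()].
#' @return `firing_rate()` returns values in [0, 1].
#' @rdname firing_function
#' @export
firing_rate <- function(V_pre, f = firing_function()) {
  if (!inherits(f, "firing_function")) f <- do.call(firing_function, f)
  stats::plogis(sqrt(f$precision) * (V_pre - f$threshold))
}

#' Inward-rectifier potassium gate
#'
#' Sigmoidal switch scaling the KIR conductance: maximal at hyperpolarised
#' potentials, zero at depolarised potentials, and exactly 50% at -75 mV.
#'
#' @param V membrane potential, mV (vectorised).
#' @param slope logistic slope in mV (default 5).
#' @param half half-activation potential, mV (default -75).
#' @return Gate value in [0, 1], monotone decreasing in `V`.
#' @examples
#' kir_gate(-75)            # 0.5
#' kir_gate(c(-100, -50))   # near 1, near 0
#' @export
kir_gate <- function(V, slope = 5, half = -75) {
  if (!is.finite(slope) || slope <= 0)
    stop("kir_gate slope must be positive", call. = FALSE)
  stats::plogis(-(V - half) / slope)
}

#' NMDA magnesium-block gate
#'
#' Voltage dependence of the NMDA-mediated current: relief of the magnesium
#' block with depolarisation, `1 / (1 + c1 * exp(-c2 * V))`.
#'
#' @param V membrane potential, mV (vectorised).
#' @param c1,c2 block coefficients (defaults 0.2 and 0.062 per mV).
#' @return Gate value in (0, 1], monotone increasing in `V`.
#' @examples
#' nmda_gate(0)   # 1 / 1.2
#' @export
nmda_gate <- function(V, c1 = 0.2, c2 = 0.062) {
  1 / (1 + c1 * exp(-c2 * V))
}

#' Gaussian exogenous (thalamic) input
#'
#' Stimulus-bound thalamic drive modelled as a Gaussian bump with peak at
#' `onset_mean` and standard deviation `duration`.
#'
#' @param t peristimulus time(s), ms.
#' @param spec list with `onset_mean` (ms, prior 64), `duration` (ms, prior
#'   16) and `amplitude`; see [input_spec()].
#' @return Drive amplitude at `t`.
#' @examples
#' exogenous_input(64, input_spec())  # the peak
#' @export
exogenous_input <- function(t, spec = input_spec()) {
  spec$amplitude * exp(-0.5 * ((t - spec$onset_mean) / spec$duration)^2)
}

#' @param onset_mean peak latency of the input bump, ms.
#' @param duration standard deviation of the bump, ms; must be positive.
#' @param amplitude bump amplitude in drive units.
#' @rdname exogenous_input
#' @export
input_spec <- function(onset_mean = 64, duration = 16, amplitude = 0.6) {
  if (!is.finite(duration) || duration <= 0)
    stop("input duration must be positive", call. = FALSE)
  list(onset_mean = onset_mean, duration = duration, amplitude = amplitude)
}
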