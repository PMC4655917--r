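---
title: "Methods: conductance-based DCM of synaptic channel function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conductance-based DCM of synaptic channel function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(channeldcm)
```

This vignette is the package's own account of its model, the design
choices made where the design was genuinely open, and what the synthetic
cohorts do and do not establish about real data.

## The generative model

Each source holds three populations (spiny stellate, pyramidal,
interneuron). The membrane potential of a population follows

$$\dot V = \kappa\Big[g_A(V_{Na}-V) + g_N\,m(V)(V_{Na}-V) + g_G(V_{Cl}-V)
  + g_K\,k(V)(V_K-V) + \alpha_{KL}(V_K-V)\Big],$$

with reversal potentials $V_{Na}=+60$, $V_{Cl}=-90$, $V_K=-70$ mV, and
each kinetic conductance relaxing as $\dot g = (\alpha\,s - g)/\tau$
($\tau$ = 4, 100, 16, 18 ms for AMPA, NMDA, GABA-A and KIR) toward its
gain-scaled afferent drive $s$. The potassium leak is static; the KIR
conductance relaxes toward its gain under tonic unit drive and its current
is scaled instantaneously by the voltage gate.

**Functional forms.** The literature prints the constants above but not
every functional form, so the package fixes them as follows and exposes
them in configuration:

* *Firing sigmoid* $H(V) = \mathrm{logit}^{-1}\!\big(\sqrt\omega\,(V -
  V_{thresh})\big)$ with $V_{thresh} = -40$ mV. The square-root link makes
  $\omega$ an inverse-variance analogue of the population threshold
  distribution — the presynaptic-calcium proxy. No baseline activation
  term is subtracted.
* *KIR gate* $k(V) = \mathrm{logit}^{-1}\!\big(-(V+75)/s\big)$: maximal
  when hyperpolarised, zero when depolarised, exactly 50% at $-75$ mV for
  any slope. The slope default is 5 mV (only the half-activation point is
  constrained by the physiology being emulated).
* *NMDA magnesium block* $m(V) = 1/(1 + 0.2\,e^{-0.062 V})$, the standard
  conductance-NMM coefficients.
* Whether KIR carries its own kinetic state was open; the 18 ms time
  constant strongly suggests one, so the package gives it a first-order
  state (`dg_K/dt = (alpha_KIR - g_K)/tau_K`) gated instantaneously.

**Intrinsic wiring and scales.** The canonical motif (stellate to
pyramidal and interneuron; interneuron to pyramidal and stellate;
pyramidal recurrent to stellate) is weighted `sp = 0.5, si = 0.5, ip =
0.8, is = 0.4, ps = 0.3`, with membrane rate constant $\kappa = 1/8$
ms$^{-1}$, base channel gains `NA 0.8, CA_NA 0.15, CL 1.2, KL 0.4, KIR
0.4` and input amplitude 0.6. These were chosen against two plausibility
requirements: the prior network must produce a biphasic evoked transient
peaking near 80 ms in primary auditory cortex that returns to baseline
within ~250 ms, with onset latencies increasing up the HG–STG–IFG
hierarchy and no persistent up-state (an earlier, stronger
stellate-to-pyramidal gain produced bistability and was rejected); and
the response must remain robust across the control cohort's parameter
distribution — every draw at the generative between-subject spread keeps
at least ~40% of the template's response amplitude, as healthy subjects
reliably show an evoked field in this paradigm (a weaker input left a
fifth of simulated controls effectively response-free and was rejected
for that reason). All are configuration-exposed.

**Network and observation.** Six sources at the usual MNI prior locations;
four forward edges (weight 0.8) targeting stellate cells, four backward
edges (0.3) targeting pyramidal cells and interneurons; Gaussian thalamic
input to bilateral HG with peak latency 64 ms and SD 16 ms ("duration" is
interpreted as the Gaussian SD, the referenced implementation's
convention). Deviant tones multiply every extrinsic edge by `exp(mod)`.
The equivalent-current-dipole proxy is the pyramidal membrane-potential
deviation from equilibrium, mapped through a seeded synthetic gain matrix
(32 sensors, smooth low-order Fourier profiles, full column rank) — a
stand-in for the real lead field, which is out of scope along with source
localisation. Conduction delays between sources are omitted.

## Numerics

The network integrator is fixed-step RK4 at `dt = 0.5` ms (compiled), with
equilibration handled by a 600 ms settle at `dt = 2` ms before stimulus
onset; trajectories blow up with an informative error if any |V| exceeds
500 mV. Sample grids are closed on the left, half-open on the right, with
t = 0 at stimulus onset. The integrator is validated against an adaptive
Runge–Kutta oracle (deSolve, tolerance $10^{-9}$) at a relative RMS below
$10^{-4}$ over 300 ms horizons and random parameter draws, and the
compiled right-hand side against an independent R implementation of the
same equations.

## Preprocessing and its observation map

The sensor pipeline mirrors standard MEG practice: zero-phase Butterworth
band-pass 0.5–30 Hz (order 4) at the raw rate, decimation to 200 Hz,
epoching to the half-open window [-100, 350) ms (exactly 90 samples),
baseline correction over [-100, 0), peak-to-peak artifact rejection (the
threshold is unit-agnostic and configuration-set — the printed "pF"
threshold of the emulated acquisition does not transfer to synthetic
units), condition averaging, removal of the first DCT component (the
temporal mean) and projection onto the 8 leading SVD modes of the
condition-concatenated data. The SVD is taken on plain data covariance
(the lead-field-weighted covariance of the emulated workflow needs the
real lead field, which is out of scope), and modes are computed per
subject.

Because the band-pass is not transparent to the evoked waveform, fitting
raw model output to filtered data biases the channel estimates (verified
at design time on noise-free sessions). The pipeline is linear and
time-invariant, so the package precomputes its action as two matrices — the
map from a trial's template to its own preprocessed epoch, and the map
from the (standard) neighbours' template to the filter tails leaking into
that epoch — and pushes every model prediction through the same map
(`preproc_response_map()`). On noise-free sessions this makes pipeline
recovery exact to within integration tolerance.

## Inversion

All fitted quantities are log-scale multipliers with Gaussian priors:
mean 0; variance 1/16 for channel gains, firing precision, extrinsic,
modulatory and observation gains; 1/32 for the input timing (common DCM
practice; nothing tighter is warranted by the emulated setting). Residual
noise is a single scalar precision across modes with a Gaussian hyperprior
on its log (mean 4, variance 1). Fitting maximises the Laplace free
energy by damped Gauss–Newton: central finite-difference Jacobians (step
$10^{-3}$), a Levenberg trust region with up to 4 damping escalations per
iteration, and a conditional Newton update of the log-precision after
every step. Iterations ascend the joint log density (the free energy with
the posterior entropy held fixed), which every accepted step provably
increases, so the iteration trace is monotone; the reported free energy
adds the Gaussian entropy of the posterior at convergence. Convergence is
an increase below $10^{-2}$ nats (default) or 64 iterations. The
inversion is deterministic (single start); percent variance explained is
$100(1 - RSS/TSS)$ on the reduced data.

Cohorts are fitted in two stages: every session from the prior mean, then
every session re-fitted from the elementwise average of the stage-1
posterior means — controls only by default, so patients start from the
same (control-defined) region of parameter space.

## The synthetic cohort

The generator emulates the passive auditory oddball design: 400 trials
per session at a fixed 1100 ms interval, 12% deviants (exactly 48) with
no two adjacent, two sessions per subject; tone frequencies are metadata.
Subject effects on the six parameters of interest are Gaussian in log
space (between-subject SD 0.25), with independent session effects
(within-subject SD 0.10) — the generative structure the diagnostics
assume. Sensor noise is white at the single-trial level with SD 200 in
template units, chosen so the standards' evoked field carries roughly a
5 dB amplitude SNR before filtering (deviants, with 48 trials, are
noisier). Virtual patients are controls whose target parameter is shifted
in log space (negative = loss of function); a potassium-leak patient uses
`alpha_KL`, a presynaptic-calcium patient `omega`. A clinical-scale cohort
(94 controls) is configuration-reachable; the package default of 20
controls keeps the full study tractable on one CPU (about ten minutes),
and all statistics are cohort-size-agnostic.

What passing tests show — and do not. The generator's noise is white and
its subject variability matches the diagnostics' Gaussian assumptions
exactly; real MEG has structured noise, head-position and lead-field
error, and between-subject variability of unknown shape. Recovery and
detection results on these cohorts therefore validate the *procedure*
(identifiability of the channel parameters given the design, calibration
of the statistics), not clinical performance. Empirical percentages from
real cohorts are not reproducible here and are not asserted anywhere in
the package.

## Diagnostics

* **Outlier screen**: per parameter of interest, sessions are scored by
  their maximum absolute posterior correlation with all remaining
  parameters; the worst subjects are trimmed until 90% remain (the
  retention rate is the constrained quantity; max-|correlation| ranking is
  the package's operationalisation of "high covariance").
* **ICC**: one-way random-effects ICC(1,1) of session 1 vs session 2
  posterior means with the one-way ANOVA F test (the variant is fixed
  here; the emulated workflow does not name one).
* **CVA / Wilks**: canonical correlations (via `stats::cancor`) between
  the subjects-by-6 matrix of session-averaged means and a design of
  patient indicator plus mean column; $\Lambda = \prod(1-r_i^2)$ with
  Bartlett's $\chi^2$ approximation. Type-I error is verified to be near
  nominal by simulation.
* **Non-overlap probability**: defined as one minus the overlapping
  coefficient, $1 - \int \min(p, q)$, by adaptive quadrature — an
  interpretive choice for the "non-overlapping probability density",
  matching the equal-variance closed form $1 - 2\Phi(-d/2)$ to $10^{-6}$.
  The "P > 0.90 probable difference" criterion therefore reproduces the
  qualitative behaviour of the emulated test, not necessarily its exact
  percentages.
* **Leave-one-out specificity**: each held-out control (session-averaged
  mean; cohort-average within-subject variance) against the remaining
  cohort's density (mean and between-subject variance of session-averaged
  means); flagged when the non-overlap exceeds 0.90.
* **ROC/AUC**: 50 decision thresholds swept from one tenth to twice the
  midpoint of the control and patient means; sensitivity and specificity
  from Gaussian tails on the loss-of-function side; trapezoidal AUC with
  endpoints clamped to (0,0) and (1,1). Patient variance is the controls'
  average within-subject (between-session) variance.
* **Ellipsoids**: axis-aligned, centre at the posterior means, semi-axes
  one posterior SD, for any three named parameters.

Session-averaging for CVA uses all subjects' sessions (the handling of
single-session patients in the emulated workflow is ambiguous; averaging
whatever sessions exist is the package's convention). No multiple-testing
correction is applied across the six parameters, matching the emulated
analysis.

## Known limitations

* The synthetic gain matrix stands in for a head model; spatial realism
  (sensor covariance, field spread) is out of scope.
* `alpha_CA_NA`, `alpha_KIR` and `omega` are weakly identified from the
  evoked response at the default operating point (posterior SDs several
  times larger than the well-identified `alpha_NA`, `alpha_Cl`,
  `alpha_KL`) — an honest property of the design that mirrors the lower
  between-session reliability of receptor-kinetic parameters in real
  cohorts.
* The free-energy landscape is non-convex; the deterministic single-start
  scheme can in principle settle in local optima for extreme parameter
  shifts. The two-stage initialisation mitigates this within cohorts.
* Conduction delays, pink sensor noise and per-edge generative
  variability are deliberately absent from the generator; all are
  configuration-extensible.
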