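#' Auditory oddball paradigm specification
#'
#' Defaults reproduce the passive mismatch-negativity design: 400 trials per
#' session, 12% deviants, fixed 1100 ms inter-trial interval, two sessions
#' per subject. Tone frequencies are metadata only; the model is driven by
#' the Gaussian thalamic input, with the condition difference carried by the
#' modulatory gains.
#'
#' @param n_trials trials per session.
#' @param deviant_fraction fraction of deviant trials (0 < f < 1).
#' @param iti inter-trial interval, ms.
#' @param sessions sessions per subject.
#' @param tones named tone frequencies, Hz (metadata).
#' @return A list of class `"paradigm_spec"`.
#' @export
paradigm_spec <- function(n_trials = 400, deviant_fraction = 0.12, iti = 1100,
                          sessions = 2, tones = c(standard = 500, deviant = 800)) {
  if (deviant_fraction <= 0 || deviant_fraction >= 1)
    stop("deviant_fraction must be in (0, 1)", call. = FALSE)
  structure(list(n_trials = n_trials, deviant_fraction = deviant_fraction,
                 iti = iti, sessions = sessions, tones = tones),
            class = "paradigm_spec")
}

#' Generate a pseudo-random trial sequence
#'
#' Emits exactly `round(n_trials * deviant_fraction)` deviants at seeded
#' pseudo-random positions, by default with no two deviants adjacent (the
#' usual mismatch-negativity constraint), and onsets on the fixed
#' inter-trial grid `t_k = k * iti`.
#'
#' @param spec a [paradigm_spec()].
#' @param seed integer seed.
#' @param no_adjacent forbid adjacent deviants.
#' @return A list with `labels` (character), `onsets` (ms) and `n_deviant`.
#' @export
generate_paradigm <- function(spec = paradigm_spec(), seed = 1,
                              no_adjacent = TRUE) {
  n <- spec$n_trials
  k <- round(n * spec$deviant_fraction)
  pos <- with_seed(seed, {
    if (no_adjacent) {
      if (k > (n + 1) %/% 2) stop("too many deviants for the spacing rule",
                                  call. = FALSE)
      # choose k of n-k+1 slots, then re-expand so chosen slots are non-adjacent
      sort(sample.int(n - k + 1, k)) + seq_len(k) - 1
    } else sort(sample.int(n, k))
  })
  labels <- rep("standard", n)
  labels[pos] <- "deviant"
  list(labels = labels, onsets = (seq_len(n) - 1) * spec$iti, n_deviant = k)
}

#' Control-cohort generative specification
#'
#' Subject-level log-scale effects on the six parameters of interest are
#' drawn from independent Gaussians (between-subject SD), with an additional
#' independent session-level Gaussian effect (within-subject SD) per
#' recording; sensor noise is additive white Gaussian at the single-trial
#' level. Everything is reproducible from the master seed.
#'
#' @param n_controls number of control subjects (>= 2).
#' @param between_sd between-subject SD of each log-scale parameter.
#' @param within_sd between-session (within-subject) SD.
#' @param noise_sd single-trial sensor noise SD, signal units.
#' @param seed master seed (kept small; per-subject streams are derived
#'   from it).
#' @param paradigm a [paradigm_spec()].
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_controls = 20, between_sd = 0.25, within_sd = 0.10,
                        noise_sd = 200, seed = 1, paradigm = paradigm_spec()) {
  if (n_controls < 2) stop("need at least 2 controls", call. = FALSE)
  if (between_sd < 0 || within_sd < 0 || noise_sd < 0)
    stop("SDs must be nonnegative", call. = FALSE)
  structure(list(n_controls = n_controls, between_sd = between_sd,
                 within_sd = within_sd, noise_sd = noise_sd,
                 seed = seed %% 100000L, paradigm = paradigm),
            class = "cohort_spec")
}

#' Draw one subject's true parameters
#'
#' @param cohort a [cohort_spec()].
#' @param index subject index (1-based); patients use indices above
#'   `n_controls`.
#' @return A list with `subject_effect` (named, the six parameters of
#'   interest) and `sessions`, a list of per-session true log-scale vectors
#'   (subject effect plus session effect).
#' @export
sample_subject <- function(cohort, index) {
  nm <- param_names_interest()
  sub_eff <- with_seed(cohort$seed * 1000L + 7L * index,
                       stats::setNames(stats::rnorm(length(nm), 0, cohort$between_sd), nm))
  sessions <- lapply(seq_len(cohort$paradigm$sessions), function(s) {
    ses_eff <- with_seed(cohort$seed * 1000L + 7L * index + 3L * s + 1L,
                         stats::rnorm(length(nm), 0, cohort$within_sd))
    sub_eff + ses_eff
  })
  list(subject = index, subject_effect = sub_eff, sessions = sessions)
}

#' Virtual channelopathy patient specification
#'
#' @param target one of the six fitted parameters of interest (e.g.
#'   `"alpha_KL"` for a potassium-leak loss of function, `"omega"` for a
#'   presynaptic-calcium deficit).
#' @param shift log-scale shift (negative = loss of function).
#' @return A list of class `"patient_spec"`.
#' @export
patient_spec <- function(target, shift) {
  if (!target %in% param_names_interest())
    stop("target must be one of: ", paste(param_names_interest(), collapse = ", "),
         call. = FALSE)
  structure(list(target = target, shift = shift), class = "patient_spec")
}

#' Turn a sampled control into a patient
#'
#' Shifts only the target parameter in every session's true vector; all
#' other generative settings (paradigm, noise, seeds) are untouched.
#'
#' @param subject output of [sample_subject()].
#' @param p a [patient_spec()].
#' @return The modified subject, with a `patient` element recording the
#'   spec.
#' @export
make_patient <- function(subject, p) {
  stopifnot(inherits(p, "patient_spec"))
  subject$subject_effect[p$target] <- subject$subject_effect[p$target] + p$shift
  subject$sessions <- lapply(subject$sessions, function(th) {
    th[p$target] <- th[p$target] + p$shift
    th
  })
  subject$patient <- p
  subject
}

#' Simulate one continuous recording session
#'
#' Embeds the per-condition evoked responses (from [simulate_erp()] at the
#' subject's true parameters) at the paradigm onsets in a continuous
#' multi-sensor record and adds white Gaussian sensor noise, ready for the
#' preprocessing chain.
#'
#' @param true_params named log-scale parameter vector (the session truth).
#' @param paradigm output of [generate_paradigm()].
#' @param net network template (condition effects enter through its
#'   modulatory gains).
#' @param gain sensor gain matrix.
#' @param noise_sd single-sample sensor noise SD.
#' @param seed seed for the noise stream.
#' @param fs raw sampling rate, Hz.
#' @param pad_ms silence padding before the first and after the last trial.
#' @return A list: `record` (sensors by samples), `fs_hz`, `onsets` (ms into
#'   the record), `labels`.
#' @export
simulate_session <- function(true_params, paradigm, net, gain, noise_sd = 200,
                             seed = 1, fs = 400, pad_ms = 500) {
  net_s <- apply_theta(net, true_params)
  dt_out <- 1000 / fs
  tmpl <- lapply(c(standard = "standard", deviant = "deviant"), function(cc) {
    sim <- simulate_erp(net_s, gain, cc, dt = 0.5, duration = 350)
    idx <- seq(1, length(sim$time), by = round(dt_out / 0.5))
    sim$sensors[, idx, drop = FALSE]
  })
  n_sensors <- nrow(gain)
  total_ms <- 2 * pad_ms + max(paradigm$onsets) + 350
  n_samp <- ceiling(total_ms * fs / 1000)
  rec <- matrix(0, n_sensors, n_samp)
  onsets <- paradigm$onsets + pad_ms
  for (i in seq_along(onsets)) {
    j0 <- round(onsets[i] * fs / 1000) + 1
    tm <- tmpl[[paradigm$labels[i]]]
    rec[, j0 + 0:(ncol(tm) - 1)] <- rec[, j0 + 0:(ncol(tm) - 1)] + tm
  }
  if (noise_sd > 0)
    rec <- rec + with_seed(seed, matrix(stats::rnorm(length(rec), 0, noise_sd),
                                        n_sensors))
  list(record = rec, fs_hz = fs, onsets = onsets, labels = paradigm$labels)
}

#' Run one session through the preprocessing chain
#'
#' Band-pass and downsample, epoch and baseline-correct, reject artifacts,
#' average to per-condition evoked fields, and bundle as reduced-mode
#' fitting data.
#'
#' @param session output of [simulate_session()].
#' @param net,gain template and gain matrix passed to [dcm_data()].
#' @param p2p_threshold peak-to-peak artifact threshold (signal units).
#' @param n_modes SVD modes retained.
#' @param map optional [preproc_response_map()] matching this pipeline,
#'   attached to the returned data so the inversion models the
#'   preprocessing.
#' @return A [dcm_data()] object.
#' @export
preprocess_session <- function(session, net, gain, p2p_threshold = Inf,
                               n_modes = 8, map = NULL) {
  ds <- bandpass_and_downsample(session$record, session$fs_hz)
  ep <- epoch_baseline(ds, session$onsets, session$labels, fs = 200)
  ep <- reject_artifacts(ep, p2p_threshold)
  erf <- average_erf(ep)
  dcm_data(erf$standard, erf$deviant, erf$time, net = net, gain = gain,
           n_modes = n_modes, preproc_map = map)
}

#' Simulate, preprocess and fit a virtual cohort
#'
#' End-to-end driver: draws every control subject (and any virtual
#' patients) from the generative model, simulates both recording sessions,
#' runs the preprocessing chain, performs the two-stage cohort inversion,
#' and tabulates the posterior summaries of the six parameters of interest.
#'
#' @param cohort a [cohort_spec()].
#' @param patients list of [patient_spec()] (each becomes one extra
#'   subject).
#' @param net network template; defaults to [assemble_network()] with a
#'   deviant modulatory gain of 0.3 on every extrinsic edge.
#' @param gain sensor gain matrix; defaults to `sensor_gain(seed =
#'   cohort$seed)`.
#' @param settings a [dcm_settings()] list.
#' @param p2p_threshold artifact-rejection threshold.
#' @param stage1_average `"controls"` (default) to form the stage-2
#'   initialisation from control sessions only, or `"all"`.
#' @return A list of class `"virtual_study"`: `table` (a
#'   [parameter_table()]), `fits`, `truth` (per-session true vectors),
#'   `init`.
#' @export
run_virtual_study <- function(cohort = cohort_spec(), patients = list(),
                              net = NULL, gain = NULL,
                              settings = dcm_settings(),
                              p2p_threshold = Inf,
                              stage1_average = c("controls", "all")) {
  stage1_average <- match.arg(stage1_average)
  if (is.null(net)) net <- cohort_network()
  if (is.null(gain)) gain <- sensor_gain(seed = cohort$seed + 1)
  n_sub <- cohort$n_controls + length(patients)
  subjects <- lapply(seq_len(n_sub), function(i) {
    s <- sample_subject(cohort, i)
    if (i > cohort$n_controls) s <- make_patient(s, patients[[i - cohort$n_controls]])
    s
  })
  map <- preproc_response_map(fs_raw = 400, iti = cohort$paradigm$iti)
  sessions <- list(); meta <- list(); truth <- list()
  for (s in subjects) {
    for (k in seq_along(s$sessions)) {
      par <- generate_paradigm(cohort$paradigm,
                               seed = cohort$seed * 1000L + 7L * s$subject + 500L + k)
      ses <- simulate_session(s$sessions[[k]], par, net, gain,
                              noise_sd = cohort$noise_sd,
                              seed = cohort$seed * 1000L + 7L * s$subject + 800L + k)
      sessions[[length(sessions) + 1]] <-
        preprocess_session(ses, net, gain, p2p_threshold = p2p_threshold,
                           map = map)
      meta[[length(meta) + 1]] <-
        list(subject = s$subject, session = k,
             group = if (is.null(s$patient)) "control" else "patient")
      truth[[length(truth) + 1]] <- s$sessions[[k]]
    }
  }
  priors <- dcm_priors(net)
  avg_idx <- if (stage1_average == "controls")
    which(vapply(meta, `[[`, "", "group") == "control") else NULL
  coh <- cohort_two_stage_fit(sessions, priors, settings, average_over = avg_idx)
  tab <- parameter_table(coh$fits, meta)
  structure(list(table = tab, fits = coh$fits, stage1 = coh$stage1,
                 init = coh$init, truth = truth, meta = meta, net = net,
                 gain = gain),
            class = "virtual_study")
}

#' @rdname run_virtual_study
#' @param modulation deviant log-gain applied to every extrinsic edge of the
#'   default template.
#' @export
cohort_network <- function(modulation = 0.3) {
  net <- assemble_network()
  net$forward <- lapply(net$forward, function(e) { e$modulation <- modulation; e })
  net$backward <- lapply(net$backward, function(e) { e$modulation <- modulation; e })
  net
}
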