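#' Band-pass filter and downsample a continuous recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass between 0.5 and 30 Hz
#' followed by decimation to the target rate. The 30 Hz low-pass edge sits
#' well below the post-decimation Nyquist frequency, so the band-pass itself
#' provides the anti-alias protection.
#'
#' @param raw sensors-by-time matrix.
#' @param rate_in input sampling rate, Hz (an integer multiple of
#'   `rate_out`, and at least twice the upper band edge).
#' @param band band edges in Hz.
#' @param rate_out output rate, Hz (default 200).
#' @param order Butterworth order (per pass).
#' @return sensors-by-time matrix at `rate_out`, with attribute `fs_hz`.
#' @export
bandpass_and_downsample <- function(raw, rate_in, band = c(0.5, 30),
                                    rate_out = 200, order = 4) {
  if (rate_in < 2 * band[2])
    stop("input rate must be at least twice the upper band edge", call. = FALSE)
  k <- rate_in / rate_out
  if (abs(k - round(k)) > 1e-9)
    stop("rate_in must be an integer multiple of rate_out", call. = FALSE)
  bf <- signal::butter(order, band / (rate_in / 2), type = "pass")
  filt <- t(apply(raw, 1, function(x) signal::filtfilt(bf, x)))
  out <- filt[, seq(1, ncol(filt), by = round(k)), drop = FALSE]
  attr(out, "fs_hz") <- rate_out
  out
}

#' Epoch and baseline-correct a continuous recording
#'
#' Cuts fixed peristimulus windows around each event onset and subtracts the
#' per-trial, per-sensor mean over the baseline interval. Windows are closed
#' on the left and half-open on the right: at 200 Hz the -100..350 ms epoch
#' holds exactly 90 samples. Trials whose window falls outside the recording
#' are dropped with a warning.
#'
#' @param cont sensors-by-time matrix.
#' @param onsets event onsets in ms from the start of the recording.
#' @param labels condition label per onset (`"standard"` or `"deviant"`).
#' @param fs sampling rate, Hz.
#' @param window peristimulus window, ms.
#' @param baseline baseline interval, ms.
#' @return An object of class `"epoched_data"`: `trials`
#'   (trials x sensors x samples), `labels`, `fs_hz`, `time` (ms).
#' @export
epoch_baseline <- function(cont, onsets, labels, fs = 200,
                           window = c(-100, 350), baseline = c(-100, 0)) {
  stopifnot(length(onsets) == length(labels))
  step <- 1000 / fs
  rel <- seq(window[1], window[2] - step, by = step)
  n_samp <- length(rel)
  base_idx <- which(rel >= baseline[1] & rel < baseline[2])
  start_idx <- round(onsets * fs / 1000) + 1 + round(window[1] * fs / 1000)
  ok <- start_idx >= 1 & (start_idx + n_samp - 1) <= ncol(cont)
  if (!all(ok))
    warning(sum(!ok), " trial(s) dropped: epoch window outside recording",
            call. = FALSE)
  keep <- which(ok)
  trials <- array(NA_real_, c(length(keep), nrow(cont), n_samp))
  for (i in seq_along(keep)) {
    seg <- cont[, start_idx[keep[i]] + 0:(n_samp - 1), drop = FALSE]
    seg <- seg - rowMeans(seg[, base_idx, drop = FALSE])
    trials[i, , ] <- seg
  }
  structure(list(trials = trials, labels = labels[keep], fs_hz = fs,
                 time = rel, window = window),
            class = "epoched_data")
}

#' Reject high-amplitude trials
#'
#' Removes trials whose maximum-over-sensors peak-to-peak amplitude exceeds
#' the threshold; trial order is preserved. The threshold is expressed in
#' the data's own signal units.
#'
#' @param ep an [epoch_baseline()] object.
#' @param threshold positive peak-to-peak rejection threshold.
#' @return The filtered `"epoched_data"`, with attribute `n_rejected`.
#' @export
reject_artifacts <- function(ep, threshold) {
  if (!is.finite(threshold) && !is.infinite(threshold))
    stop("threshold must be numeric", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  p2p <- apply(ep$trials, 1, function(tr) max(apply(tr, 1, function(x) diff(range(x)))))
  keep <- which(p2p <= threshold)
  if (!length(keep)) stop("all trials rejected", call. = FALSE)
  out <- ep
  out$trials <- ep$trials[keep, , , drop = FALSE]
  out$labels <- ep$labels[keep]
  attr(out, "n_rejected") <- length(p2p) - length(keep)
  out
}

#' Average epochs into per-condition evoked fields
#'
#' @param ep an [epoch_baseline()] object.
#' @return A list of class `"erf_set"` with one sensors-by-time matrix per
#'   condition plus the shared `time` vector (ms).
#' @export
average_erf <- function(ep) {
  conds <- unique(ep$labels)
  if (!length(conds)) stop("no trials to average", call. = FALSE)
  out <- lapply(conds, function(cc) {
    idx <- which(ep$labels == cc)
    m <- apply(ep$trials[idx, , , drop = FALSE], c(2, 3), mean)
    m
  })
  names(out) <- conds
  structure(c(out, list(time = ep$time, fs_hz = ep$fs_hz)), class = "erf_set")
}

#' Remove the first discrete-cosine component (temporal mean)
#'
#' The first DCT basis function is constant, so removing it mean-corrects
#' each sensor over time. Idempotent.
#'
#' @param erf sensors-by-time matrix.
#' @return The mean-corrected matrix.
#' @export
dct_detrend <- function(erf) {
  erf - rowMeans(erf)
}

#' Project onto principal SVD modes
#'
#' Computes the singular value decomposition of the (condition-concatenated)
#' sensors-by-time matrix and returns the projection onto the leading
#' `n_modes` left-singular vectors, the maximal-variance rank-`n_modes`
#' orthogonal projection of the data covariance.
#'
#' @param X sensors-by-time data matrix.
#' @param n_modes number of modes retained (default 8; at most the sensor
#'   count).
#' @return A list: `projection` (`n_modes` by sensors), `reduced`
#'   (`n_modes` by time), `var_retained` (percent).
#' @export
svd_reduce <- function(X, n_modes = 8) {
  if (n_modes > nrow(X))
    stop("n_modes exceeds the number of sensors", call. = FALSE)
  sv <- svd(X, nu = n_modes, nv = 0)
  P <- t(sv$u)
  list(projection = P, reduced = P %*% X,
       var_retained = 100 * sum(sv$d[seq_len(n_modes)]^2) / sum(sv$d^2))
}

#' Linear observation map of the preprocessing chain
#'
#' The whole sensor-level chain applied to a periodic trial sequence -
#' zero-phase band-pass at the raw rate, decimation, epoching and baseline
#' correction - is linear and time-invariant, so its effect on an evoked
#' template can be precomputed as a pair of matrices: `Mc` maps a trial's
#' own template to its preprocessed epoch, and `Mn` maps the (standard)
#' template of the neighbouring trials to the tails they leak into that
#' epoch through the filter. Model predictions multiplied by these maps are
#' then directly comparable to pipeline-preprocessed data.
#'
#' @param fs_raw raw sampling rate, Hz.
#' @param fs_out epoched rate, Hz.
#' @param band band-pass edges, Hz.
#' @param order Butterworth order.
#' @param iti inter-trial interval, ms.
#' @param template_ms duration of the evoked template, ms (from stimulus
#'   onset).
#' @param window epoch window, ms.
#' @param baseline baseline-correction interval, ms.
#' @param n_slots trials represented on each side of the centre trial.
#' @return A list of class `"preproc_map"` with `Mc`, `Mn` (epoch samples by
#'   template samples), the template time grid `template_time`, and the
#'   epoch grid `time`.
#' @export
preproc_response_map <- function(fs_raw = 400, fs_out = 200, band = c(0.5, 30),
                                 order = 4, iti = 1100, template_ms = 350,
                                 window = c(-100, 350), baseline = c(-100, 0),
                                 n_slots = 4) {
  dt_raw <- 1000 / fs_raw
  tmpl_time <- seq(0, template_ms - dt_raw, by = dt_raw)
  n_t <- length(tmpl_time)
  slots <- (-n_slots):n_slots
  pad <- 1000
  onset_ms <- (slots - min(slots)) * iti + pad
  center <- which(slots == 0)
  total <- max(onset_ms) + template_ms + pad
  n_raw <- ceiling(total * fs_raw / 1000)
  bf <- signal::butter(order, band / (fs_raw / 2), type = "pass")
  k <- fs_raw / fs_out
  step_out <- 1000 / fs_out
  rel <- seq(window[1], window[2] - step_out, by = step_out)
  base_idx <- which(rel >= baseline[1] & rel < baseline[2])
  epoch_of <- function(x) {
    ds <- x[seq(1, length(x), by = k)]
    i0 <- round(onset_ms[center] * fs_out / 1000) + 1 + round(window[1] * fs_out / 1000)
    ep <- ds[i0 + seq_along(rel) - 1]
    ep - mean(ep[base_idx])
  }
  col_for <- function(i, which_slots) {
    x <- numeric(n_raw)
    for (s in which_slots) {
      j0 <- round(onset_ms[s] * fs_raw / 1000) + 1
      x[j0 + i - 1] <- x[j0 + i - 1] + 1
    }
    epoch_of(signal::filtfilt(bf, x))
  }
  Mc <- vapply(seq_len(n_t), col_for, numeric(length(rel)),
               which_slots = center)
  Mn <- vapply(seq_len(n_t), col_for, numeric(length(rel)),
               which_slots = setdiff(seq_along(slots), center))
  structure(list(Mc = Mc, Mn = Mn, template_time = tmpl_time, time = rel,
                 fs_raw = fs_raw, fs_out = fs_out, band = band, order = order,
                 iti = iti),
            class = "preproc_map")
}
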