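# EOD detection: baseline removal by running-median subtraction, peak picking
# on the squared signal with a refractory minimum distance, cross-channel
# merging, and 31-sample waveform extraction with polarity canonicalization.

#' Detection configuration
#'
#' @param threshold_V detection threshold in original amplitude units (volts);
#'   applied as `threshold_V^2` on the squared trace. Default 5 mV, set from
#'   the ~0.2 mV RMS noise floor of tank recordings.
#' @param min_dist_us minimum spacing between accepted peaks (us).
#' @param window_us extraction half-window (us): at 50 kHz, +/-300 us gives
#'   15 samples either side of the peak, i.e. 31-sample waveforms.
#' @param baseline_kernel_ms running-median kernel for baseline removal (ms);
#'   must greatly exceed the 200-400 us pulse width so pulses survive.
#' @param merge_tol_us cross-channel coincidence tolerance (us): detections on
#'   both channels within this window are one physical pulse, and only the
#'   higher-amplitude channel is kept.
#' @param noise_rms_mV recorded noise floor (metadata only; the threshold is
#'   not adaptive).
#' @return `detection_config` list.
#' @export
detection_config <- function(threshold_V = 0.005, min_dist_us = 400,
                             window_us = 300, baseline_kernel_ms = 5,
                             merge_tol_us = 200, noise_rms_mV = 0.2) {
  if (threshold_V <= 0) stop("threshold_V must be positive")
  if (2 * window_us < 400)
    stop("window_us too small: the +/- window must span a 200-400 us pulse")
  structure(list(threshold_V = threshold_V, min_dist_us = min_dist_us,
                 window_us = window_us, baseline_kernel_ms = baseline_kernel_ms,
                 merge_tol_us = merge_tol_us, noise_rms_mV = noise_rms_mV),
            class = "detection_config")
}

#' Remove baseline drift by running-median subtraction
#'
#' The per-channel signal isoline is approximated by a running median and
#' subtracted, so slow drift (electrode polarization, movement artefacts) is
#' removed while the much shorter EOD pulses pass through. A pure DC offset
#' maps to zero.
#'
#' @param recording an [eod_recording()].
#' @param baseline_kernel_ms kernel length in ms; the sample count is forced
#'   odd. Must be at least 3x the 400 us maximum pulse width.
#' @return baseline-corrected [eod_recording()].
#' @export
remove_baseline <- function(recording, baseline_kernel_ms = 5) {
  stopifnot(inherits(recording, "eod_recording"))
  k <- round(baseline_kernel_ms * 1e-3 * recording$fs)
  if (k %% 2 == 0) k <- k + 1L
  if (k * 1e3 / recording$fs < 3 * 0.4)
    stop("baseline kernel shorter than 3x the maximum pulse width; ",
         "it would erase pulses")
  x <- recording$samples
  for (ch in 1:2) x[, ch] <- x[, ch] - stats::runmed(x[, ch], k,
                                                     endrule = "median")
  eod_recording(x, recording$fs, recording$meta)
}

# Local maxima of x above `thr`, greedily accepted in decreasing height with a
# refractory suppression of min_dist samples (MATLAB findpeaks semantics with
# MinPeakDistance). Returns sample indices (1-based).
find_peaks_mindist <- function(x, thr, min_dist) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                  x[2:(n - 1)] > thr) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(n)
  blocked <- logical(n)
  for (i in cand) {
    if (blocked[i]) next
    keep[i] <- TRUE
    lo <- max(1L, i - min_dist); hi <- min(n, i + min_dist)
    blocked[lo:hi] <- TRUE
  }
  sort(which(keep))
}

#' Detect EODs on a baseline-corrected recording
#'
#' The signal is squared to enhance the peak and make detection insensitive to
#' pulse polarity (the EOD polarity depends on the fish's orientation relative
#' to the electrodes). Per channel, peaks of the squared trace above
#' `threshold_V^2` with spacing >= `min_dist_us` are found; detections
#' coincident across channels within `merge_tol_us` are merged and assigned to
#' the channel with the larger amplitude; a final refractory pass at
#' `min_dist_us` collapses residual near-coincident detections (overlapping
#' pulses from the two fish yield a single event).
#'
#' @param recording a baseline-corrected [eod_recording()].
#' @param config a [detection_config()].
#' @return event data.frame (`t_s`, `channel`, `peak_amp_V`, `label`,
#'   `truth`), sorted by time.
#' @export
detect_eods <- function(recording, config = detection_config()) {
  stopifnot(inherits(recording, "eod_recording"))
  fs <- recording$fs
  min_dist <- round(config$min_dist_us * 1e-6 * fs)
  if (min_dist < 2)
    stop("sampling rate too low to honour min_dist_us (< 2 samples)")
  thr2 <- config$threshold_V^2
  hits <- list()
  for (ch in 1:2) {
    idx <- find_peaks_mindist(recording$samples[, ch]^2, thr2, min_dist)
    if (length(idx))
      hits[[ch]] <- data.frame(idx = idx, channel = ch - 1L,
                               amp = recording$samples[idx, ch])
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits))
    return(eod_events(numeric(0), integer(0), numeric(0)))
  # greedy cross-channel merge then global refractory pass, by amplitude
  min_dist_keep <- max(round(config$min_dist_us * 1e-6 * fs), 1)
  ord <- order(abs(hits$amp), decreasing = TRUE)
  kept_idx <- numeric(0)
  kept_rows <- integer(0)
  for (r in ord) {
    i <- hits$idx[r]
    # within merge_tol: same physical pulse on the other channel; within
    # min_dist: refractory collapse of overlapping pulses — either way the
    # larger-amplitude detection (processed first) wins
    if (length(kept_idx) && any(abs(kept_idx - i) < min_dist_keep)) next
    kept_idx <- c(kept_idx, i)
    kept_rows <- c(kept_rows, r)
  }
  kept <- hits[kept_rows[order(hits$idx[kept_rows])], ]
  eod_events(t_s = (kept$idx - 1) / fs, channel = kept$channel,
             peak_amp_V = kept$amp)
}

#' Extract normalized EOD waveforms
#'
#' For each event, `window_us` before and after the absolute-maximum sample is
#' taken from the winning channel (31 samples at 50 kHz with the 300 us
#' default). Each snippet is normalized by its absolute maximum, and snippets
#' whose extremum is negative are polarity-flipped so every stored waveform
#' has a positive extremum. Events closer than one window to a recording edge
#' are dropped with a warning (a partial window would corrupt normalization).
#'
#' @param recording baseline-corrected [eod_recording()].
#' @param events event table from [detect_eods()].
#' @param config a [detection_config()].
#' @return n x L matrix (L = `2*round(window_us*fs/1e6) + 1`) with the
#'   retained events as `attr(, "events")` and the sampling rate as
#'   `attr(, "fs")`.
#' @export
extract_waveforms <- function(recording, events, config = detection_config()) {
  stopifnot(inherits(recording, "eod_recording"))
  fs <- recording$fs
  half <- round(config$window_us * 1e-6 * fs)
  n <- nrow(recording$samples)
  idx <- round(events$t_s * fs) + 1L
  if (any(idx < 1 | idx > n)) stop("event index out of recording range")
  ok <- idx > half & idx <= n - half
  if (any(!ok))
    warning(sum(!ok), " event(s) within one window of a recording edge dropped")
  idx <- idx[ok]
  events <- events[ok, , drop = FALSE]
  wf <- matrix(0, nrow = length(idx), ncol = 2 * half + 1)
  for (k in seq_along(idx)) {
    y <- recording$samples[(idx[k] - half):(idx[k] + half),
                           events$channel[k] + 1L]
    m <- which.max(abs(y))
    if (y[m] < 0) y <- -y                  # canonical orientation
    wf[k, ] <- y / abs(y[m])
  }
  rownames(events) <- NULL
  attr(wf, "events") <- events
  attr(wf, "fs") <- fs
  wf
}
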