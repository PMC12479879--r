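# Sonification of labeled EOD trains: pulse-wise sinusoid bursts (one audible
# click-tone per discharge, a distinct frequency per fish) and IPI-driven
# frequency modulation (one continuous carrier per fish whose pitch tracks
# the smoothed discharge rate).

#' Sonification configuration
#'
#' All synthesis parameters are exposed; the defaults favour clear auditory
#' discrimination of the two fish and keep every instantaneous frequency well
#' below Nyquist.
#'
#' @param audio_fs_hz output sampling rate.
#' @param f_a_hz,f_b_hz pulse-mode burst frequencies for fish A and B (a
#'   musical fifth apart by default).
#' @param burst_ms pulse-mode burst length (raised-cosine envelope).
#' @param amplitude_mode `"fixed"` or `"from_peak_amp"` (bursts scaled by
#'   |peak amplitude| normalized to the recording maximum, preserving the
#'   amplitude cue of the original EODs).
#' @param carrier_a_hz,carrier_b_hz FM-mode carrier frequencies.
#' @param rate_smoothing_s causal exponential smoothing time constant applied
#'   to the instantaneous discharge rate.
#' @param max_deviation_octaves FM pitch range: octaves of deviation per unit
#'   relative rate change.
#' @return `sonify_config` list.
#' @export
sonify_config <- function(audio_fs_hz = 44100, f_a_hz = 440, f_b_hz = 660,
                          burst_ms = 12, amplitude_mode = c("fixed", "from_peak_amp"),
                          carrier_a_hz = 220, carrier_b_hz = 330,
                          rate_smoothing_s = 0.25, max_deviation_octaves = 1) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (burst_ms * 1e-3 * audio_fs_hz < 8)
    stop("burst_ms too short for the audio sampling rate (< 8 samples)")
  structure(list(audio_fs_hz = audio_fs_hz, f_a_hz = f_a_hz, f_b_hz = f_b_hz,
                 burst_ms = burst_ms, amplitude_mode = amplitude_mode,
                 carrier_a_hz = carrier_a_hz, carrier_b_hz = carrier_b_hz,
                 rate_smoothing_s = rate_smoothing_s,
                 max_deviation_octaves = max_deviation_octaves),
            class = "sonify_config")
}

#' Pulse-wise sonification of a labeled event train
#'
#' Each EOD becomes a brief raised-cosine-enveloped sinusoid burst at its
#' fish's frequency, starting at the event time; overlapping bursts sum; the
#' mix is peak-normalized to 0.9 full scale.
#'
#' @param events labeled event table (`t_s`, `label` with two values,
#'   optionally `peak_amp_V` for `amplitude_mode = "from_peak_amp"`).
#' @param duration_s audio length (s); events must lie within it.
#' @param config a [sonify_config()].
#' @return numeric vector of `duration_s * audio_fs_hz` samples in
#'   \[-0.9, 0.9\].
#' @export
pulsewise_audio <- function(events, duration_s, config = sonify_config()) {
  fs <- config$audio_fs_hz
  n <- round(duration_s * fs)
  if (nrow(events) && (min(events$t_s) < 0 || max(events$t_s) > duration_s))
    stop("event time(s) outside [0, duration_s]")
  audio <- numeric(n)
  if (!nrow(events)) return(audio)
  nb <- round(config$burst_ms * 1e-3 * fs)
  env <- 0.5 * (1 - cos(2 * pi * (0:(nb - 1)) / (nb - 1)))
  freqs <- c(config$f_a_hz, config$f_b_hz)
  fish <- sort(unique(events$label))
  gains <- rep(1, nrow(events))
  if (config$amplitude_mode == "from_peak_amp")
    gains <- abs(events$peak_amp_V) / max(abs(events$peak_amp_V))
  tt <- (0:(nb - 1)) / fs
  for (i in seq_len(nrow(events))) {
    f <- freqs[match(events$label[i], fish)]
    i0 <- round(events$t_s[i] * fs) + 1L
    i1 <- min(n, i0 + nb - 1L)
    if (i0 > n) next
    seg <- 1:(i1 - i0 + 1)
    audio[i0:i1] <- audio[i0:i1] + gains[i] * env[seg] * sin(2 * pi * f * tt[seg])
  }
  peak <- max(abs(audio))
  if (peak > 0) audio <- audio * 0.9 / peak
  audio
}

#' Smoothed instantaneous discharge rate of one event train
#'
#' The raw rate is the piecewise-constant 1/IPI between consecutive events
#' (zero before the first event and after the last); it is smoothed with a
#' causal exponential window of time constant `smoothing_s`, and forced to
#' zero from 2 s after the last event.
#'
#' @param event_times sorted event times (s).
#' @param smoothing_s exponential time constant (s).
#' @param duration_s signal length (s).
#' @param fs output sampling rate (Hz).
#' @return numeric vector of `duration_s * fs` rate samples (Hz).
#' @export
instantaneous_rate <- function(event_times, smoothing_s, duration_s,
                               fs = 44100) {
  if (is.unsorted(event_times)) stop("event times must be sorted")
  n <- round(duration_s * fs)
  t <- (0:(n - 1)) / fs
  raw <- numeric(n)
  if (length(event_times) >= 2) {
    ipi <- diff(event_times)
    seg <- findInterval(t, event_times)       # 0 before first event
    inside <- seg >= 1 & seg < length(event_times)
    raw[inside] <- 1 / ipi[seg[inside]]
  }
  alpha <- 1 - exp(-1 / (fs * smoothing_s))
  smoothed <- stats::filter(alpha * raw, 1 - alpha, method = "recursive")
  smoothed <- as.numeric(smoothed)
  if (length(event_times))
    smoothed[t > event_times[length(event_times)] + 2] <- 0
  smoothed
}

#' Frequency-modulation sonification of a labeled event train
#'
#' Each fish gets a continuous carrier whose instantaneous frequency is
#' `carrier * 2^(max_deviation_octaves * (rate(t) - r_ref) / r_ref)` with
#' `r_ref` the fish's session-median discharge rate, so equal rate ratios map
#' to equal musical intervals and a constant-rate train sits exactly on its
#' carrier. Phase is accumulated by integration (no discontinuities). The
#' two tones are returned as separate channels.
#'
#' @param events labeled event table (`t_s`, `label` with two values).
#' @param duration_s audio length (s).
#' @param config a [sonify_config()].
#' @param mix return a mono mixdown instead of an n x 2 matrix.
#' @return n x 2 matrix (or length-n vector if `mix`), peak-normalized to
#'   0.9.
#' @export
fm_audio <- function(events, duration_s, config = sonify_config(),
                     mix = FALSE) {
  fs <- config$audio_fs_hz
  n <- round(duration_s * fs)
  carriers <- c(config$carrier_a_hz, config$carrier_b_hz)
  fish <- sort(unique(events$label))
  out <- matrix(0, nrow = n, ncol = 2)
  for (k in seq_along(fish)) {
    times <- events$t_s[events$label == fish[k]]
    rate <- instantaneous_rate(sort(times), config$rate_smoothing_s,
                               duration_s, fs)
    pos <- rate[rate > 0]
    r_ref <- if (length(pos)) median(pos) else 1
    freq <- carriers[k] *
      2^(config$max_deviation_octaves * (rate - r_ref) / r_ref)
    fmax <- max(freq)
    if (fmax >= fs / 2)
      stop("instantaneous frequency ", round(fmax), " Hz reaches Nyquist; ",
           "reduce max_deviation_octaves or the carrier")
    phase <- 2 * pi * cumsum(freq) / fs
    out[, k] <- sin(phase)
  }
  peak <- max(abs(out))
  if (peak > 0) out <- out * 0.9 / peak
  if (mix) rowMeans(out) else out
}
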