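# EOD feature representations: time-domain waveform, one-sided FFT magnitude
# spectrum, and the analytic generalized Morse-wavelet scalogram used by the
# separation pipeline.

#' Morse wavelet / scalogram parameters
#'
#' The generalized Morse wavelet is parameterized by the symmetry parameter
#' `gamma` and the time-bandwidth product `p2` (so beta = `p2 / gamma`);
#' `gamma = 3, p2 = 60` gives the symmetric, Airy-like member with a good
#' time/frequency resolution trade-off for 200-400 us biphasic pulses. The
#' scale grid is logarithmic with `voices_per_octave` scales per octave over
#' `[freq_lo_hz, freq_hi_hz]` (default 1-25 kHz: 56 scales, spanning the
#' energy of the pulses up to Nyquist at 50 kHz).
#'
#' @param gamma Morse symmetry parameter (> 0).
#' @param p2 time-bandwidth product P^2 (> 0).
#' @param voices_per_octave scales per octave (>= 1).
#' @param pad zeros appended on each side of the waveform before the CWT
#'   (higher frequency resolution, no boundary effects on the retained
#'   columns).
#' @param freq_lo_hz,freq_hi_hz analyzed pseudo-frequency band.
#' @return `morse_params` list.
#' @export
morse_params <- function(gamma = 3, p2 = 60, voices_per_octave = 12,
                         pad = 15, freq_lo_hz = 1000, freq_hi_hz = 25000) {
  if (gamma <= 0 || p2 <= 0) stop("gamma and p2 must be positive")
  if (voices_per_octave < 1) stop("voices_per_octave must be >= 1")
  if (freq_lo_hz >= freq_hi_hz) stop("freq_lo_hz must be < freq_hi_hz")
  structure(list(gamma = gamma, p2 = p2,
                 voices_per_octave = voices_per_octave, pad = pad,
                 freq_lo_hz = freq_lo_hz, freq_hi_hz = freq_hi_hz),
            class = "morse_params")
}

# Pseudo-frequency grid: freq_lo * 2^(k / voices), truncated at freq_hi.
morse_freq_grid <- function(params) {
  n_oct <- log2(params$freq_hi_hz / params$freq_lo_hz)
  k <- 0:floor(n_oct * params$voices_per_octave)
  params$freq_lo_hz * 2^(k / params$voices_per_octave)
}

#' Morse-wavelet scalogram of one EOD waveform
#'
#' The waveform is zero-padded (`pad` zeros each side, 31 -> 61 samples), the
#' analytic Morse CWT is evaluated in the frequency domain on the logarithmic
#' scale grid, magnitudes are cropped back to the central 31 columns and the
#' whole matrix is divided by its maximum coefficient.
#'
#' Each scale's frequency response is the Morse window `(w/wc)^beta *
#' exp(-beta/gamma ((w/wc)^gamma - 1))` (unit peak at the scale's centre
#' frequency `wc`), supported on positive frequencies only, so the transform
#' is analytic and its magnitude is insensitive to waveform polarity.
#'
#' @param waveform numeric vector (length 31 at the 50 kHz / 300 us default).
#' @param params a [morse_params()].
#' @param fs sampling rate (Hz).
#' @return `eod_scalogram`: list with `coeffs` (S x length(waveform) magnitude
#'   matrix, max 1) and `freqs_hz` (pseudo-frequency per row).
#' @export
morse_scalogram <- function(waveform, params = morse_params(), fs = 50000) {
  bank <- morse_filter_bank(params, fs,
                            length(waveform) + 2 * params$pad)
  coeffs <- morse_cwt_mag(as.numeric(waveform), bank, params$pad)
  structure(list(coeffs = coeffs / max(coeffs), freqs_hz = bank$freqs),
            class = "eod_scalogram")
}

# Frequency-domain Morse filter bank: n x S matrix of unit-peak windows, one
# column per scale, positive frequencies only (analytic transform).
morse_filter_bank <- function(params, fs, n) {
  if (params$freq_hi_hz > fs / 2)
    stop("freq_hi_hz exceeds the Nyquist frequency fs/2")
  beta <- params$p2 / params$gamma
  freqs <- morse_freq_grid(params)
  w <- 2 * pi * (0:(n - 1)) / n          # digital angular frequency
  pos <- w > 0 & w <= pi
  H <- matrix(0, nrow = n, ncol = length(freqs))
  for (s in seq_along(freqs)) {
    r <- w[pos] / (2 * pi * freqs[s] / fs)
    H[pos, s] <- exp(beta * log(r) -
                       beta / params$gamma * (r^params$gamma - 1))
  }
  list(H = H, freqs = freqs, n = n)
}

# CWT magnitudes for one waveform against a precomputed bank; returns the
# S x L matrix cropped back to the unpadded columns, unnormalized.
morse_cwt_mag <- function(waveform, bank, pad) {
  x <- c(rep(0, pad), waveform, rep(0, pad))
  stopifnot(length(x) == bank$n)
  X <- fft(x)
  W <- stats::mvfft(bank$H * X, inverse = TRUE) / bank$n
  keep <- (pad + 1):(bank$n - pad)
  t(Mod(W))[, keep, drop = FALSE]
}

#' One-sided FFT magnitude spectrum of one EOD waveform
#'
#' The 31-sample waveform is zero-padded to 64 samples; the one-sided
#' magnitude spectrum (33 bins, DC to Nyquist) is normalized by its maximum.
#'
#' @param waveform numeric vector of length 31.
#' @param nfft FFT length after zero-padding.
#' @return numeric vector of `nfft/2 + 1` normalized magnitudes.
#' @export
fft_spectrum <- function(waveform, nfft = 64) {
  x <- as.numeric(waveform)
  if (all(x == 0)) stop("all-zero waveform has no spectrum")
  x <- c(x, rep(0, nfft - length(x)))
  mag <- Mod(fft(x))[1:(nfft / 2 + 1)]
  mag / max(mag)
}

#' Assemble an n x d feature matrix from extracted waveforms
#'
#' @param waveforms n x L waveform matrix from [extract_waveforms()].
#' @param domain `"time"` (raw waveform rows), `"frequency"` (normalized FFT
#'   spectra) or `"timefreq"` (row-major flattened Morse scalograms,
#'   d = S x L).
#' @param params a [morse_params()] (timefreq domain).
#' @param fs sampling rate (Hz); defaults to `attr(waveforms, "fs")`.
#' @return n x d numeric matrix; row order preserves event order.
#' @export
feature_matrix <- function(waveforms, domain = c("timefreq", "time", "frequency"),
                           params = morse_params(),
                           fs = attr(waveforms, "fs")) {
  domain <- match.arg(domain)
  waveforms <- as.matrix(waveforms)
  if (!nrow(waveforms)) stop("no waveforms to featurize")
  if (is.null(fs)) fs <- 50000
  switch(domain,
    time = {
      out <- waveforms
      attributes(out) <- list(dim = dim(waveforms))
      out
    },
    frequency = t(apply(waveforms, 1, fft_spectrum)),
    timefreq = {
      bank <- morse_filter_bank(params, fs, ncol(waveforms) + 2 * params$pad)
      d <- length(bank$freqs) * ncol(waveforms)
      out <- matrix(0, nrow = nrow(waveforms), ncol = d)
      for (i in seq_len(nrow(waveforms))) {
        sc <- morse_cwt_mag(waveforms[i, ], bank, params$pad)
        out[i, ] <- as.numeric(t(sc)) / max(sc)
      }
      out
    })
}
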