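# Small synthetic inputs built in code for the tests.

# Recording with biphasic pulses planted at given times/amplitudes/channels.
plant_recording <- function(times_s, amps_V, channels = 0L, fs = 50000,
                            duration_s = max(times_s) + 0.01,
                            model = make_fish(1, 0)) {
  n <- round(duration_s * fs)
  x <- matrix(0, n, 2)
  channels <- rep_len(channels, length(times_s))
  amps_V <- rep_len(amps_V, length(times_s))
  tpk <- eodsep:::pulse_peak_time(model)
  dur <- (model$tau1_us + model$tau2_us) * 1e-6
  for (k in seq_along(times_s)) {
    # place so the pulse's absolute maximum lands on the sample at times_s[k]
    onset <- times_s[k] - tpk
    i0 <- max(1L, floor(onset * fs) + 1L)
    i1 <- min(n, i0 + ceiling(dur * fs) + 1L)
    tt <- ((i0:i1) - 1) / fs - onset
    x[i0:i1, channels[k] + 1L] <- x[i0:i1, channels[k] + 1L] +
      amps_V[k] * eodsep:::pulse_value(model, tt)
  }
  eod_recording(x, fs)
}

# Sample index (1-based) of each planted pulse's absolute maximum.
planted_peak_index <- function(times_s, fs = 50000, model = make_fish(1, 0)) {
  vapply(times_s, function(t0) {
    onset <- t0 - eodsep:::pulse_peak_time(model)
    i0 <- floor(onset * fs) + 1L
    dur <- (model$tau1_us + model$tau2_us) * 1e-6
    tt <- ((i0:(i0 + ceiling(dur * fs) + 1L)) - 1) / fs - onset
    i0 + which.max(abs(eodsep:::pulse_value(model, tt))) - 1
  }, numeric(1))
}

# n normalized 31-sample waveforms of one fish with sub-sample phase jitter
# and additive noise, mimicking extract_waveforms output.
fish_waveforms <- function(model, n, noise_sd = 0.02, seed = 1, fs = 50000) {
  eodsep:::with_seed(seed, {
    tpk <- eodsep:::pulse_peak_time(model)
    wf <- t(vapply(seq_len(n), function(i) {
      off <- runif(1)
      y <- eodsep:::pulse_value(model, tpk + ((-15:15) + off) / fs) +
        rnorm(31, sd = noise_sd)
      m <- which.max(abs(y))
      if (y[m] < 0) y <- -y
      y / abs(y[m])
    }, numeric(31)))
    attr(wf, "fs") <- fs
    wf
  })
}
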