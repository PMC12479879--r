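labeled_events <- function(t_s, label, amp = 0.01) {
  eod_events(t_s, 0L, amp, label = label)
}

test_that("pulse-wise audio is silent without events and local to bursts", {
  cfg <- sonify_config()
  silent <- pulsewise_audio(labeled_events(numeric(0), character(0)), 1, cfg)
  expect_equal(length(silent), 44100)
  expect_true(all(silent == 0))

  one <- pulsewise_audio(labeled_events(1, "A"), 2, cfg)
  expect_equal(length(one), 2 * 44100)
  support <- which(one != 0)
  expect_gte(min(support) / 44100, 1 - 1e-6)
  expect_lte(max(support) / 44100, 1 + cfg$burst_ms * 1e-3 + 1e-6)
  expect_equal(max(abs(one)), 0.9)

  expect_error(pulsewise_audio(labeled_events(3, "A"), 2, cfg), "outside")
})

test_that("each burst carries its fish's frequency", {
  cfg <- sonify_config()
  ev <- labeled_events(c(0.2, 0.5, 0.8), c("A", "B", "A"))
  audio <- pulsewise_audio(ev, 1, cfg)
  nb <- round(cfg$burst_ms * 1e-3 * cfg$audio_fs_hz)
  for (i in 1:3) {
    i0 <- round(ev$t_s[i] * cfg$audio_fs_hz) + 1
    seg <- audio[i0:(i0 + nb - 1)]
    spec <- Mod(fft(c(seg, rep(0, 4096 - nb))))[1:2048]
    f_hat <- (which.max(spec) - 1) * cfg$audio_fs_hz / 4096
    f_want <- if (ev$label[i] == "A") cfg$f_a_hz else cfg$f_b_hz
    expect_lt(abs(f_hat - f_want), cfg$audio_fs_hz / 4096 + 1e-9)
  }
})

test_that("burst count recovered from the envelope equals the event count", {
  cfg <- sonify_config()
  times <- seq(0.1, 1.9, by = 0.1)
  audio <- pulsewise_audio(labeled_events(times, rep_len(c("A", "B"), length(times))), 2, cfg)
  env <- abs(audio) > 1e-6
  onsets <- sum(diff(c(FALSE, env)) == 1)
  expect_equal(onsets, length(times))
})

test_that("smoothed rate follows the closed-form exponential step response", {
  tau <- 0.25
  times <- seq(1, 9, by = 0.1)          # regular 10 Hz train from t = 1 s
  fs <- 8000
  r <- instantaneous_rate(times, tau, 10, fs = fs)
  t <- (0:(length(r) - 1)) / fs
  inside <- t > 1 & t < 9
  closed <- 10 * (1 - exp(-(t - 1) / tau))
  expect_lt(max(abs(r - closed)[inside]), 0.15)   # discrete EMA vs continuous
  at <- function(x) r[round(x * fs)]
  expect_gt(at(1 + 5 * tau), 10 * 0.99)           # within 1% after 5 tau
  expect_lt(abs(at(1 + 3 * tau) - 10 * (1 - exp(-3))), 0.15)
  # zero before the first event, forced to zero 2 s after the last
  expect_true(all(r[t < 1] < 1e-6))
  expect_true(all(r[t > times[length(times)] + 2] == 0))
  expect_error(instantaneous_rate(c(2, 1), tau, 3), "sorted")
})

test_that("a single event produces no rate; IPI doubling halves the rate", {
  r <- instantaneous_rate(1, 0.25, 4, fs = 4000)
  expect_true(all(r == 0))
  r1 <- instantaneous_rate(seq(1, 9, by = 0.1), 0.25, 10, fs = 4000)
  r2 <- instantaneous_rate(seq(1, 9, by = 0.2), 0.25, 10, fs = 4000)
  expect_equal(max(r2), max(r1) / 2, tolerance = 0.02)
})

test_that("FM audio sits on the carrier at constant rate and stays continuous", {
  cfg <- sonify_config(rate_smoothing_s = 0.1)
  times <- seq(0.5, 9.5, by = 0.1)
  ev <- labeled_events(times, rep("A", length(times)))
  audio <- fm_audio(ev, 10, cfg)
  expect_equal(dim(audio), c(10 * 44100, 2))
  # steady state: count zero crossings over a late 2 s window
  seg <- audio[(6 * 44100):(8 * 44100), 1]
  f_hat <- sum(diff(sign(seg)) != 0) / 2 / 2
  expect_lt(abs(f_hat - cfg$carrier_a_hz), 2)
  # phase continuity of the synthesized tone
  ph <- analytic_phase(audio[(2 * 44100):(3 * 44100), 1] / 0.9)
  dph <- abs(diff(ph))
  dph <- pmin(dph, 2 * pi - dph)        # unwrap
  dph <- dph[500:(length(dph) - 500)]   # FFT-Hilbert edge artifacts
  f_max <- cfg$carrier_a_hz * 2^cfg$max_deviation_octaves * 1.05
  expect_lt(max(dph), 2 * pi * f_max / 44100)
})

test_that("FM rejects near-Nyquist configurations", {
  cfg <- sonify_config(carrier_a_hz = 2000, max_deviation_octaves = 2,
                       rate_smoothing_s = 0.05)
  # long 10 Hz stretch pins the reference rate, then a 200 Hz burst
  times <- c(seq(0.2, 8, by = 0.1), seq(8.005, 9, by = 0.005))
  ev <- labeled_events(times, rep("A", length(times)))
  expect_error(fm_audio(ev, 9.5, cfg), "Nyquist")
})

test_that("WAV audio writing round-trips and refuses silent clipping", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(numeric(44100), path, 44100)
  w <- read_wav(path)
  expect_equal(nrow(w$samples), 44100)

  x <- sin(2 * pi * 440 * (0:999) / 8000) * 0.5
  x32 <- as.numeric(readBin(writeBin(x, raw(), size = 4), "numeric",
                            length(x), size = 4))
  write_wav(x32, path, 8000, format = "float32")
  expect_identical(as.numeric(read_wav(path)$samples), x32)

  expect_error(write_wav(c(0.5, 1.2), path, 8000, format = "pcm16"), "clip")
  expect_silent(write_wav(c(0.5, 1.2), path, 8000, format = "pcm16",
                          allow_clip = TRUE))
})

test_that("sonifying a shifted train shifts the audio", {
  cfg <- sonify_config()
  ev1 <- labeled_events(c(0.2, 0.4, 0.7), c("A", "B", "A"))
  ev2 <- ev1; ev2$t_s <- ev2$t_s + 0.5
  a1 <- pulsewise_audio(ev1, 1, cfg)
  a2 <- pulsewise_audio(ev2, 1.5, cfg)
  shift <- round(0.5 * cfg$audio_fs_hz)
  expect_equal(a2[(shift + 1):length(a2)], a1[1:(length(a2) - shift)],
               tolerance = 1e-12)
})
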