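# Synthetic dyad simulator.
#
# Generates ground-truth-labelled two-channel recordings with the statistical
# structure the separation method relies on: individual-specific biphasic
# waveforms (~200-400 us), position-dependent per-channel amplitude and
# polarity, stochastic gamma-renewal inter-pulse intervals, slow baseline
# drift and additive white noise.

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Population-centre waveform/IPI parameters and the relative spread reached at
# divergence 1. Centre: 280 us biphasic pulse (43% first phase), second phase
# 70% of the first and inverted, 20 mV source amplitude, gamma(3) IPIs at 8 Hz.
fish_center <- list(tau_total_us = 280, frac1 = 0.43, ratio = -0.7,
                    skew = 0, base_amp_mV = 20, ipi_shape = 3,
                    ipi_mean_s = 0.125)
fish_spread <- c(tau_total_us = 0.30, frac1 = 0.30, ratio = 0.40,
                 skew = 0.60, base_amp_mV = 0.30)

#' Draw an individual fish model
#'
#' Shape parameters are placed at a fixed distance (`divergence`) from the
#' population centre in normalized parameter space, in a seed-determined
#' random direction: `divergence = 0` returns the population-mean waveform for
#' every seed, and two independent fish at the same positive divergence are
#' almost surely distinct.
#'
#' @param seed integer RNG seed; the draw is deterministic given the seed.
#' @param divergence in \[0, 1\]: how far the individual's shape parameters lie
#'   from the population centre.
#' @param ipi_mean_s mean inter-pulse interval (s); rate = 1/`ipi_mean_s`.
#' @param ipi_shape gamma shape of the IPI renewal process (>= 1 gives
#'   refractory-like regularity).
#' @return `fish_model` list: `tau1_us`, `tau2_us`, `ratio`, `skew`,
#'   `base_amp_mV`, `ipi_shape`, `ipi_mean_s`, `seed`.
#' @export
make_fish <- function(seed, divergence, ipi_mean_s = fish_center$ipi_mean_s,
                      ipi_shape = fish_center$ipi_shape) {
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1)
    stop("divergence must lie in [0, 1]")
  if (ipi_mean_s < 0.005)
    stop("ipi_mean_s below 5 ms (discharge rate above 200 Hz)")
  u <- with_seed(seed, {
    z <- rnorm(length(fish_spread))
    if (divergence == 0) z * 0 else z / sqrt(sum(z^2)) * divergence
  })
  names(u) <- names(fish_spread)
  tau_total <- clamp(fish_center$tau_total_us *
                       (1 + fish_spread["tau_total_us"] * u["tau_total_us"]),
                     200, 400)
  frac1 <- clamp(fish_center$frac1 * (1 + fish_spread["frac1"] * u["frac1"]),
                 0.25, 0.65)
  model <- list(
    tau1_us = unname(tau_total * frac1),
    tau2_us = unname(tau_total * (1 - frac1)),
    ratio = unname(clamp(fish_center$ratio *
                           (1 + fish_spread["ratio"] * u["ratio"]),
                         -0.9, -0.25)),
    skew = unname(fish_spread["skew"] * u["skew"]),
    base_amp_mV = unname(max(5, fish_center$base_amp_mV *
                               (1 + fish_spread["base_amp_mV"] * u["base_amp_mV"]))),
    ipi_shape = ipi_shape, ipi_mean_s = ipi_mean_s, seed = seed)
  structure(model, class = "fish_model")
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' @export
print.fish_model <- function(x, ...) {
  cat(sprintf(
    "<fish_model> pulse %.0f+%.0f us, ratio %.2f, skew %.2f, %.1f mV, %.1f Hz\n",
    x$tau1_us, x$tau2_us, x$ratio, x$skew, x$base_amp_mV, 1 / x$ipi_mean_s))
  invisible(x)
}

# Continuous-time biphasic pulse: a positive raised-cosine lobe of width tau1
# followed by a negative lobe of width tau2 scaled by `ratio`; `skew` warps
# time within each lobe. Peak-normalized to 1, exactly zero outside
# [0, tau1 + tau2]. t in seconds.
pulse_value <- function(model, t) {
  tau1 <- model$tau1_us * 1e-6
  tau2 <- model$tau2_us * 1e-6
  warp <- 2^model$skew
  y <- numeric(length(t))
  in1 <- t >= 0 & t < tau1
  in2 <- t >= tau1 & t <= tau1 + tau2
  lobe <- function(u) 0.5 * (1 - cos(2 * pi * u^warp))
  y[in1] <- lobe(t[in1] / tau1)
  y[in2] <- model$ratio * lobe((t[in2] - tau1) / tau2)
  y / max(1, abs(model$ratio))
}

# Time (s, from pulse onset) of the pulse's absolute maximum. The positive
# lobe dominates (|ratio| < 1), peaking where u^warp = 1/2.
pulse_peak_time <- function(model) {
  model$tau1_us * 1e-6 * 0.5^(1 / 2^model$skew)
}

#' Sample a fish's template waveform
#'
#' @param model a [make_fish()] model.
#' @param fs sampling rate (Hz), >= 10 kHz.
#' @return numeric vector covering the pulse support, peak-normalized to 1.
#' @export
template_waveform <- function(model, fs) {
  if (fs < 1e4) stop("fs below 10 kHz undersamples a 200-400 us pulse")
  dur <- (model$tau1_us + model$tau2_us) * 1e-6
  pulse_value(model, seq(0, dur, by = 1 / fs))
}

#' Simulator configuration
#'
#' @param duration_s recording length (s).
#' @param fs_hz sampling rate (Hz), >= 10 kHz.
#' @param noise_rms_mV additive white-noise RMS (mV); the study-condition
#'   default 0.2 mV matches the noise floor of the experimental recordings.
#' @param drift_amp_mV,drift_freq_hz slow sinusoidal baseline drift.
#' @param walk_step step SD of the positional/orientation random walks
#'   (updated at 2 Hz).
#' @param seed RNG seed; the simulation is deterministic given the seed.
#' @return `dyad_sim_config` list.
#' @export
dyad_sim_config <- function(duration_s = 120, fs_hz = 50000,
                            noise_rms_mV = 0.2, drift_amp_mV = 1,
                            drift_freq_hz = 0.2, walk_step = 0.15,
                            seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (fs_hz < 1e4) stop("fs_hz must be >= 10 kHz")
  if (noise_rms_mV < 0) stop("noise_rms_mV must be >= 0")
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 noise_rms_mV = noise_rms_mV, drift_amp_mV = drift_amp_mV,
                 drift_freq_hz = drift_freq_hz, walk_step = walk_step,
                 seed = as.integer(seed)),
            class = "dyad_sim_config")
}

# Gamma-renewal event times on (0, duration); continuous (not sample-aligned).
renewal_times <- function(shape, mean_s, duration_s) {
  n_guess <- ceiling(duration_s / mean_s + 6 * sqrt(duration_s / mean_s + 1)) + 10
  t <- cumsum(rgamma(n_guess, shape = shape, scale = mean_s / shape))
  while (length(t) && t[length(t)] < duration_s) {
    t <- c(t, t[length(t)] +
             cumsum(rgamma(n_guess, shape = shape, scale = mean_s / shape)))
  }
  t[t < duration_s - 0.002]  # keep full pulse support inside the recording
}

# Smooth latent walk sampled at 2 Hz, linearly interpolated at query times.
latent_walk <- function(start, step, duration_s, at) {
  knots <- seq(0, duration_s + 0.5, by = 0.5)
  z <- start + c(0, cumsum(rnorm(length(knots) - 1, sd = step)))
  approx(knots, z, xout = at, rule = 2)$y
}

#' Simulate a two-fish dyad recording
#'
#' Event times per fish come from its gamma-IPI renewal process. Each pulse is
#' the fish's continuous-time template evaluated at the recording's sample
#' grid (event times are not sample-aligned), scaled per channel by a smoothly
#' varying positional gain `g(t)` / `1 - g(t)` (the two electrodes sit at
#' opposite corners) with a sign flip whenever the simulated orientation
#' reverses. White noise and slow sinusoidal drift are added. Truth events
#' carry fish identity and a `collision` flag marking pulses within 400 us of
#' the other fish's pulse.
#'
#' @param fishA,fishB [make_fish()] models; `fishB = NULL` simulates a solo
#'   recording (used for baseline training sessions).
#' @param config a [dyad_sim_config()].
#' @return list with `recording` ([eod_recording()]) and `truth` (event
#'   data.frame with columns `t_s`, `channel`, `peak_amp_V`, `label`, `truth`,
#'   `collision`).
#' @export
simulate_dyad <- function(fishA, fishB, config = dyad_sim_config()) {
  stopifnot(inherits(config, "dyad_sim_config"))
  fs <- config$fs_hz
  n <- round(config$duration_s * fs)
  with_seed(config$seed, {
    x <- matrix(0, nrow = n, ncol = 2)
    truth_list <- list()
    # fish A starts nearer the channel-0 electrode, fish B nearer channel 1
    starts <- c(1, -1)
    fishes <- list(A = fishA, B = fishB)
    fishes <- fishes[!vapply(fishes, is.null, logical(1))]
    for (i in seq_along(fishes)) {
      fish <- fishes[[i]]
      times <- renewal_times(fish$ipi_shape, fish$ipi_mean_s, config$duration_s)
      if (!length(times)) next
      zg <- latent_walk(starts[i], config$walk_step, config$duration_s, times)
      g <- 0.2 + 0.6 / (1 + exp(-zg))                  # channel-0 gain share
      zo <- latent_walk(1, config$walk_step, config$duration_s, times)
      sgn <- ifelse(zo >= 0, 1, -1)                    # orientation polarity
      amp <- fish$base_amp_mV * 1e-3
      dur <- (fish$tau1_us + fish$tau2_us) * 1e-6
      tpk <- pulse_peak_time(fish)
      half <- ceiling(dur * fs) + 1L
      for (k in seq_along(times)) {
        i0 <- max(1L, floor(times[k] * fs) + 1L)
        i1 <- min(n, i0 + half)
        tt <- ((i0:i1) - 1) / fs - times[k]
        p <- pulse_value(fish, tt)
        gains <- c(g[k], 1 - g[k]) * sgn[k] * amp
        x[i0:i1, 1] <- x[i0:i1, 1] + p * gains[1]
        x[i0:i1, 2] <- x[i0:i1, 2] + p * gains[2]
        # truth time: sample index of this pulse's absolute maximum
        kmax <- which.max(abs(p))
        pk <- i0 + kmax - 1L
        ch <- if (abs(gains[1]) >= abs(gains[2])) 0L else 1L
        truth_list[[length(truth_list) + 1L]] <- data.frame(
          t_s = (pk - 1) / fs, channel = ch,
          peak_amp_V = gains[ch + 1L] * p[kmax],
          label = NA_character_, truth = names(fishes)[i],
          stringsAsFactors = FALSE)
      }
    }
    if (!length(truth_list)) {
      truth <- eod_events(numeric(0), integer(0), numeric(0),
                          character(0), character(0),
                          collision = logical(0))
    } else {
      truth <- do.call(rbind, truth_list)
      truth <- truth[order(truth$t_s), , drop = FALSE]
      rownames(truth) <- NULL
      if (nrow(truth) > 1) {
        gap_prev <- c(Inf, diff(truth$t_s))
        gap_next <- c(diff(truth$t_s), Inf)
        other_prev <- c(FALSE, truth$truth[-nrow(truth)] != truth$truth[-1])
        other_next <- c(truth$truth[-nrow(truth)] != truth$truth[-1], FALSE)
        truth$collision <- (gap_prev < 400e-6 & other_prev) |
          (gap_next < 400e-6 & other_next)
      } else truth$collision <- FALSE
    }
    if (config$noise_rms_mV > 0)
      x <- x + rnorm(length(x), sd = config$noise_rms_mV * 1e-3)
    if (config$drift_amp_mV > 0) {
      tgrid <- (seq_len(n) - 1) / fs
      ph <- runif(2, 0, 2 * pi)
      for (ch in 1:2)
        x[, ch] <- x[, ch] + config$drift_amp_mV * 1e-3 *
          sin(2 * pi * config$drift_freq_hz * tgrid + ph[ch])
    }
    list(recording = eod_recording(x, fs,
                                   meta = list(source = "simulate_dyad",
                                               seed = config$seed)),
         truth = truth)
  })
}

#' Perturb a fish model (session-to-session waveform drift)
#'
#' Applies a small multiplicative jitter to the shape parameters, emulating the
#' across-session waveform variability that degrades supervised classifiers
#' trained on an earlier solo session.
#'
#' @param model a [make_fish()] model.
#' @param amount relative jitter SD (e.g. 0.08 for ~8%).
#' @param seed RNG seed.
#' @return a perturbed `fish_model`.
#' @export
perturb_fish <- function(model, amount, seed) {
  with_seed(seed, {
    j <- function(x) x * (1 + rnorm(1, sd = amount))
    model$tau1_us <- clamp(j(model$tau1_us), 50, 350)
    model$tau2_us <- clamp(j(model$tau2_us), 50, 350)
    model$ratio <- clamp(j(model$ratio), -0.9, -0.25)
    model$skew <- model$skew + rnorm(1, sd = amount)
    model
  })
}
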