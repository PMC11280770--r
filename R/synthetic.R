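#' Configuration of a synthetic band-dependent classification task
#'
#' Defines a generatable TFR classification problem in which the
#' class-discriminative signal lives in class-specific frequency
#' sub-bands while a shared high-power nuisance component occupies its own
#' band — the structure radar micro-Doppler data exhibits (a strong
#' torso-like return at low frequency, weak limb-like returns at high
#' frequency; strong breathing vs weak heartbeat components). The
#' nuisance-to-signal power ratio is the knob that makes the task hard for
#' power-biased feature learning.
#'
#' @param n_classes number of classes C.
#' @param samples_per_class samples generated per class.
#' @param tfr_shape integer pair (T, F): time frames and frequency bins.
#' @param class_bands list of C numeric pairs `(center, width)` on the
#'   normalized \[-1, 1\] frequency axis, one per class. Classes sharing a
#'   band are discriminated by their modulation rate inside the band.
#'   Default: evenly spaced bands of width 0.3 in \[0.1, 0.8\].
#' @param nuisance_band numeric pair `(center, width)` of the shared
#'   nuisance component.
#' @param power_ratio_db nuisance-to-signal power ratio in dB (20 means
#'   the nuisance carries 100x the signal power), applied before
#'   standardization.
#' @param noise_sd standard deviation of the additive white noise,
#'   relative to unit nuisance amplitude.
#' @param seed integer seed.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_classes = 4L, samples_per_class = 200L,
                             tfr_shape = c(32L, 64L),
                             class_bands = NULL,
                             nuisance_band = c(-0.5, 0.4),
                             power_ratio_db = 20,
                             noise_sd = 0.1,
                             seed = 1024L) {
  stopifnot(n_classes >= 1L, samples_per_class >= 1L,
            length(tfr_shape) == 2L, all(tfr_shape >= 8L))
  if (is.null(class_bands)) {
    centers <- seq(0.1, 0.8, length.out = n_classes)
    class_bands <- lapply(centers, function(ctr) c(ctr, 0.3))
  }
  stopifnot(length(class_bands) == n_classes)
  for (b in class_bands) {
    stopifnot(length(b) == 2L, b[2L] > 0,
              b[1L] - b[2L] / 2 >= -1, b[1L] + b[2L] / 2 <= 1)
  }
  stopifnot(length(nuisance_band) == 2L, nuisance_band[2L] > 0)
  structure(
    list(n_classes = as.integer(n_classes),
         samples_per_class = as.integer(samples_per_class),
         tfr_shape = as.integer(tfr_shape),
         class_bands = class_bands,
         nuisance_band = nuisance_band,
         power_ratio_db = power_ratio_db,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# A frequency-modulated ridge: at frame t the instantaneous normalized
# frequency swings sinusoidally inside the band; the ridge is a Gaussian
# bump of width width/10 around it, so effectively all of its energy
# (>3 sd) stays inside the configured band. FM (rather than a stationary
# tone) matters: the discriminative pattern is not translation invariant
# along the frequency axis.
.fm_ridge <- function(n_t, freq_axis, center, width, rate, phase = 0,
                      amp_jitter = NULL) {
  bump_sd <- width / 10
  swing <- width / 2 - 3 * bump_sd
  tt <- seq_len(n_t)
  f_t <- center + swing * sin(2 * pi * rate * tt / n_t + phase)
  out <- matrix(0, n_t, length(freq_axis))
  for (t in tt) {
    out[t, ] <- exp(-0.5 * ((freq_axis - f_t[t]) / bump_sd)^2)
  }
  if (!is.null(amp_jitter)) out <- out * amp_jitter
  out
}

# Shared nuisance component: a band-limited blob whose amplitude
# breathes slowly in time, identical in distribution for every class.
.nuisance_component <- function(n_t, freq_axis, band) {
  prof <- exp(-0.5 * ((freq_axis - band[1L]) / (band[2L] / 4))^2)
  amp <- 1 + 0.3 * sin(2 * pi * stats::runif(1) + 2 * pi * seq_len(n_t) / n_t)
  outer(amp, prof)
}

# Scale `signal` so that its total power is `db` decibels below the
# nuisance component's.
.scale_to_db_below <- function(signal, nuisance, db) {
  ps <- sum(signal^2)
  pn <- sum(nuisance^2)
  if (ps == 0) return(signal)
  signal * sqrt(pn / ps * 10^(-db / 10))
}

#' Generate a band-dependent synthetic classification task
#'
#' Each sample is the standardized sum of (a) a shared high-power
#' nuisance component confined to `nuisance_band`, (b) a class-specific
#' frequency-modulated ridge confined to that class's band — classes
#' sharing a band differ in modulation rate — and (c) white noise. Labels
#' are balanced; generation is bit-reproducible under the seed.
#'
#' @param cfg a [synthetic_config()].
#' @return a list of `n_classes * samples_per_class` [tfr_sample()]
#'   objects with integer labels 1..C and synthetic subject identifiers
#'   (round-robin over 10 pseudo-subjects, enabling LOO experiments).
#' @export
gen_band_task <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  n_t <- cfg$tfr_shape[1L]; n_f <- cfg$tfr_shape[2L]
  fax <- normalized_freq_axis(n_f)
  out <- vector("list", cfg$n_classes * cfg$samples_per_class)
  k <- 0L
  for (cl in seq_len(cfg$n_classes)) {
    band <- cfg$class_bands[[cl]]
    for (s in seq_len(cfg$samples_per_class)) {
      nui <- .nuisance_component(n_t, fax, cfg$nuisance_band)
      sig <- .fm_ridge(n_t, fax, band[1L], band[2L],
                       rate = cl, phase = stats::runif(1, 0, 2 * pi))
      sig <- .scale_to_db_below(sig, nui, cfg$power_ratio_db)
      vals <- nui + sig
      if (cfg$noise_sd > 0) {
        vals <- vals + matrix(stats::rnorm(n_t * n_f, sd = cfg$noise_sd),
                              n_t, n_f)
      }
      k <- k + 1L
      out[[k]] <- tfr_sample(standardize(vals), freq_axis = fax, label = cl,
                             subject_id = sprintf("S%02d", (k - 1L) %% 10L + 1L))
    }
  }
  out
}

#' Generate a gait-like synthetic task
#'
#' Emulates the power structure of walking micro-Doppler signatures: a
#' high-power, low-frequency torso-like ridge common to all classes, plus
#' class-dependent low-power, higher-frequency limb-like ridges. The class
#' information lives only in the limb component, whose power sits
#' `power_ratio_db` below the torso's, so a learner biased towards
#' high-power regions sees nearly identical inputs across classes.
#'
#' @param cfg a [synthetic_config()]; `class_bands` is ignored in favour
#'   of `limb_band`.
#' @param torso_band numeric pair `(center, width)` of the shared torso
#'   ridge.
#' @param limb_band numeric pair `(center, width)` of the class-specific
#'   limb ridges.
#' @param limb_amplitude multiplier on the limb component; 0 removes the
#'   class information entirely (classes become indistinguishable).
#' @return a list of [tfr_sample()] objects, labels 1..C, balanced.
#' @export
gen_gait_like <- function(cfg, torso_band = c(0.05, 0.25),
                          limb_band = c(0.55, 0.35), limb_amplitude = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  n_t <- cfg$tfr_shape[1L]; n_f <- cfg$tfr_shape[2L]
  fax <- normalized_freq_axis(n_f)
  out <- vector("list", cfg$n_classes * cfg$samples_per_class)
  k <- 0L
  for (cl in seq_len(cfg$n_classes)) {
    for (s in seq_len(cfg$samples_per_class)) {
      torso <- .fm_ridge(n_t, fax, torso_band[1L], torso_band[2L],
                         rate = 1, phase = stats::runif(1, 0, 2 * pi))
      limb <- .fm_ridge(n_t, fax, limb_band[1L], limb_band[2L],
                        rate = 1 + cl, phase = stats::runif(1, 0, 2 * pi))
      limb <- .scale_to_db_below(limb, torso, cfg$power_ratio_db) *
        limb_amplitude
      vals <- torso + limb
      if (cfg$noise_sd > 0) {
        vals <- vals + matrix(stats::rnorm(n_t * n_f, sd = cfg$noise_sd),
                              n_t, n_f)
      }
      k <- k + 1L
      out[[k]] <- tfr_sample(standardize(vals), freq_axis = fax, label = cl,
                             subject_id = sprintf("S%02d", (k - 1L) %% 10L + 1L))
    }
  }
  out
}

#' Configuration of a simulated vital-sign radar signal
#'
#' Parameters of the standard chest-displacement model for a continuous
#' wave radar: the complex baseband return is a phase-modulated
#' exponential whose phase is the sum of a breathing sinusoid and a
#' heartbeat sinusoid. Breathing must lie in the physiological 0.1-0.9 Hz
#' band and heartbeat in 1-2.5 Hz; breathing moves the chest much more
#' than the heartbeat, so its modulation amplitude is larger by
#' `amplitude_ratio`.
#'
#' @param fs sampling rate in Hz.
#' @param duration signal duration in seconds.
#' @param breathing_hz breathing rate in \[0.1, 0.9\] Hz.
#' @param heartbeat_hz heartbeat rate in \[1, 2.5\] Hz.
#' @param amplitude_ratio breathing-to-heartbeat displacement ratio
#'   (use `Inf` for breathing only).
#' @param breathing_rad peak phase deviation of the breathing component,
#'   in radians.
#' @param noise_sd additive complex noise level (0 for a clean signal).
#' @param scenario label attached to the generated segment.
#' @return an object of class `"vital_sim_config"`.
#' @export
vital_sim_config <- function(fs = 100, duration = 20, breathing_hz = 0.3,
                             heartbeat_hz = 1.2, amplitude_ratio = 10,
                             breathing_rad = 1, noise_sd = 0,
                             scenario = "resting") {
  stopifnot(fs > 0, duration > 0)
  if (breathing_hz < 0.1 || breathing_hz > 0.9) {
    stop("breathing_hz must lie in [0.1, 0.9] Hz")
  }
  if (heartbeat_hz < 1 || heartbeat_hz > 2.5) {
    stop("heartbeat_hz must lie in [1, 2.5] Hz")
  }
  stopifnot(amplitude_ratio > 0)
  structure(
    list(fs = fs, duration = duration, breathing_hz = breathing_hz,
         heartbeat_hz = heartbeat_hz, amplitude_ratio = amplitude_ratio,
         breathing_rad = breathing_rad, noise_sd = noise_sd,
         scenario = scenario),
    class = "vital_sim_config"
  )
}

#' Simulate a vital-sign radar signal
#'
#' Generates `fs * duration` complex samples of
#' `exp(1i * (a_b sin(2 pi f_b t) + a_h sin(2 pi f_h t)))` with
#' `a_b = breathing_rad` and `a_h = a_b / amplitude_ratio`, plus optional
#' complex white noise. The demodulated phase of the clean signal
#' concentrates its spectrum at the breathing and heartbeat rates.
#'
#' @param cfg a [vital_sim_config()].
#' @param seed optional integer seed (only matters when `noise_sd > 0`).
#' @return a [radar_segment()] labelled with `cfg$scenario`.
#' @export
gen_vital_signal <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "vital_sim_config"))
  n <- round(cfg$fs * cfg$duration)
  t <- (seq_len(n) - 1) / cfg$fs
  a_b <- cfg$breathing_rad
  a_h <- if (is.finite(cfg$amplitude_ratio)) a_b / cfg$amplitude_ratio else 0
  phase <- a_b * sin(2 * pi * cfg$breathing_hz * t) +
    a_h * sin(2 * pi * cfg$heartbeat_hz * t)
  s <- exp(1i * phase)
  if (cfg$noise_sd > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    if (!is.null(seed)) set.seed(seed)
    s <- s + complex(real = stats::rnorm(n, sd = cfg$noise_sd),
                     imaginary = stats::rnorm(n, sd = cfg$noise_sd))
  }
  radar_segment(s, cfg$fs, subject_id = "sim", label = cfg$scenario)
}
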