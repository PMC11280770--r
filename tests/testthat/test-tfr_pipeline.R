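test_that("segmentation yields fixed-length overlapping windows", {
  sig <- radar_segment(complex(real = rnorm(5000), imaginary = rnorm(5000)),
                       sampling_rate = 100)
  segs <- segment_signal(sig, window_seconds = 20, overlap_fraction = 0.5)
  expect_true(all(vapply(segs, function(s) length(s$samples), integer(1)) ==
                    2000L))
  # consecutive segments share half their samples
  expect_identical(segs[[1]]$samples[1001:2000], segs[[2]]$samples[1:1000])
})

test_that("segmentation enumerates exactly the valid window starts", {
  sig <- radar_segment(complex(real = seq_len(3000)), sampling_rate = 1)
  segs <- segment_signal(sig, window_seconds = 2000, overlap_fraction = 0.5)
  expect_length(segs, 2L)
  expect_equal(Re(segs[[1]]$samples[1]), 1)
  expect_equal(Re(segs[[2]]$samples[1]), 1001)
  # shorter than one window: empty, not an error
  short <- radar_segment(complex(real = seq_len(1999)), sampling_rate = 1)
  expect_length(segment_signal(short, 2000, 0.5), 0L)
})

test_that("every segment is a contiguous slice at the hop stride", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(500:3000, 1)
    wl <- sample(100:400, 1)
    ov <- runif(1, 0, 0.9)
    sig <- radar_segment(complex(real = rnorm(n), imaginary = rnorm(n)), 1)
    segs <- segment_signal(sig, wl, ov)
    hop <- wl - floor(ov * wl)
    for (k in seq_along(segs)) {
      s <- (k - 1L) * hop + 1L
      expect_identical(segs[[k]]$samples, sig$samples[s:(s + wl - 1L)])
    }
    expect_length(segs, if (n < wl) 0L else floor((n - wl) / hop) + 1L)
  }
})

test_that("band-pass filter preserves passband tones and kills stopband tones", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  mid <- 500:2500
  tone <- function(f) radar_segment(complex(real = sin(2 * pi * f * t)), fs)
  y10 <- bandpass_filter(tone(10), 0.1, 20, order = 4)
  p_in <- mean(sin(2 * pi * 10 * t[mid])^2)
  p_out <- mean(Re(y10$samples[mid])^2)
  expect_lt(abs(p_out / p_in - 1), 0.01)
  # 40 Hz sits one octave above the 20 Hz edge: the designed filter's own
  # frequency response is the oracle for the attenuation
  y40 <- bandpass_filter(tone(40), 0.1, 20, order = 4)
  p40 <- mean(Re(y40$samples[mid])^2) / mean(sin(2 * pi * 40 * t[mid])^2)
  # one octave above the 20 Hz edge a 4th-order filter guarantees at
  # least (f/fc)^(2*order) = 2^8 power attenuation; zero-phase filtering
  # can only attenuate further
  expect_lt(p40, (20 / 40)^(2 * 4))
  # linearity: zero in, zero out
  z <- bandpass_filter(radar_segment(complex(real = numeric(300)), fs),
                       0.1, 20)
  expect_equal(max(Mod(z$samples)), 0, tolerance = 1e-12)
  expect_error(bandpass_filter(tone(10), 20, 0.1), "low_hz")
})

test_that("STFT dimensions follow the framing formula", {
  seg <- radar_segment(complex(real = rnorm(2000), imaginary = rnorm(2000)),
                       100)
  cfg <- stft_config(512L, "hanning", 128L, 108L)
  spec <- stft_spectrogram(seg, cfg)
  expect_identical(dim(spec), c(94L, 512L))
  # exactly one frame when the window spans the signal
  one <- radar_segment(complex(real = rnorm(512)), 100)
  spec1 <- stft_spectrogram(one, stft_config(512L, "kaiser", 512L, 256L))
  expect_identical(nrow(spec1), 1L)
  # zero signal, zero spectrogram
  z <- stft_spectrogram(radar_segment(complex(real = numeric(600)), 100), cfg)
  expect_equal(max(Mod(z)), 0)
  short <- radar_segment(complex(real = rnorm(100)), 100)
  expect_error(stft_spectrogram(short, cfg), "128")
})

test_that("frame counts match brute-force start enumeration", {
  set.seed(11)
  for (rep in 1:20) {
    wl <- sample(8:64, 1)
    ov <- sample(0:(wl - 1L), 1)
    n <- sample(wl:(wl * 10), 1)
    cfg <- stft_config(n_dft = 64L, "hanning", wl, ov)
    hop <- wl - ov
    brute <- length(seq(1L, n - wl + 1L, by = hop))
    expect_identical(stft_frame_count(n, cfg), as.integer(brute))
  }
})

test_that("two-sided spectrum localizes a tone at its signed frequency", {
  fs <- 64
  t <- (0:511) / fs
  f0 <- -10
  seg <- radar_segment(exp(2i * pi * f0 * t), fs)
  spec <- stft_spectrogram(seg, stft_config(256L, "hanning", 256L, 0L))
  freq <- attr(spec, "freq_hz")
  expect_true(all(diff(freq) > 0))
  peak <- freq[which.max(Mod(spec[1, ]))]
  expect_lt(abs(peak - f0), fs / 256 + 1e-9)
})

test_that("log scaling matches its closed form and is monotone", {
  expect_equal(log_scale(0, "gait"), -100)
  expect_equal(log_scale(0, "vital"), -50)
  expect_equal(log_scale(1, "gait"), 20 * log10(1 + 1e-5))
  x <- sort(runif(100, 0, 10))
  expect_true(all(diff(log_scale(x, "gait")) > 0))
  expect_true(all(diff(log_scale(x, "vital")) > 0))
  expect_error(log_scale(-1, "gait"), "nonnegative")
})

test_that("standardization gives mean 0, sd 1 and is idempotent", {
  m <- matrix(rnorm(200, mean = 5, sd = 3), 10)
  s <- standardize(m)
  expect_lt(abs(mean(s)), 1e-6)
  expect_lt(abs(sd(as.vector(s)) - 1), 1e-6)
  expect_equal(standardize(s), s, tolerance = 1e-8)
  expect_true(all(standardize(matrix(7, 4, 4)) == 0))
})

test_that("magnitude/phase composition round-trips its halves", {
  set.seed(5)
  spec <- matrix(complex(real = rnorm(8 * 64), imaginary = rnorm(8 * 64)),
                 8, 64)
  out <- compose_vital_sample(spec)
  expect_identical(dim(out$values), c(8L, 64L))
  expect_identical(out$channel_semantics, "magnitude_phase_composite")
  idx <- 33:64   # nonnegative-frequency half of a shifted axis
  mag <- standardize(log_scale(Mod(spec), "vital"))[, idx]
  ph <- standardize(Arg(spec))[, idx]
  expect_equal(out$values[, 1:32], mag)
  expect_equal(out$values[, 33:64], ph)
  # zero spectrogram: both halves constant zero after standardization
  z <- compose_vital_sample(matrix(0i, 8, 64))
  expect_true(all(z$values == 0))
  expect_error(compose_vital_sample(matrix(0i, 8, 63)), "even")
})

test_that("mix augmentation mixes equally and takes the minority label", {
  a <- tfr_sample(matrix(rnorm(32), 4), label = "resting")
  b <- tfr_sample(matrix(rnorm(32), 4), label = "apnea")
  m <- mix_augment(a, b)
  expect_identical(m$label, "apnea")
  expect_equal(m$values, 0.5 * a$values + 0.5 * b$values)
  expect_true(all(m$values >= pmin(a$values, b$values) - 1e-12))
  expect_true(all(m$values <= pmax(a$values, b$values) + 1e-12))
  # self-mix is the identity on values; negation cancels
  expect_equal(mix_augment(a, b <- tfr_sample(a$values, label = "x"))$values,
               a$values)
  neg <- tfr_sample(-a$values, label = "apnea")
  expect_true(all(mix_augment(a, neg)$values == 0))
  wrong <- tfr_sample(matrix(0, 2, 16), label = "apnea")
  expect_error(mix_augment(a, wrong), "shape")
})

test_that("dataset splitting respects ratios, partitions, and the seed", {
  samples <- lapply(1:10, function(i) {
    tfr_sample(matrix(i, 4, 8), label = i %% 2)
  })
  sp <- split_dataset(samples, c(8, 1, 1), seed = 9)
  expect_length(sp$train, 8L)
  expect_length(sp$validation, 1L)
  expect_length(sp$test, 1L)
  sp2 <- split_dataset(samples, c(8, 1, 1), seed = 9)
  expect_identical(sp, sp2)
  # random sizes/ratios always partition the input
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    r <- runif(3, 0.5, 3)
    ss <- lapply(seq_len(n), function(i) tfr_sample(matrix(i, 2, 4), label = 1))
    sp <- split_dataset(ss, r, seed = rep)
    ids <- c(vapply(sp$train, function(s) s$values[1], numeric(1)),
             vapply(sp$validation, function(s) s$values[1], numeric(1)),
             vapply(sp$test, function(s) s$values[1], numeric(1)))
    expect_setequal(ids, seq_len(n))
    expect_length(ids, n)
  }
})

test_that("LOO splits are subject-disjoint and cover the dataset", {
  samples <- unlist(lapply(1:6, function(sub) {
    lapply(1:4, function(i) tfr_sample(matrix(rnorm(8), 2),
                                       label = i %% 2,
                                       subject_id = sprintf("P%d", sub)))
  }), recursive = FALSE)
  splits <- loo_split(samples, val_fraction = 0.2, seed = 4)
  expect_length(splits, 6L)
  all_test <- character()
  for (sp in splits) {
    test_subs <- unique(vapply(sp$test, function(s) s$subject_id,
                               character(1)))
    train_subs <- vapply(c(sp$train, sp$validation),
                         function(s) s$subject_id, character(1))
    expect_length(test_subs, 1L)
    expect_false(test_subs %in% train_subs)
    expect_length(c(sp$train, sp$validation, sp$test), length(samples))
    all_test <- c(all_test, test_subs)
  }
  expect_setequal(all_test, sprintf("P%d", 1:6))
})

test_that("the vital recipe composes end to end on a simulated signal", {
  sig <- gen_vital_signal(vital_sim_config(fs = 100, duration = 45))
  out <- preprocess_signal(sig, vital_recipe())
  # 45 s at 100 Hz: windows start at 0 s, 10 s, 20 s -> 3 segments
  expect_length(out, 3L)
  cfg <- vital_recipe()$stft
  expect_identical(dim(out[[1]]$values),
                   c(stft_frame_count(2000L, cfg), cfg$n_dft))
  expect_true(all(vapply(out, function(s) all(is.finite(s$values)),
                         logical(1))))
})
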