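#' Segment a radar signal into fixed-length overlapping windows
#'
#' Cuts the signal into windows of `window_seconds` seconds with a given
#' overlap fraction, the first step of the vital-sign recipe (20 s windows
#' with 50% overlap at 100 Hz give 2000-sample segments). Trailing samples
#' that do not fill a whole window are dropped.
#'
#' @param signal a [radar_segment()].
#' @param window_seconds window duration in seconds;
#'   `window_seconds * sampling_rate` must be a whole number of samples.
#' @param overlap_fraction fraction of each window shared with its
#'   successor, in \[0, 1).
#' @return a list of [radar_segment()] objects (possibly empty when the
#'   signal is shorter than one window); each inherits the input's
#'   sampling rate, subject and label.
#' @examples
#' sig <- radar_segment(complex(real = rnorm(3000)), 100)
#' length(segment_signal(sig, 20, 0.5))   # one 2000-sample window fits
#' @export
segment_signal <- function(signal, window_seconds, overlap_fraction = 0.5) {
  stopifnot(inherits(signal, "radar_segment"))
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("'overlap_fraction' must be in [0, 1)")
  }
  wl_exact <- window_seconds * signal$sampling_rate
  wl <- round(wl_exact)
  if (abs(wl_exact - wl) > 1e-8) {
    stop("window_seconds * sampling_rate must be a whole number of samples")
  }
  wl <- as.integer(wl)
  hop <- wl - as.integer(floor(overlap_fraction * wl))
  n <- length(signal$samples)
  if (n < wl) return(list())
  starts <- seq.int(1L, n - wl + 1L, by = hop)
  lapply(starts, function(s) {
    radar_segment(signal$samples[s:(s + wl - 1L)], signal$sampling_rate,
                  subject_id = signal$subject_id, label = signal$label)
  })
}

#' Butterworth band-pass filter a radar segment
#'
#' Applies a zero-phase Butterworth band-pass filter (via forward-backward
#' filtering) to the in-phase and quadrature components separately. The
#' vital-sign recipe uses a 4th-order filter with cutoffs \[0.1, 20\] Hz,
#' keeping the breathing (0.1-0.9 Hz) and heartbeat (1-2.5 Hz) bands while
#' removing DC drift and out-of-band noise.
#'
#' @param segment a [radar_segment()].
#' @param low_hz,high_hz passband edges in Hz; `0 < low_hz < high_hz <
#'   sampling_rate / 2`.
#' @param order filter order of the Butterworth prototype.
#' @return a filtered [radar_segment()] of the same length.
#' @export
bandpass_filter <- function(segment, low_hz = 0.1, high_hz = 20, order = 4) {
  stopifnot(inherits(segment, "radar_segment"))
  fs <- segment$sampling_rate
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("need 0 < low_hz < high_hz < sampling_rate/2")
  }
  bt <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  re <- signal::filtfilt(bt, Re(segment$samples))
  im <- signal::filtfilt(bt, Im(segment$samples))
  radar_segment(complex(real = re, imaginary = im), fs,
                subject_id = segment$subject_id, label = segment$label)
}

.stft_window <- function(cfg) {
  switch(cfg$window_kind,
         hanning = signal::hanning(cfg$window_length),
         kaiser  = signal::kaiser(cfg$window_length, cfg$kaiser_beta))
}

#' Number of STFT frames for a signal length
#'
#' The closed-form framing count `floor((n - window_length) / hop) + 1`
#' with `hop = window_length - overlap`; trailing partial windows are
#' dropped.
#'
#' @param n signal length in samples (`n >= window_length`).
#' @param cfg an [stft_config()].
#' @return integer frame count.
#' @export
stft_frame_count <- function(n, cfg) {
  hop <- cfg$window_length - cfg$overlap
  as.integer(floor((n - cfg$window_length) / hop) + 1L)
}

#' Two-sided complex spectrogram via the short-time Fourier transform
#'
#' Frames the segment, applies the configured window, zero-pads each frame
#' to `n_dft` points and takes the DFT. With `two_sided = TRUE` (the
#' default) bins are reordered so the frequency axis runs from -fs/2
#' towards +fs/2, matching the normalized \[-1, 1\] filter axis.
#'
#' @param segment a [radar_segment()] with at least `window_length` samples.
#' @param cfg an [stft_config()].
#' @return a complex T x F matrix (T frames, F = `n_dft` bins) with
#'   attributes `freq_hz` (bin frequencies in Hz) and `sampling_rate`.
#' @examples
#' seg <- radar_segment(complex(real = rnorm(2000), imaginary = rnorm(2000)), 100)
#' dim(stft_spectrogram(seg, stft_config(512, "hanning", 128, 108)))  # 94 x 512
#' @export
stft_spectrogram <- function(segment, cfg) {
  stopifnot(inherits(segment, "radar_segment"), inherits(cfg, "stft_config"))
  x <- segment$samples
  n <- length(x)
  if (n < cfg$window_length) {
    stop(sprintf("segment has %d samples but the STFT window needs at least %d",
                 n, cfg$window_length))
  }
  wl <- cfg$window_length
  hop <- wl - cfg$overlap
  nt <- stft_frame_count(n, cfg)
  win <- .stft_window(cfg)
  frames <- matrix(0i, nrow = cfg$n_dft, ncol = nt)
  for (t in seq_len(nt)) {
    s <- (t - 1L) * hop
    frames[seq_len(wl), t] <- x[(s + 1L):(s + wl)] * win
  }
  spec <- stats::mvfft(frames)            # n_dft x nt, bins 0..n_dft-1
  spec <- t(spec)                         # nt x n_dft
  fs <- segment$sampling_rate
  freq <- (seq_len(cfg$n_dft) - 1L) / cfg$n_dft * fs
  if (cfg$two_sided) {
    # fftshift: negative-frequency bins first, so the axis runs -fs/2 .. +fs/2
    half <- ceiling(cfg$n_dft / 2)
    ord <- c((half + 1L):cfg$n_dft, 1L:half)
    spec <- spec[, ord, drop = FALSE]
    freq <- freq[ord]
    freq[freq >= fs / 2] <- freq[freq >= fs / 2] - fs
  }
  attr(spec, "freq_hz") <- freq
  attr(spec, "sampling_rate") <- fs
  spec
}

#' Logarithmic power scaling
#'
#' The two scaling functions of the preprocessing recipes:
#' gait spectrograms use `20 * log10(x + 1e-5)`, vital-sign magnitude
#' spectrograms use `10 * log10(x + 1e-5)`. Both are strictly increasing
#' on \[0, Inf).
#'
#' @param values nonnegative numeric vector or matrix.
#' @param mode `"gait"` or `"vital"`.
#' @return the elementwise-scaled input (same shape).
#' @examples
#' log_scale(0, "gait")   # -100
#' log_scale(0, "vital")  # -50
#' @export
log_scale <- function(values, mode = c("gait", "vital")) {
  mode <- match.arg(mode)
  if (any(values < 0)) stop("log_scale is defined for nonnegative values only")
  k <- if (mode == "gait") 20 else 10
  out <- k * log10(values + 1e-5)
  out
}

#' Per-sample standardization (z-score)
#'
#' Standardizes a matrix over all its entries to mean 0 and (sample)
#' standard deviation 1. A constant input maps to all zeros. This is the
#' per-sample standardization used throughout the pipeline; no
#' dataset-level statistics are involved, so samples remain comparable
#' regardless of the set they were processed in.
#'
#' @param values numeric vector or matrix.
#' @return the standardized input (same shape).
#' @export
standardize <- function(values) {
  m <- mean(values)
  s <- stats::sd(as.vector(values))
  if (!is.finite(s) || s == 0) {
    values[] <- 0
    return(values)
  }
  (values - m) / s
}

#' Compose a vital-sign sample from a complex spectrogram
#'
#' Builds the magnitude/phase composite input of the vital-sign recipe:
#' the magnitude part is log-scaled (`10*log10(x+1e-5)`) and standardized,
#' the phase part is standardized, and one half of each (along the
#' frequency axis) is concatenated into a single T x F matrix. Which
#' spectral half is taken is configurable since either choice carries the
#' same information for a conjugate-symmetric axis.
#'
#' @param spec complex T x F spectrogram with an even number of bins F,
#'   stored two-sided shifted (negative frequencies first).
#' @param magnitude_half `"positive"` (default) places the
#'   nonnegative-frequency half of the magnitude in bins `1..F/2` and the
#'   nonnegative-frequency half of the phase in bins `F/2+1..F`;
#'   `"negative"` uses the negative-frequency halves instead.
#' @param label,subject_id metadata forwarded to the output sample.
#' @return a [tfr_sample()] with `channel_semantics =
#'   "magnitude_phase_composite"`.
#' @export
compose_vital_sample <- function(spec, magnitude_half = c("positive", "negative"),
                                 label = NA, subject_id = NA_character_) {
  magnitude_half <- match.arg(magnitude_half)
  nf <- ncol(spec)
  if (nf %% 2L != 0L) stop("compose_vital_sample needs an even number of bins")
  half <- nf %/% 2L
  idx <- if (magnitude_half == "positive") (half + 1L):nf else 1L:half
  mag <- standardize(log_scale(Mod(spec), mode = "vital"))[, idx, drop = FALSE]
  ph <- standardize(Arg(spec))[, idx, drop = FALSE]
  tfr_sample(cbind(mag, ph), label = label, subject_id = subject_id,
             channel_semantics = "magnitude_phase_composite")
}

#' Mix augmentation for minority classes
#'
#' Combines a resting-class sample and a minority-class sample in equal
#' proportions; the augmented sample takes the minority label. Used only
#' during training to counter class imbalance.
#'
#' @param resting a [tfr_sample()] from the majority (resting) class.
#' @param minority a [tfr_sample()] from another class; must have the same
#'   shape and a label different from `resting`'s.
#' @return a new [tfr_sample()] with values
#'   `0.5 * resting$values + 0.5 * minority$values` and the minority label.
#' @export
mix_augment <- function(resting, minority) {
  stopifnot(inherits(resting, "tfr_sample"), inherits(minority, "tfr_sample"))
  if (!identical(dim(resting$values), dim(minority$values))) {
    stop("mix_augment requires samples of identical shape")
  }
  tfr_sample(0.5 * resting$values + 0.5 * minority$values,
             freq_axis = resting$freq_axis,
             label = minority$label,
             subject_id = minority$subject_id,
             channel_semantics = resting$channel_semantics)
}

#' Random train/validation/test split
#'
#' Shuffles the samples with the given seed and splits them by the ratio
#' triple. Validation and test sizes are rounded to the nearest integer
#' (half rounds up, i.e. towards the test set); the training set takes the
#' remainder. The canonical 7:1.5:1.5 split of 8000 samples allocates
#' exactly 1200 to the test set.
#'
#' @param samples list of [tfr_sample()] objects.
#' @param ratios three nonnegative numbers (train, validation, test);
#'   normalized to sum to 1.
#' @param seed integer seed controlling the shuffle.
#' @return a list of class `"dataset_split"` with elements `train`,
#'   `validation`, `test` (lists of samples) and `ratios`.
#' @export
split_dataset <- function(samples, ratios = c(7, 1.5, 1.5), seed = 1024L) {
  stopifnot(is.list(samples), length(ratios) == 3L, all(ratios >= 0))
  ratios <- ratios / sum(ratios)
  n <- length(samples)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  ord <- sample.int(n)
  n_test <- as.integer(floor(n * ratios[3L] + 0.5))
  n_val <- as.integer(floor(n * ratios[2L] + 0.5))
  if (n_test + n_val > n) n_val <- n - n_test
  i_test <- ord[seq_len(n_test)]
  i_val <- ord[n_test + seq_len(n_val)]
  i_train <- ord[-seq_len(n_test + n_val)]
  structure(
    list(train = samples[i_train], validation = samples[i_val],
         test = samples[i_test], ratios = ratios),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train=%d validation=%d test=%d (ratios %s)\n",
              length(x$train), length(x$validation), length(x$test),
              paste(signif(x$ratios, 3), collapse = ":")))
  invisible(x)
}

#' Leave-one-subject-out splits
#'
#' Builds one [split][split_dataset] per subject: that subject's samples
#' form the test set, a seeded 20% draw of the remaining samples forms the
#' validation set, and the rest trains the model. Splits are
#' subject-disjoint by construction, the appropriate protocol when model
#' generalization across people is the question.
#'
#' @param samples list of [tfr_sample()] objects with `subject_id` set.
#' @param val_fraction fraction of the non-test samples used for
#'   validation.
#' @param seed integer seed for the validation draw.
#' @return a list of `"dataset_split"` objects, one per distinct subject,
#'   named by subject.
#' @export
loo_split <- function(samples, val_fraction = 0.2, seed = 1024L) {
  subs <- vapply(samples, function(s) as.character(s$subject_id), character(1))
  if (anyNA(subs)) stop("all samples need a subject_id for LOO splitting")
  uniq <- unique(subs)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  out <- lapply(uniq, function(sub) {
    test_idx <- which(subs == sub)
    rest <- which(subs != sub)
    n_val <- as.integer(floor(length(rest) * val_fraction + 0.5))
    val_idx <- sample(rest, n_val)
    train_idx <- setdiff(rest, val_idx)
    structure(
      list(train = samples[train_idx], validation = samples[val_idx],
           test = samples[test_idx],
           ratios = c(length(train_idx), n_val, length(test_idx)) /
             length(samples),
           test_subject = sub),
      class = "dataset_split"
    )
  })
  names(out) <- uniq
  out
}

#' Run a full preprocessing recipe on a raw signal
#'
#' Convenience wrapper chaining the pipeline stages for one raw signal.
#' For the vital recipe: segmentation, band-pass filtering, STFT, and
#' magnitude/phase composition, yielding one [tfr_sample()] per segment.
#' For the gait recipe: STFT of the whole signal, log power scaling and
#' standardization, yielding a single-sample list.
#'
#' @param signal a [radar_segment()] holding the full recording.
#' @param recipe a recipe list from [vital_recipe()] or [gait_recipe()].
#' @return a list of [tfr_sample()] objects.
#' @export
preprocess_signal <- function(signal, recipe = vital_recipe()) {
  stopifnot(inherits(signal, "radar_segment"))
  if (identical(recipe$name, "vital")) {
    segs <- segment_signal(signal, recipe$segment_seconds,
                           recipe$segment_overlap)
    lapply(segs, function(seg) {
      seg <- bandpass_filter(seg, recipe$bandpass[1L], recipe$bandpass[2L],
                             recipe$bandpass_order)
      spec <- stft_spectrogram(seg, recipe$stft)
      compose_vital_sample(spec, label = seg$label,
                           subject_id = seg$subject_id)
    })
  } else {
    spec <- stft_spectrogram(signal, recipe$stft)
    vals <- standardize(log_scale(Mod(spec)^2, mode = recipe$log_mode))
    list(tfr_sample(vals, label = signal$label,
                    subject_id = signal$subject_id))
  }
}

# Save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
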