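#' Construct a raw radar segment
#'
#' A contiguous stretch of complex (I/Q) radar samples with its sampling
#' rate and bookkeeping metadata. This is the unit the preprocessing
#' pipeline consumes: segments are band-pass filtered and transformed into
#' spectrograms.
#'
#' @param samples complex vector of I/Q samples (a real vector is promoted
#'   to complex with zero quadrature component).
#' @param sampling_rate sampling rate in Hz, must be positive.
#' @param subject_id opaque subject identifier used for subject-disjoint
#'   (leave-one-out) splitting.
#' @param label class label (any atomic value), or `NA` when unknown.
#' @return an object of class `"radar_segment"`.
#' @examples
#' seg <- radar_segment(complex(real = rnorm(200), imaginary = rnorm(200)), 100)
#' length(seg$samples)
#' @export
radar_segment <- function(samples, sampling_rate, subject_id = NA_character_,
                          label = NA) {
  if (!is.complex(samples)) {
    stopifnot(is.numeric(samples))
    samples <- complex(real = samples, imaginary = numeric(length(samples)))
  }
  if (length(samples) < 1L) stop("a radar segment needs at least one sample")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("'sampling_rate' must be a single positive number (Hz)")
  }
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         subject_id = subject_id, label = label),
    class = "radar_segment"
  )
}

#' @export
print.radar_segment <- function(x, ...) {
  cat(sprintf("<radar_segment> %d complex samples @ %g Hz (%.3g s)",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (!is.na(x$subject_id)) cat(sprintf("  subject=%s", x$subject_id))
  if (!all(is.na(x$label))) cat(sprintf("  label=%s", format(x$label)))
  cat("\n")
  invisible(x)
}

#' Short-time Fourier transform configuration
#'
#' Bundles the framing and windowing parameters of the STFT. The two
#' stock recipes are [vital_recipe()] (512 DFT points, 128-point Hanning
#' window, 108-sample overlap) and [gait_recipe()] (512 DFT points,
#' 512-point Kaiser window, 50% overlap).
#'
#' @param n_dft number of DFT points (frequency bins of the output).
#' @param window_kind `"hanning"` or `"kaiser"`.
#' @param window_length window length in samples; at most `n_dft`
#'   (shorter windows are zero-padded to `n_dft`).
#' @param overlap overlap between consecutive windows, in samples;
#'   `0 <= overlap < window_length`.
#' @param two_sided logical; keep the two-sided spectrum with the
#'   frequency axis reordered to run from -fs/2 towards +fs/2.
#' @param kaiser_beta shape parameter of the Kaiser window (ignored for
#'   Hanning). The default 14 gives strong sidelobe suppression.
#' @return an object of class `"stft_config"`.
#' @export
stft_config <- function(n_dft, window_kind = c("hanning", "kaiser"),
                        window_length, overlap, two_sided = TRUE,
                        kaiser_beta = 14) {
  window_kind <- match.arg(window_kind)
  n_dft <- as.integer(n_dft)
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (!(overlap >= 0L && overlap < window_length && window_length <= n_dft)) {
    stop("need 0 <= overlap < window_length <= n_dft")
  }
  structure(
    list(n_dft = n_dft, window_kind = window_kind,
         window_length = window_length, overlap = overlap,
         two_sided = isTRUE(two_sided), kaiser_beta = kaiser_beta),
    class = "stft_config"
  )
}

#' Stock preprocessing recipes
#'
#' `vital_recipe()` reproduces the vital-sign pipeline: 20 s segments with
#' 50% overlap, 4th-order Butterworth band-pass at \[0.1, 20\] Hz, STFT
#' with 512 DFT points and a 128-point Hanning window with 108-sample
#' overlap, magnitude scaled by `10*log10(x + 1e-5)`, standardization, and
#' magnitude/phase half-and-half composition. `gait_recipe()` reproduces
#' the gait pipeline: STFT with 512 DFT points and a 512-point Kaiser
#' window with 50% overlap, power scaled by `20*log10(x + 1e-5)`, then
#' standardization.
#'
#' @return a list with the STFT configuration and the remaining pipeline
#'   parameters, consumed by [preprocess_signal()].
#' @export
vital_recipe <- function() {
  list(name = "vital",
       segment_seconds = 20, segment_overlap = 0.5,
       bandpass = c(0.1, 20), bandpass_order = 4,
       stft = stft_config(512L, "hanning", 128L, 108L),
       log_mode = "vital")
}

#' @rdname vital_recipe
#' @export
gait_recipe <- function() {
  list(name = "gait",
       segment_seconds = NA_real_, segment_overlap = NA_real_,
       bandpass = NULL, bandpass_order = 4,
       stft = stft_config(512L, "kaiser", 512L, 256L),
       log_mode = "gait")
}

#' Construct a time-frequency representation sample
#'
#' A `tfr_sample` holds a T x F real matrix of (standardized) spectrogram
#' values: T time frames by F frequency bins. The frequency axis is
#' linearly normalized to \[-1, 1\], the domain on which sub-band filters
#' are parameterized.
#'
#' @param values numeric T x F matrix, all entries finite.
#' @param freq_axis strictly increasing numeric vector of length F in
#'   \[-1, 1\]; defaults to an even grid over \[-1, 1\].
#' @param label class label, or `NA`.
#' @param subject_id opaque subject identifier.
#' @param channel_semantics `"power"` for plain spectrograms or
#'   `"magnitude_phase_composite"` for the vital-sign composition.
#' @return an object of class `"tfr_sample"`.
#' @export
tfr_sample <- function(values, freq_axis = NULL, label = NA,
                       subject_id = NA_character_,
                       channel_semantics = c("power",
                                             "magnitude_phase_composite")) {
  channel_semantics <- match.arg(channel_semantics)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("TFR values must all be finite")
  nf <- ncol(values)
  if (is.null(freq_axis)) freq_axis <- normalized_freq_axis(nf)
  if (length(freq_axis) != nf) {
    stop("freq_axis length must equal the number of frequency bins")
  }
  if (any(diff(freq_axis) <= 0)) stop("freq_axis must be strictly increasing")
  structure(
    list(values = values, freq_axis = freq_axis, label = label,
         subject_id = subject_id, channel_semantics = channel_semantics),
    class = "tfr_sample"
  )
}

#' @export
print.tfr_sample <- function(x, ...) {
  cat(sprintf("<tfr_sample> %d frames x %d bins (%s)",
              nrow(x$values), ncol(x$values), x$channel_semantics))
  if (!all(is.na(x$label))) cat(sprintf("  label=%s", format(x$label)))
  cat("\n")
  invisible(x)
}

#' Normalized frequency axis for F bins
#'
#' Maps F frequency-bin centers linearly onto \[-1, 1\] (endpoints
#' included), the convention used by the sub-band filters.
#'
#' @param n_bins number of frequency bins F.
#' @return numeric vector of length `n_bins`.
#' @export
normalized_freq_axis <- function(n_bins) {
  if (n_bins == 1L) return(0)
  seq(-1, 1, length.out = n_bins)
}

# Coerce a list of tfr_sample (or a T x F x N array + labels) to the
# internal array form used by training: list(x = T x F x N array,
# labels = vector, freq_axis, subjects).
.as_tfr_array <- function(x, labels = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (is.null(labels)) stop("labels must be supplied with an array input")
    return(list(x = x, labels = labels,
                freq_axis = normalized_freq_axis(dim(x)[2L]),
                subjects = rep(NA_character_, dim(x)[3L])))
  }
  if (inherits(x, "tfr_sample")) x <- list(x)
  stopifnot(is.list(x), length(x) >= 1L,
            all(vapply(x, inherits, logical(1), "tfr_sample")))
  d <- dim(x[[1L]]$values)
  ok <- vapply(x, function(s) identical(dim(s$values), d), logical(1))
  if (!all(ok)) stop("all TFR samples must share the same shape")
  arr <- array(0, dim = c(d[1L], d[2L], length(x)))
  for (i in seq_along(x)) arr[, , i] <- x[[i]]$values
  list(x = arr,
       labels = if (is.null(labels)) {
         unlist(lapply(x, function(s) s$label))
       } else labels,
       freq_axis = x[[1L]]$freq_axis,
       subjects = vapply(x, function(s) as.character(s$subject_id),
                         character(1)))
}
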