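#' Write and read TFR samples as a plain-text directory container
#'
#' The on-disk schema is deliberately simple and text-only: one CSV matrix
#' per sample (`sample_0001.csv`, no header, T rows x F columns), a
#' `manifest.csv` with columns `file`, `label`, `subject`,
#' `channel_semantics`, and a `freq_axis.csv` holding the shared
#' normalized frequency axis. `read_tfr_dir()` restores the sample list.
#'
#' @param samples list of [tfr_sample()] objects sharing one shape.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tfr_dir <- function(samples, dir) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("sample_%04d.csv", seq_along(samples))
  for (i in seq_along(samples)) {
    utils::write.table(samples[[i]]$values, file.path(dir, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(
    file = files,
    label = vapply(samples, function(s) as.character(s$label), character(1)),
    subject = vapply(samples, function(s) as.character(s$subject_id),
                     character(1)),
    channel_semantics = vapply(samples, function(s) s$channel_semantics,
                               character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.table(samples[[1L]]$freq_axis, file.path(dir, "freq_axis.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_tfr_dir
#' @export
read_tfr_dir <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  fax <- as.numeric(utils::read.table(file.path(dir, "freq_axis.csv"),
                                      sep = ",")[[1L]])
  lapply(seq_len(nrow(manifest)), function(i) {
    vals <- as.matrix(utils::read.table(file.path(dir, manifest$file[i]),
                                        sep = ","))
    dimnames(vals) <- NULL
    lab <- manifest$label[i]
    lab_num <- suppressWarnings(as.numeric(lab))
    tfr_sample(vals, freq_axis = fax,
               label = if (!is.na(lab_num)) lab_num else lab,
               subject_id = manifest$subject[i],
               channel_semantics = manifest$channel_semantics[i])
  })
}

#' Write and read raw I/Q signals as CSV
#'
#' One CSV per signal with columns `re`, `im`, plus a JSON sidecar
#' (`<path>.json`) holding the sampling rate, subject and label.
#'
#' @param segment a [radar_segment()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(segment, path) {
  stopifnot(inherits(segment, "radar_segment"))
  utils::write.csv(data.frame(re = Re(segment$samples),
                              im = Im(segment$samples)),
                   path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = segment$sampling_rate,
                            subject_id = segment$subject_id,
                            label = segment$label),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  radar_segment(complex(real = df$re, imaginary = df$im), meta$fs_hz,
                subject_id = meta$subject_id,
                label = if (is.null(meta$label)) NA else meta$label)
}

#' Save and load a fitted model
#'
#' Serializes the complete checkpoint — filter bank, encoder parameters
#' and batch-norm statistics, proxies, classes, history and configuration
#' — to a single RDS file.
#'
#' @param object a fitted [ebdl()] model.
#' @param path file path.
#' @return `save_ebdl()` returns `path` invisibly; `load_ebdl()` returns
#'   the restored `"ebdl"` object.
#' @export
save_ebdl <- function(object, path) {
  stopifnot(inherits(object, "ebdl"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_ebdl
#' @export
load_ebdl <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "ebdl")) stop("file does not contain an ebdl model")
  object
}
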