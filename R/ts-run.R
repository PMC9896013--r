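#' Multichannel time-series run
#'
#' The basic unit of data: one recording run for one subject, stored as a
#' channels x samples matrix together with its sampling rate and metadata.
#' Hemoglobin contrasts (`HbO`, `HbR`, `HbT`) are concentration changes in
#' micromolar; raw intensities (`intensity_760`, `intensity_850`) are in
#' arbitrary detector counts; `BOLD` is in arbitrary units.
#'
#' @param data numeric matrix, channels x samples.
#' @param sampling_rate sampling frequency in Hz, positive scalar.
#' @param subject_id,run_id character labels.
#' @param contrast one of `"intensity_760"`, `"intensity_850"`, `"HbO"`,
#'   `"HbR"`, `"HbT"`, `"BOLD"`.
#' @param channel_ids character vector, one per row of `data`; defaults to
#'   `ch01, ch02, ...`.
#' @param quality_flags logical vector, one per channel, `TRUE` = good.
#' @return an object of class `ts_run`.
#' @export
ts_run <- function(data, sampling_rate, subject_id = "s01", run_id = "r01",
                   contrast = c("HbO", "HbR", "HbT", "BOLD",
                                "intensity_760", "intensity_850"),
                   channel_ids = NULL, quality_flags = NULL) {
  contrast <- match.arg(contrast)
  if (!is.matrix(data) || !is.numeric(data))
    stop_invalid("`data` must be a numeric channels x samples matrix")
  if (anyNA(data)) stop_invalid("`data` contains missing samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop_invalid("`sampling_rate` must be a positive scalar (Hz)")
  n_ch <- nrow(data)
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(n_ch))
  if (length(channel_ids) != n_ch)
    stop_invalid("`channel_ids` length (", length(channel_ids),
                 ") != number of rows (", n_ch, ")")
  if (is.null(quality_flags)) quality_flags <- rep(TRUE, n_ch)
  if (length(quality_flags) != n_ch)
    stop_invalid("`quality_flags` must have one entry per channel")
  rownames(data) <- channel_ids
  structure(
    list(data = data, sampling_rate = sampling_rate,
         subject_id = as.character(subject_id),
         run_id = as.character(run_id), contrast = contrast,
         channel_ids = as.character(channel_ids),
         quality_flags = as.logical(quality_flags)),
    class = "ts_run")
}

#' @export
print.ts_run <- function(x, ...) {
  cat(sprintf(
    "<ts_run> subject %s, run %s, contrast %s\n  %d channels x %d samples @ %.3g Hz (%.1f s), %d channel(s) flagged bad\n",
    x$subject_id, x$run_id, x$contrast, nrow(x$data), ncol(x$data),
    x$sampling_rate, ncol(x$data) / x$sampling_rate, sum(!x$quality_flags)))
  invisible(x)
}

#' @export
dim.ts_run <- function(x) dim(x$data)

n_samples <- function(run) ncol(run$data)
n_channels <- function(run) nrow(run$data)

# Replace the data matrix, keeping metadata; optionally re-label contrast.
with_data <- function(run, data, contrast = run$contrast) {
  ts_run(data, run$sampling_rate, run$subject_id, run$run_id, contrast,
         run$channel_ids, run$quality_flags)
}

#' Write / read a run as delimited text with a JSON sidecar
#'
#' Each run is stored as a tab-separated channels x samples matrix
#' (`<stem>.tsv`, one row per channel, no header) plus a JSON sidecar
#' (`<stem>.json`) holding subject, run, contrast, sampling rate, channel ids
#' and quality flags.
#'
#' @param run a [ts_run()].
#' @param stem file path without extension.
#' @return `write_run` returns `stem` invisibly; `read_run` returns a
#'   [ts_run()].
#' @export
write_run <- function(run, stem) {
  stopifnot(inherits(run, "ts_run"))
  utils::write.table(run$data, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(subject_id = run$subject_id, run_id = run$run_id,
               contrast = run$contrast, sampling_rate = run$sampling_rate,
               channel_ids = run$channel_ids,
               quality_flags = run$quality_flags)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_run
#' @export
read_run <- function(stem) {
  dat <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t"))
  dimnames(dat) <- NULL
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  ts_run(dat, meta$sampling_rate, meta$subject_id, meta$run_id,
         meta$contrast, meta$channel_ids, meta$quality_flags)
}
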