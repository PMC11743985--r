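# Delimited-text readers/writers for the pipeline's table and series
# formats. Tables are tab-separated with a header; ROI series are one
# samples x ROI matrix per subject plus a JSON sidecar carrying the
# sampling rate and ROI names.

#' Write / read a behavioral or metrics table
#'
#' Plain tab-separated text with a header row. `read_experience_table()`
#' and `read_ni_table()` validate the expected columns and label sets on
#' the way in.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `write_tsv()` returns `path` invisibly; readers return a
#'   data.frame.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_tsv <- function(path) {
  if (!file.exists(path))
    abort_painattn(sprintf("file not found: %s", path), "io_error")
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname table_io
#' @export
read_experience_table <- function(path) {
  validate_experience_records(read_tsv(path))
}

#' @rdname table_io
#' @export
read_ni_table <- function(path) {
  validate_ni_records(read_tsv(path))
}

#' Write / read one subject's ROI series matrix
#'
#' The matrix (rows = samples, columns = ROIs) goes to
#' `<subject_id>_timeseries.tsv`; a JSON sidecar
#' `<subject_id>_timeseries.json` records `subject_id`, `fs`, `n_samples`,
#' and the ROI names.
#'
#' @param mat numeric samples x ROI matrix with ROI column names.
#' @param fs sampling rate, Hz.
#' @param subject_id subject identifier (used in the file names).
#' @param dir directory to write into (created if missing).
#' @return `write_roi_series()` returns the tsv path invisibly;
#'   `read_roi_series()` returns a list with `mat`, `fs`, `subject_id`.
#' @export
write_roi_series <- function(mat, fs, subject_id, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, paste0(subject_id, "_timeseries"))
  data.table::fwrite(as.data.frame(mat), paste0(base, ".tsv"), sep = "\t")
  jsonlite::write_json(
    list(subject_id = subject_id, fs = fs, n_samples = nrow(mat),
         roi = colnames(mat)),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(base, ".tsv"))
}

#' @rdname write_roi_series
#' @export
read_roi_series <- function(dir, subject_id) {
  base <- file.path(dir, paste0(subject_id, "_timeseries"))
  if (!file.exists(paste0(base, ".tsv")))
    abort_painattn(sprintf("no series file for subject '%s' in %s",
                           subject_id, dir), "io_error")
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(data.table::fread(paste0(base, ".tsv"), sep = "\t"))
  if (!identical(colnames(mat), as.character(meta$roi)))
    abort_painattn("series columns disagree with sidecar ROI names",
                   "io_error")
  list(mat = mat, fs = meta$fs, subject_id = meta$subject_id)
}

#' Compute band metrics for every subject series found in a directory
#'
#' Scans `dir` for `*_timeseries.tsv` files written by
#' [write_roi_series()] and computes the full metric table, allowing the
#' spectral stage to be re-run from on-disk intermediates.
#'
#' @param dir directory of series files.
#' @param config a [welch_config()].
#' @return long-format metrics data.frame (see [compute_band_metrics()]).
#' @export
compute_metrics_from_dir <- function(dir, config = welch_config()) {
  files <- sort(list.files(dir, pattern = "_timeseries\\.tsv$"))
  if (!length(files))
    abort_painattn(sprintf("no series files in %s", dir), "io_error")
  sids <- sub("_timeseries\\.tsv$", "", files)
  out <- do.call(rbind, lapply(sids, function(sid) {
    sr <- read_roi_series(dir, sid)
    do.call(rbind, lapply(colnames(sr$mat), function(r)
      compute_band_metrics(
        roi_timeseries(sr$mat[, r], fs = sr$fs, subject_id = sid, roi = r),
        config = config)))
  }))
  rownames(out) <- NULL
  out
}
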