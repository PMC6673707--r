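# Long-format shell-record table I/O.
#
# One row per participant x tract x WMH type x distance. Column order is
# fixed so that test diffs and checksums are deterministic. Missing means
# (empty shells) are written as empty fields and read back as NA.

.record_columns <- c("participant", "tract", "wmh_type", "distance_mm",
                     "n_voxels", "mean_fa", "mean_md", "excluded_csf")

empty_records <- function() {
  data.frame(
    participant = character(), tract = character(), wmh_type = character(),
    distance_mm = numeric(), n_voxels = integer(),
    mean_fa = numeric(), mean_md = numeric(), excluded_csf = logical(),
    stringsAsFactors = FALSE
  )
}

validate_records <- function(records) {
  if (!is.data.frame(records))
    stop("`records` must be a data.frame of shell records")
  missing_cols <- setdiff(.record_columns, names(records))
  if (length(missing_cols) > 0L)
    stop(sprintf("records are missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  records[, .record_columns, drop = FALSE]
}

#' Write shell records to CSV
#'
#' Comma-delimited UTF-8 with one header row and the fixed column order
#' (participant, tract, wmh_type, distance_mm, n_voxels, mean_fa, mean_md,
#' excluded_csf). Missing means are empty fields. Floats are written with
#' full precision (17 significant digits) so [read_records()] round-trips
#' them exactly.
#'
#' @param records shell-record data.frame (see [assemble_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  out <- records
  for (col in c("distance_mm", "mean_fa", "mean_md")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  out$excluded_csf <- ifelse(records$excluded_csf, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read shell records written by [write_records()]
#'
#' @param path CSV path.
#' @return Shell-record data.frame with the canonical column types.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          participant = "character", tract = "character",
                          wmh_type = "character", distance_mm = "numeric",
                          n_voxels = "integer", mean_fa = "numeric",
                          mean_md = "numeric", excluded_csf = "logical"))
  validate_records(df)
}
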