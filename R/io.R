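## Reading and writing the standard tables. CSV is the reference format
## (ISO-8601 UTC timestamps); Parquet is used when the file extension is
## .parquet and the arrow package is available.

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

is_parquet <- function(path) grepl("\\.parquet$", path, ignore.case = TRUE)

need_arrow <- function() {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stopf("Parquet input/output requires the 'arrow' package; use .csv instead")
  }
}

write_table <- function(df, path, time_cols) {
  for (cc in intersect(time_cols, names(df))) df[[cc]] <- fmt_time(df[[cc]])
  if (is_parquet(path)) {
    need_arrow()
    arrow::write_parquet(df, path)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
}

read_table <- function(path, time_cols) {
  df <- if (is_parquet(path)) {
    need_arrow()
    as.data.frame(arrow::read_parquet(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  for (cc in intersect(time_cols, names(df))) df[[cc]] <- parse_time(df[[cc]])
  df
}

#' Write / read an event table
#'
#' @param events event table; `path` ends in `.csv` or `.parquet`.
#' @param path file path.
#' @export
write_events <- function(events, path) write_table(events, path, "time")

#' @rdname write_events
#' @export
read_events <- function(path) read_table(path, "time")

#' Write / read a static table
#'
#' @param statics static table; `path` ends in `.csv` or `.parquet`.
#' @param path file path.
#' @export
write_statics <- function(statics, path) {
  write_table(statics, path, c("admission_time", "discharge_time", "death_time"))
}

#' @rdname write_statics
#' @export
read_statics <- function(path) {
  read_table(path, c("admission_time", "discharge_time", "death_time"))
}

#' Write a generated cohort to a directory
#'
#' Writes `events`, `statics` and `truth` as CSV (or Parquet with
#' `format = "parquet"`).
#'
#' @param cohort a `generated_cohort`, see [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "parquet") ".parquet" else ".csv"
  write_events(cohort$events, file.path(dir, paste0("events", ext)))
  write_statics(cohort$statics, file.path(dir, paste0("statics", ext)))
  write_table(cohort$truth, file.path(dir, paste0("truth", ext)), character())
  invisible(dir)
}
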