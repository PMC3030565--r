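#' Build a TDR record
#'
#' A TDR record holds a regularly sampled diving-depth time series as a
#' tibble with a `time` column (POSIXct, seconds precision), a `depth`
#' column (metres, positive downwards, `NA` allowed) and zero or more
#' named concurrent sensor series (e.g. light, temperature) of the same
#' length. The sampling interval in seconds is carried as an attribute
#' and inferred from the timestamps.
#'
#' Timestamps must be strictly increasing. If consecutive differences are
#' not all equal, the record is still built — the filters are index-based
#' and never resample — but a warning reports the irregularity and the
#' modal difference is used as the sampling interval.
#'
#' @param time POSIXct vector, or numeric seconds since the epoch.
#' @param depth numeric vector of depths in metres; `NA` marks missing.
#' @param ... named numeric vectors of concurrent sensor series.
#' @param source_name free-text provenance label.
#' @return A tibble of class `tdr_tbl` with attributes
#'   `sampling_interval` (seconds) and `source_name`.
#' @examples
#' tdr_record(seq(0, 20, by = 5), c(0, 1, 2, 1, 0))
#' @export
tdr_record <- function(time, depth, ..., source_name = "") {
  if (is.numeric(time)) {
    time <- as.POSIXct(time, origin = "1970-01-01", tz = "UTC")
  }
  if (!inherits(time, "POSIXct")) {
    abort_usage("`time` must be POSIXct or numeric seconds.")
  }
  n <- length(time)
  if (n < 1L) abort_usage("A TDR record needs at least one sample.")
  depth <- as.double(depth)
  if (length(depth) != n) {
    abort_data("`depth` and `time` must have equal length.")
  }
  concurrent <- list(...)
  if (length(concurrent) > 0 &&
      (is.null(names(concurrent)) || any(names(concurrent) == ""))) {
    abort_usage("Concurrent series must be named.")
  }
  for (nm in names(concurrent)) {
    if (length(concurrent[[nm]]) != n) {
      abort_data(sprintf("Concurrent series `%s` has length %d, expected %d.",
                         nm, length(concurrent[[nm]]), n))
    }
  }
  dts <- diff(as.numeric(time))
  if (n > 1L && any(dts <= 0)) {
    abort_data("Timestamps must be strictly increasing.")
  }
  interval <- if (n > 1L) modal_value(dts) else 1
  if (n > 2L && length(unique(dts)) > 1L) {
    warn(sprintf(
      "Irregular sampling: %d of %d intervals differ from the modal %g s; filters are index-based and the record is kept as is.",
      sum(dts != interval), length(dts), interval),
      class = "divezoc_irregular_sampling")
  }
  out <- tibble(time = time, depth = depth, !!!concurrent)
  new_tdr_tbl(out, sampling_interval = interval, source_name = source_name)
}

new_tdr_tbl <- function(df, sampling_interval, source_name = "") {
  structure(df,
            sampling_interval = sampling_interval,
            source_name = source_name,
            class = c("tdr_tbl", class(tibble())))
}

#' @export
print.tdr_tbl <- function(x, ...) {
  cat(sprintf("# TDR record: %d samples @ %g s", nrow(x), sampling_interval(x)))
  src <- attr(x, "source_name")
  if (nzchar(src)) cat(sprintf(" [%s]", src))
  cat("\n")
  conc <- setdiff(names(x), c("time", "depth"))
  if (length(conc)) cat("# Concurrent:", paste(conc, collapse = ", "), "\n")
  NextMethod()
}

#' Sampling interval of a TDR record
#'
#' @param record a `tdr_tbl`.
#' @return Interval between consecutive samples, in seconds.
#' @export
sampling_interval <- function(record) {
  attr(record, "sampling_interval")
}

#' Names of concurrent sensor series in a record
#' @param record a `tdr_tbl`.
#' @return Character vector (possibly empty).
#' @export
concurrent_vars <- function(record) {
  setdiff(names(record), c("time", "depth"))
}

#' Extract a contiguous span of a TDR record
#'
#' Spans are 1-based and inclusive at both ends, the convention used for
#' all index spans in this package. All columns are sliced identically
#' and the sampling interval is preserved.
#'
#' @param record a `tdr_tbl`.
#' @param start,end first and last sample index to keep (inclusive).
#' @return A `tdr_tbl` with `end - start + 1` samples.
#' @examples
#' r <- tdr_record(seq(0, 45, by = 5), 0:9)
#' tdr_subset(r, 3, 7)
#' @export
tdr_subset <- function(record, start, end) {
  span <- check_span(start, end, nrow(record))
  out <- dplyr::slice(as_tibble(record), span[1]:span[2])
  new_tdr_tbl(out, sampling_interval(record), attr(record, "source_name"))
}

#' Read a TDR record from CSV
#'
#' The column layout varies between instrument exports, so it is mapped
#' explicitly rather than guessed. Timestamps may live in a single
#' ISO-8601-style column, or in separate date and time columns
#' (`date_col` + `time_col`), or in a numeric seconds column. Empty
#' fields, `"NA"` and `"NaN"` are read as missing depth; rows whose
#' depth fails to parse as a number become missing depth rather than
#' being dropped, so the series stays regularly indexed.
#'
#' @param path CSV file with a header row.
#' @param depth_col name of the depth column (metres).
#' @param time_col name of the timestamp (or clock-time) column.
#' @param date_col optional name of a separate date column; when given,
#'   `time_col` holds the clock time and the two are pasted together.
#' @param concurrent_cols optional character vector of concurrent sensor
#'   column names to carry along.
#' @param tz time zone for parsing; defaults to UTC.
#' @return A [tdr_record()] tibble.
#' @export
read_tdr_csv <- function(path, depth_col = "depth", time_col = "time",
                         date_col = NULL, concurrent_cols = NULL,
                         tz = "UTC") {
  if (!file.exists(path)) abort_usage(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  needed <- c(time_col, date_col, depth_col, concurrent_cols)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort_usage(sprintf("Column(s) not in %s: %s", path,
                        paste(missing_cols, collapse = ", ")))
  }
  ts_chr <- if (is.null(date_col)) raw[[time_col]] else {
    paste(raw[[date_col]], raw[[time_col]])
  }
  time <- parse_timestamps(ts_chr, tz = tz)
  depth <- parse_depth(raw[[depth_col]])
  conc <- lapply(raw[concurrent_cols], parse_depth)
  names(conc) <- concurrent_cols
  rlang::exec(tdr_record, time = time, depth = depth, !!!conc,
              source_name = basename(path))
}

parse_timestamps <- function(x, tz = "UTC") {
  x <- trimws(x)
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) {
    return(as.POSIXct(num, origin = "1970-01-01", tz = tz))
  }
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                "%Y/%m/%d %H:%M:%S", "%d/%m/%Y %H:%M:%S")) {
    parsed <- as.POSIXct(x, format = fmt, tz = tz)
    if (!anyNA(parsed)) return(parsed)
  }
  abort_data("Could not parse timestamps: unrecognised format.")
}

parse_depth <- function(x) {
  x <- trimws(x)
  x[x %in% c("", "NA", "NaN", "nan")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Write a TDR record to CSV
#'
#' Writes `time` (as `YYYY-MM-DD HH:MM:SS`), `depth` and any concurrent
#' columns, with missing values as empty fields. Numeric values are
#' written at full precision, so `read_tdr_csv()` on the result
#' reproduces the record exactly (timestamps) and to stored precision
#' (depth, concurrent series).
#'
#' @param record a `tdr_tbl`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tdr_csv <- function(record, path) {
  df <- as_tibble(record)
  df$time <- format(df$time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' @method autoplot tdr_tbl
#' @export
autoplot.tdr_tbl <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.2, na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Depth (m)") +
    ggplot2::theme_minimal()
}
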