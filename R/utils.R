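# Classed conditions so callers (and the CLI) can distinguish bad
# arguments/usage from bad data.

abort_usage <- function(msg, ...) {
  abort(msg, class = "divezoc_usage_error", ...)
}

abort_data <- function(msg, ...) {
  abort(msg, class = "divezoc_data_error", ...)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort_usage(sprintf("`%s` must be a single number in [%s, %s].",
                        name, format(min), format(max)))
  }
  invisible(x)
}

check_span <- function(start, end, n, name = "span") {
  if (!is.numeric(start) || !is.numeric(end) || length(start) != 1L ||
      length(end) != 1L || is.na(start) || is.na(end)) {
    abort_usage(sprintf("`%s` start/end must be single numbers.", name))
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (start < 1L || end < start || (!is.null(n) && end > n)) {
    abort_usage(sprintf(
      "`%s` must satisfy 1 <= start <= end%s (got %d..%d).",
      name, if (is.null(n)) "" else sprintf(" <= %d", n), start, end))
  }
  c(start, end)
}

# Most-frequent value of a numeric vector; ties broken by the smaller value.
modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  as.numeric(names(tab)[1L])
}
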