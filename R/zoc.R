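#' Recursive moving-quantile zero-offset correction
#'
#' Estimates the wandering surface level of a depth series by chaining
#' running-quantile filters and subtracting the final estimate from the
#' input. Step 1 filters the raw depth with window `k[1]` and quantile
#' `probs[1]`; each later step filters the previous step's output. Two
#' steps usually suffice: a narrow median to knock down noise, then a
#' wide low quantile to track the surface level through drifts and level
#' shifts.
#'
#' When `depth_bounds` is given, each step only filters the samples of
#' its input series that lie inside `[lower, upper]` — the band where
#' the surface is expected. Samples outside the band (dives, spikes) are
#' set aside and the step's output at those positions is filled by
#' linear interpolation between the nearest in-band outputs, so every
#' step's output has full length. The band membership is re-evaluated on
#' each step's own input series.
#'
#' When `na_rm = TRUE`, missing samples are removed before filtering,
#' the compacted series is filtered, and outputs are reinserted at the
#' original positions; missing positions stay missing in every step's
#' output. This speeds things up but is only appropriate when the gaps
#' do not hide a change in the surface trend. With `na_rm = FALSE`
#' (default) missing samples stay in place and each window simply
#' computes its quantile over whatever observations it holds.
#'
#' The corrected depth is `depth - surface` where `surface` is the last
#' step's output; it is missing wherever the input or the surface
#' estimate is missing. Since the surface estimate bisects the residual
#' noise, corrected surface readings straddle zero; `clamp_negative`
#' optionally zeroes the negative ones afterwards (an analyst's choice,
#' off by default — if used, downstream dive thresholds should exceed
#' the residual error).
#'
#' @param depth numeric depth series in metres, positive downwards;
#'   `NA` marks missing samples.
#' @param k integer vector of window widths in samples, one per step.
#' @param probs numeric vector of quantile fractions in `[0, 1]`, one
#'   per step, same length as `k`.
#' @param depth_bounds optional `c(lower, upper)` in metres with
#'   `lower < upper`: the band where the surface signal is expected.
#' @param na_rm remove missing samples before filtering?
#' @param clamp_negative set negative corrected depths to zero?
#' @return An object of class `zoc_filter`: a list with `input`, `steps`
#'   (list of full-length per-step outputs), `surface` (the last step's
#'   output), `corrected`, the parameters, and per-step timings in
#'   seconds. Supports [tidy()], [glance()], [augment()], `autoplot()`
#'   and [write_filter_csv()].
#' @examples
#' d <- c(rep(0, 30), 5, 12, 20, 12, 5, rep(0, 30)) + 0.5
#' f <- depth_filter(d, k = c(5, 21), probs = c(0.5, 0.25))
#' range(f$corrected)
#' @export
depth_filter <- function(depth, k, probs, depth_bounds = NULL,
                         na_rm = FALSE, clamp_negative = FALSE) {
  depth <- as.double(depth)
  n <- length(depth)
  if (n < 1L) abort_usage("`depth` must have at least one sample.")
  if (length(k) != length(probs) || length(k) == 0L) {
    abort_usage("`k` and `probs` must be non-empty vectors of equal length.")
  }
  purrr::walk2(k, probs, check_window)
  if (!is.null(depth_bounds)) {
    if (!is.numeric(depth_bounds) || length(depth_bounds) != 2L ||
        anyNA(depth_bounds) || depth_bounds[1] >= depth_bounds[2]) {
      abort_usage("`depth_bounds` must be c(lower, upper) with lower < upper.")
    }
  }

  obs <- if (na_rm) !is.na(depth) else rep(TRUE, n)
  cur <- depth[obs]
  steps <- vector("list", length(k))
  timings <- numeric(length(k))

  for (s in seq_along(k)) {
    t0 <- proc.time()[["elapsed"]]
    if (is.null(depth_bounds)) {
      out <- run_quantile(cur, k[s], probs[s])
    } else {
      in_band <- !is.na(cur) & cur >= depth_bounds[1] & cur <= depth_bounds[2]
      if (!any(in_band)) {
        abort_data(sprintf(
          "No samples within depth_bounds [%g, %g] at step %d: nothing to anchor the surface estimate.",
          depth_bounds[1], depth_bounds[2], s))
      }
      masked <- cur
      masked[!in_band] <- NA_real_
      out <- run_quantile(masked, k[s], probs[s])
      out <- interpolate_out_of_bounds(out, in_band)
    }
    cur <- out
    full <- rep(NA_real_, n)
    full[obs] <- out
    steps[[s]] <- full
    timings[s] <- proc.time()[["elapsed"]] - t0
  }

  surface <- steps[[length(steps)]]
  corrected <- depth - surface
  if (clamp_negative) corrected <- pmax(corrected, 0)

  structure(
    list(input = depth, steps = steps, surface = surface,
         corrected = corrected, k = as.integer(k), probs = as.double(probs),
         depth_bounds = depth_bounds, na_rm = na_rm,
         clamp_negative = clamp_negative, timings = timings),
    class = "zoc_filter")
}

#' Linear interpolation across masked-out positions
#'
#' Positions where `in_bounds` is `TRUE` keep their value; each maximal
#' run of `FALSE` positions is replaced by linear interpolation (in
#' sample index) between the nearest `TRUE` neighbours. Runs touching a
#' series end are filled with the nearest kept value (constant
#' extension — extrapolating a trend off the end of the record is not
#' defensible). Used after each bounded filter step so that step outputs
#' keep full length.
#'
#' @param x numeric series.
#' @param in_bounds logical series of the same length; at least one
#'   `TRUE` required.
#' @return Numeric series of `length(x)`.
#' @examples
#' interpolate_out_of_bounds(c(0, 9, 9, 3), c(TRUE, FALSE, FALSE, TRUE))
#' @export
interpolate_out_of_bounds <- function(x, in_bounds) {
  if (length(x) != length(in_bounds)) {
    abort_usage("`x` and `in_bounds` must have equal length.")
  }
  in_bounds <- as.logical(in_bounds)
  if (anyNA(in_bounds)) abort_usage("`in_bounds` must not contain NA.")
  if (!any(in_bounds)) {
    abort_data("All positions masked out: nothing to interpolate from.")
  }
  if (all(in_bounds)) return(x)
  knots <- which(in_bounds & !is.na(x))
  if (length(knots) == 0L) return(x)
  out <- if (length(knots) == 1L) {
    rep(x[knots], length(x))
  } else {
    approx(knots, x[knots], xout = seq_along(x), rule = 2)$y
  }
  out[in_bounds] <- x[in_bounds]
  out
}

#' Zero-offset-correct a TDR record
#'
#' Record-level wrapper around [depth_filter()]: the returned record is
#' identical to the input except that `depth` holds the corrected
#' series; concurrent columns and timestamps are untouched. The full
#' `zoc_filter` fit travels along as the `"zoc_fit"` attribute,
#' retrievable with [zoc_fit()], so the call chains naturally:
#' `record |> correct_depth(k = c(12, 720), probs = c(0.5, 0.35))`.
#'
#' @param record a `tdr_tbl` from [tdr_record()] or [read_tdr_csv()].
#' @inheritParams depth_filter
#' @return The corrected `tdr_tbl` with attribute `zoc_fit`.
#' @export
correct_depth <- function(record, k, probs, depth_bounds = NULL,
                          na_rm = FALSE, clamp_negative = FALSE) {
  if (!inherits(record, "tdr_tbl")) abort_usage("`record` must be a tdr_tbl.")
  fit <- depth_filter(record$depth, k = k, probs = probs,
                      depth_bounds = depth_bounds, na_rm = na_rm,
                      clamp_negative = clamp_negative)
  out <- record
  out$depth <- fit$corrected
  attr(out, "zoc_fit") <- fit
  out
}

#' Retrieve the filter fit attached by [correct_depth()]
#' @param record a corrected `tdr_tbl`.
#' @return The `zoc_filter` object, or `NULL` if none is attached.
#' @export
zoc_fit <- function(record) {
  attr(record, "zoc_fit")
}

#' Export a filter fit as an audit CSV
#'
#' Writes one row per sample with the input depth, every intermediate
#' filter output, the surface estimate and the corrected depth, so a
#' correction can be inspected column by column.
#'
#' @param fit a `zoc_filter`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_csv <- function(fit, path) {
  readr::write_csv(augment(fit), path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.zoc_filter <- function(x, ...) {
  cat(sprintf("Zero-offset correction: %d samples, %d filter step(s)\n",
              length(x$input), length(x$k)))
  for (s in seq_along(x$k)) {
    cat(sprintf("  step %d: k = %d, p = %g  (%.2f s)\n",
                s, x$k[s], x$probs[s], x$timings[s]))
  }
  if (!is.null(x$depth_bounds)) {
    cat(sprintf("  surface band: [%g, %g] m\n",
                x$depth_bounds[1], x$depth_bounds[2]))
  }
  ok <- !is.na(x$corrected)
  cat(sprintf("  corrected depth range: [%.2f, %.2f] m (%d missing)\n",
              min(x$corrected[ok]), max(x$corrected[ok]), sum(!ok)))
  invisible(x)
}
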