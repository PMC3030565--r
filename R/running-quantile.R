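#' Center-aligned running quantile with missing-data windows
#'
#' For each position `i`, returns the `p`-quantile of the non-missing
#' values in the fixed-width window of `k` samples centred at `i`. The
#' window keeps its nominal width regardless of how many of its samples
#' are missing: the quantile is computed over the `k - m` observations
#' present, where `m` is the window's missing count, and is itself
#' missing when every sample in the window is missing. At the series
#' ends the window is clipped to the available samples.
#'
#' Conventions, fixed and relied on throughout the package:
#' * the window at `i` covers indices `i - floor((k-1)/2)` to
#'   `i + floor(k/2)`, so even widths take the extra sample on the right;
#' * quantiles interpolate linearly between order statistics (the
#'   continuous "type 7" definition, [stats::quantile()]'s default) —
#'   small fractions such as `p = 0.35` on narrow windows are sensitive
#'   to this choice, so it is pinned rather than configurable.
#'
#' @param x numeric series; `NA`/`NaN` mark missing samples.
#' @param k window width in samples (positive integer).
#' @param p quantile fraction in `[0, 1]`; `0` gives a running minimum,
#'   `0.5` a running median, `1` a running maximum.
#' @return Numeric series of `length(x)`.
#' @seealso [brute_force_quantile()] for the reference implementation
#'   used to cross-check this one.
#' @examples
#' run_quantile(c(1, 5, 2, 8, 3), k = 3, p = 0.5)
#' run_quantile(c(0, 0, NA, NA, 3, 3), k = 4, p = 0.5)
#' @export
run_quantile <- function(x, k, p) {
  check_window(k, p)
  x <- as.double(x)
  if (length(x) == 0L) return(numeric(0))
  run_quantile_cpp(x, as.integer(k), as.double(p))
}

#' Reference running quantile by per-window sorting
#'
#' Same contract as [run_quantile()], computed the slow, obviously
#' correct way: each window is collected explicitly, missing values are
#' dropped, and the quantile is taken with [stats::quantile()] (type 7).
#' Exists as the independent oracle the fast implementation is tested
#' against; use [run_quantile()] for real work.
#'
#' @inheritParams run_quantile
#' @return Numeric series of `length(x)`.
#' @export
brute_force_quantile <- function(x, k, p) {
  check_window(k, p)
  x <- as.double(x)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  dl <- (k - 1L) %/% 2L
  dr <- k %/% 2L
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - dl):min(n, i + dr)]
    w <- w[!is.na(w)]
    if (length(w) == 0L) return(NA_real_)
    unname(quantile(w, probs = p, type = 7, names = FALSE))
  }, double(1))
}

check_window <- function(k, p) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    abort_usage("`k` must be a single positive integer window width.")
  }
  check_scalar_number(p, "p", min = 0, max = 1)
  invisible(TRUE)
}
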