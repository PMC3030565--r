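#' Root mean square error between aligned series
#'
#' `sqrt(mean((corrected - clean)^2))` over the positions where both
#' series are observed (pairwise deletion). When a correction has done
#' its job, this approaches the standard deviation of the measurement
#' noise: the offset has been removed and only the noise remains.
#'
#' @param corrected,clean numeric series of equal length.
#' @return RMSE in the series' units (metres for depth).
#' @examples
#' rmse(c(3, -4), c(0, 0))  # sqrt(25/2)
#' @export
rmse <- function(corrected, clean) {
  ok <- comparable(corrected, clean)
  sqrt(mean((corrected[ok] - clean[ok])^2))
}

#' Kolmogorov-Smirnov test of deviations against the injected noise
#'
#' One-sample, two-sided KS test of the deviations
#' `corrected - clean` against a `Normal(0, sigma^2)` reference — the
#' distribution the deviations would follow if the correction removed
#' the offset perfectly and left only the injected noise. Uses the
#' asymptotic p-value (the intended sample sizes are in the tens of
#' thousands).
#'
#' @inheritParams rmse
#' @param sigma reference noise standard deviation (`> 0`).
#' @return A list with `statistic` (D, in `[0, 1]`) and `p.value`.
#' @export
deviation_ks <- function(corrected, clean, sigma) {
  check_scalar_number(sigma, "sigma", min = .Machine$double.xmin)
  ok <- comparable(corrected, clean)
  dev <- corrected[ok] - clean[ok]
  kt <- suppressWarnings(ks.test(dev, "pnorm", 0, sigma, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

comparable <- function(corrected, clean) {
  if (length(corrected) != length(clean)) {
    abort_usage("`corrected` and `clean` must have equal length.")
  }
  ok <- !is.na(corrected) & !is.na(clean)
  if (!any(ok)) abort_data("No jointly non-missing samples to compare.")
  ok
}

#' Evaluate a correction against a known clean record
#'
#' Bundles [rmse()], a summary of the deviation distribution and
#' [deviation_ks()] into one report. Records must be aligned sample for
#' sample (identical timestamps); positions missing in either record are
#' excluded and counted via `n_compared`.
#'
#' @param clean the ground-truth `tdr_tbl`.
#' @param corrected the corrected `tdr_tbl` (e.g. from
#'   [correct_depth()]).
#' @param sigma the injected noise standard deviation, the reference for
#'   the KS comparison.
#' @return A one-row tibble of class `zoc_eval`: `rmse`, `n_compared`,
#'   deviation mean/sd/min/quartiles/max, `ks_statistic`, `ks_pvalue`,
#'   `sigma`. The deviations themselves are carried in the
#'   `"deviations"` attribute for plotting.
#' @export
evaluate_correction <- function(clean, corrected, sigma) {
  if (!inherits(clean, "tdr_tbl") || !inherits(corrected, "tdr_tbl")) {
    abort_usage("`clean` and `corrected` must be tdr_tbl records.")
  }
  if (nrow(clean) != nrow(corrected) ||
      !isTRUE(all.equal(as.numeric(clean$time), as.numeric(corrected$time)))) {
    abort_data("Records are not aligned: timestamps differ.")
  }
  ok <- comparable(corrected$depth, clean$depth)
  dev <- corrected$depth[ok] - clean$depth[ok]
  qs <- unname(quantile(dev, c(0.25, 0.5, 0.75), type = 7))
  kt <- deviation_ks(corrected$depth, clean$depth, sigma)
  out <- tibble(
    rmse = sqrt(mean(dev^2)),
    n_compared = sum(ok),
    dev_mean = mean(dev),
    dev_sd = sd(dev),
    dev_min = min(dev),
    dev_q25 = qs[1],
    dev_median = qs[2],
    dev_q75 = qs[3],
    dev_max = max(dev),
    ks_statistic = kt$statistic,
    ks_pvalue = kt$p.value,
    sigma = sigma)
  structure(out, deviations = dev,
            class = c("zoc_eval", class(out)))
}

#' @export
print.zoc_eval <- function(x, ...) {
  cat(sprintf(
    "Correction evaluation over %d samples\n  RMSE: %.4f m (injected sigma %.3g m)\n  deviations: mean %.4f, sd %.4f, range [%.3f, %.3f]\n  KS vs N(0, sigma^2): D = %.4f, p = %.3g\n",
    x$n_compared, x$rmse, x$sigma, x$dev_mean, x$dev_sd,
    x$dev_min, x$dev_max, x$ks_statistic, x$ks_pvalue))
  invisible(x)
}
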