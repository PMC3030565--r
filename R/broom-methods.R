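#' Tidiers for zero-offset-correction fits
#'
#' `tidy()` returns one row per filter step with its parameters and an
#' output summary; `glance()` a one-row model summary; `augment()` the
#' full per-sample table (input, each step's output, surface estimate,
#' corrected depth) — the audit table [write_filter_csv()] exports.
#'
#' @param x a `zoc_filter` from [depth_filter()].
#' @param ... unused, for generic consistency.
#' @return A tibble.
#' @name zoc_filter_tidiers
NULL

#' @rdname zoc_filter_tidiers
#' @method tidy zoc_filter
#' @export
tidy.zoc_filter <- function(x, ...) {
  purrr::map2_dfr(seq_along(x$steps), x$steps, function(s, out) {
    ok <- !is.na(out)
    tibble(step = s, k = x$k[s], p = x$probs[s],
           n_missing = sum(!ok),
           min = if (any(ok)) min(out[ok]) else NA_real_,
           median = if (any(ok)) median(out[ok]) else NA_real_,
           max = if (any(ok)) max(out[ok]) else NA_real_)
  })
}

#' @rdname zoc_filter_tidiers
#' @method glance zoc_filter
#' @export
glance.zoc_filter <- function(x, ...) {
  ok <- !is.na(x$corrected)
  tibble(
    n = length(x$input),
    n_steps = length(x$k),
    bounded = !is.null(x$depth_bounds),
    na_rm = x$na_rm,
    clamped = x$clamp_negative,
    surface_min = min(x$surface, na.rm = TRUE),
    surface_max = max(x$surface, na.rm = TRUE),
    corrected_min = if (any(ok)) min(x$corrected[ok]) else NA_real_,
    corrected_max = if (any(ok)) max(x$corrected[ok]) else NA_real_,
    n_missing_corrected = sum(!ok),
    elapsed = sum(x$timings))
}

#' @rdname zoc_filter_tidiers
#' @method augment zoc_filter
#' @export
augment.zoc_filter <- function(x, ...) {
  steps <- x$steps
  names(steps) <- paste0("step_", seq_along(steps))
  tibble(index = seq_along(x$input), input = x$input, !!!steps,
         surface = x$surface, corrected = x$corrected)
}

#' Tidiers for correction evaluations
#'
#' `glance()` returns the evaluation as a plain one-row tibble;
#' `tidy()` a long table of the deviation summary statistics.
#'
#' @param x a `zoc_eval` from [evaluate_correction()].
#' @param ... unused.
#' @return A tibble.
#' @name zoc_eval_tidiers
NULL

#' @rdname zoc_eval_tidiers
#' @method glance zoc_eval
#' @export
glance.zoc_eval <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname zoc_eval_tidiers
#' @method tidy zoc_eval
#' @export
tidy.zoc_eval <- function(x, ...) {
  glance(x) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "statistic",
                        values_to = "value")
}
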