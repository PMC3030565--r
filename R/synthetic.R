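#' Simulate a clean multi-bout dive record
#'
#' Generates a regularly sampled depth series emulating an archival-tag
#' deployment on a diving marine animal: bouts of piecewise-linear
#' descent–bottom–ascent dives separated by surface intervals, longer
#' surface periods between bouts, and a dry (hauled-out) period splitting
#' the record into two trips. Depth is exactly 0 at the surface and
#' during the dry period, and non-negative everywhere, so the record is
#' free of transducer error by construction and serves as ground truth
#' for parameter-recovery experiments (see [corrupt_tdr()]).
#'
#' Dive geometry is deliberately simple — zero-offset correction only
#' ever looks at the surface signal, so V/U dive shapes are adequate and
#' shape realism is out of scope. Defaults emulate an otariid-style
#' record: 5 s sampling, 60,000 samples (~3.5 d), dives of 10–80 m
#' lasting ~1–3.5 min, surface intervals of 1–10 min, and a dry period
#' over the middle tenth of the record.
#'
#' @param n_samples record length in samples.
#' @param sampling_interval seconds between samples.
#' @param n_dives maximum number of dives to place (`Inf` fills the
#'   record; `0` gives an all-zero depth series).
#' @param depth_range metres, `c(min, max)` of per-dive maximum depth.
#' @param descent_range,bottom_range,ascent_range seconds, duration
#'   ranges of the three dive phases.
#' @param surface_range seconds, `c(min, max)` surface interval between
#'   dives within a bout.
#' @param dives_per_bout dives between longer inter-bout surface pauses.
#' @param interbout_range seconds, surface pause between bouts.
#' @param dry_period fraction-of-record `c(start, end)` held at exactly
#'   0 m (animal out of the water); `NULL` for none.
#' @param start_time POSIXct first timestamp.
#' @param seed integer seed; the same seed reproduces the record
#'   bit for bit. `NULL` uses (and advances) the session RNG.
#' @return A clean [tdr_record()].
#' @examples
#' r <- simulate_dives(n_samples = 5000, seed = 1)
#' max(r$depth)
#' @export
simulate_dives <- function(n_samples = 60000,
                           sampling_interval = 5,
                           n_dives = Inf,
                           depth_range = c(10, 80),
                           descent_range = c(20, 60),
                           bottom_range = c(10, 90),
                           ascent_range = c(20, 60),
                           surface_range = c(60, 600),
                           dives_per_bout = 8,
                           interbout_range = c(1200, 2400),
                           dry_period = c(0.45, 0.55),
                           start_time = as.POSIXct("2020-01-01", tz = "UTC"),
                           seed = NULL) {
  check_scalar_number(n_samples, "n_samples", min = 1)
  check_scalar_number(sampling_interval, "sampling_interval", min = 1e-9)
  for (nm in c("depth_range", "descent_range", "bottom_range",
               "ascent_range", "surface_range", "interbout_range")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] <= 0 ||
        r[2] < r[1]) {
      abort_usage(sprintf("`%s` must be positive c(min, max).", nm))
    }
  }
  min_dive_s <- descent_range[1] + bottom_range[1] + ascent_range[1]
  if (min_dive_s / sampling_interval > n_samples) {
    abort_usage("Shortest possible dive is longer than the record.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  n <- as.integer(n_samples)
  dt <- sampling_interval
  depth <- numeric(n)
  if (!is.null(dry_period)) {
    dry_lo <- max(1L, as.integer(round(dry_period[1] * n)))
    dry_hi <- min(n, as.integer(round(dry_period[2] * n)))
  } else {
    dry_lo <- n + 1L
    dry_hi <- 0L
  }

  i <- 1L + as.integer(round(runif(1, surface_range[1], surface_range[2]) / dt))
  placed <- 0L
  in_bout <- 0L
  while (i <= n && placed < n_dives) {
    if (i >= dry_lo && i <= dry_hi) {
      # hauled out: skip to the end of the dry period plus a surface interval
      i <- dry_hi + 1L +
        as.integer(round(runif(1, surface_range[1], surface_range[2]) / dt))
      in_bout <- 0L
      next
    }
    prof <- dive_profile(
      max_depth = runif(1, depth_range[1], depth_range[2]),
      descent_s = runif(1, descent_range[1], descent_range[2]),
      bottom_s = runif(1, bottom_range[1], bottom_range[2]),
      ascent_s = runif(1, ascent_range[1], ascent_range[2]),
      dt = dt)
    j <- i + length(prof) - 1L
    if (j > n) break
    if (i < dry_lo && j >= dry_lo) {
      i <- dry_hi + 1L
      in_bout <- 0L
      next
    }
    depth[i:j] <- prof
    placed <- placed + 1L
    in_bout <- in_bout + 1L
    pause_s <- if (in_bout >= dives_per_bout) {
      in_bout <- 0L
      runif(1, interbout_range[1], interbout_range[2])
    } else {
      runif(1, surface_range[1], surface_range[2])
    }
    i <- j + 1L + max(1L, as.integer(round(pause_s / dt)))
  }

  time <- start_time + dt * (seq_len(n) - 1)
  tdr_record(time, depth, source_name = "simulated")
}

# Piecewise-linear descent / flat bottom / linear ascent, in samples.
# First and last profile samples are strictly below the maximum and above
# the surface; the surrounding surface samples are exactly 0.
dive_profile <- function(max_depth, descent_s, bottom_s, ascent_s, dt) {
  nd <- max(1L, as.integer(round(descent_s / dt)))
  nb <- max(1L, as.integer(round(bottom_s / dt)))
  na_ <- max(1L, as.integer(round(ascent_s / dt)))
  c(max_depth * seq_len(nd) / nd,
    rep(max_depth, nb),
    max_depth * rev(seq_len(na_) - 1L) / na_)
}

#' Corruption operators
#'
#' Constructors for the operators [corrupt_tdr()] applies, emulating the
#' transducer pathologies zero-offset correction exists to remove. All
#' index spans are 1-based inclusive.
#'
#' * `op_noise(sigma)` — adds i.i.d. Gaussian noise `N(0, sigma^2)` to
#'   every sample.
#' * `op_drift(start, end, delta)` — adds a linear ramp running from 0
#'   at `start` to `delta` at `end` (slow temperature-driven baseline
#'   drift).
#' * `op_shift(start, end, offset)` — adds a constant `offset` over the
#'   span (an abrupt, sustained level shift).
#' * `op_gap(start, end)` — sets depth to missing over the span.
#'
#' @param sigma noise standard deviation in metres (`>= 0`).
#' @param start,end 1-based inclusive sample indices.
#' @param delta total drift in metres reached at `end`.
#' @param offset level shift in metres.
#' @return An object of class `corrupt_op`.
#' @name corrupt_ops
NULL

#' @rdname corrupt_ops
#' @export
op_noise <- function(sigma) {
  check_scalar_number(sigma, "sigma", min = 0)
  structure(list(sigma = sigma), class = c("op_noise", "corrupt_op"))
}

#' @rdname corrupt_ops
#' @export
op_drift <- function(start, end, delta) {
  span <- check_span(start, end, NULL, "drift span")
  check_scalar_number(delta, "delta")
  structure(list(start = span[1], end = span[2], delta = delta),
            class = c("op_drift", "corrupt_op"))
}

#' @rdname corrupt_ops
#' @export
op_shift <- function(start, end, offset) {
  span <- check_span(start, end, NULL, "shift span")
  check_scalar_number(offset, "offset")
  structure(list(start = span[1], end = span[2], offset = offset),
            class = c("op_shift", "corrupt_op"))
}

#' @rdname corrupt_ops
#' @export
op_gap <- function(start, end) {
  span <- check_span(start, end, NULL, "gap span")
  structure(list(start = span[1], end = span[2]),
            class = c("op_gap", "corrupt_op"))
}

#' Apply corruption operators to a record
#'
#' Applies the operators in the order given; the input record is never
#' modified (pure function). All operators are additive except `op_gap`,
#' which blanks depth over its span; noise added to a missing sample
#' stays missing.
#'
#' @param record a `tdr_tbl`.
#' @param ops a list of [corrupt_ops] objects (a bare `corrupt_op` is
#'   promoted to a length-1 list).
#' @param seed integer seed for the noise draw; `NULL` uses the session
#'   RNG.
#' @return The corrupted `tdr_tbl`.
#' @examples
#' r <- simulate_dives(n_samples = 2000, seed = 1)
#' bad <- corrupt_tdr(r, list(op_noise(1), op_drift(1, 2000, -2)), seed = 2)
#' @export
corrupt_tdr <- function(record, ops, seed = NULL) {
  if (!inherits(record, "tdr_tbl")) abort_usage("`record` must be a tdr_tbl.")
  if (inherits(ops, "corrupt_op")) ops <- list(ops)
  if (!is.list(ops) || !all(vapply(ops, inherits, logical(1), "corrupt_op"))) {
    abort_usage("`ops` must be a list of corruption operators (op_*).")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(record)
  d <- record$depth
  for (op in ops) {
    if (!inherits(op, "op_noise")) check_span(op$start, op$end, n)
    d <- apply_op(op, d)
  }
  out <- record
  out$depth <- d
  out
}

apply_op <- function(op, d) UseMethod("apply_op")

#' @export
apply_op.op_noise <- function(op, d) d + rnorm(length(d), 0, op$sigma)

#' @export
apply_op.op_drift <- function(op, d) {
  idx <- op$start:op$end
  d[idx] <- d[idx] + seq(0, op$delta, length.out = length(idx))
  d
}

#' @export
apply_op.op_shift <- function(op, d) {
  idx <- op$start:op$end
  d[idx] <- d[idx] + op$offset
  d
}

#' @export
apply_op.op_gap <- function(op, d) {
  d[op$start:op$end] <- NA_real_
  d
}

#' The package's benchmark corruption recipe
#'
#' The standard stress test used throughout the package's evaluation:
#' on a record of at least 60,000 samples, blank samples 36,000–42,000
#' (a recorder outage), then add unit-or-chosen-sigma Gaussian noise
#' everywhere, a linear drift from 0 down to −2 m over samples
#' 8,000–36,000 (the first trip), and a constant +3 m level shift over
#' samples 36,000–60,000 (the last trip). Note the drift and shift spans
#' share sample 36,000, where both apply; the shift begins inside the
#' blanked gap, so the transition itself is unobserved — the situation
#' the missing-gap filtering semantics exist for.
#'
#' Because the gap belongs to the record before any error is added, the
#' comparable ground truth is the clean record with the same gap:
#' `benchmark_corrupt()` returns both.
#'
#' @param record a clean `tdr_tbl` with `>= 60000` samples.
#' @param sigma noise standard deviation in metres.
#' @param seed integer seed for the noise draw.
#' @return `benchmark_ops()`: the operator list. `benchmark_corrupt()`:
#'   a list with elements `clean` (gap applied, no error) and
#'   `corrupted` (gap, noise, drift and shift applied).
#' @export
benchmark_ops <- function(sigma = 1) {
  list(op_gap(36000, 42000),
       op_noise(sigma),
       op_drift(8000, 36000, -2),
       op_shift(36000, 60000, 3))
}

#' @rdname benchmark_ops
#' @export
benchmark_corrupt <- function(record, sigma = 1, seed = NULL) {
  if (nrow(record) < 60000L) {
    abort_usage("The benchmark corruption needs a record of >= 60000 samples.")
  }
  list(clean = corrupt_tdr(record, list(op_gap(36000, 42000))),
       corrupted = corrupt_tdr(record, benchmark_ops(sigma), seed = seed))
}
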