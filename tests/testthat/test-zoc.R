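test_that("single unbounded step is exactly a running quantile; chaining composes", {
  set.seed(31)
  d <- abs(rnorm(300)) + c(rep(0, 150), rep(2, 150))
  f1 <- depth_filter(d, k = 7, probs = 0.5)
  expect_equal(f1$steps[[1]], run_quantile(d, 7, 0.5))
  expect_equal(f1$surface, f1$steps[[1]])
  f3 <- depth_filter(d, k = c(7, 15, 31), probs = c(0.5, 0.35, 0.1))
  manual <- run_quantile(run_quantile(run_quantile(d, 7, 0.5), 15, 0.35), 31, 0.1)
  expect_equal(f3$surface, manual)
  expect_equal(length(f3$steps), 3L)
})

test_that("corrected + surface reconstructs the input; missing propagates exactly", {
  set.seed(32)
  d <- rnorm(400, 1)
  d[c(10, 100:140)] <- NA
  f <- depth_filter(d, k = c(5, 25), probs = c(0.5, 0.35))
  ok <- !is.na(d) & !is.na(f$surface)
  expect_equal(f$corrected[ok] + f$surface[ok], d[ok])
  expect_identical(is.na(f$corrected), is.na(d) | is.na(f$surface))
  expect_true(all(lengths(f$steps) == length(d)))
})

test_that("constant-zero depth is left untouched", {
  f <- depth_filter(rep(0, 100), k = c(5, 21), probs = c(0.5, 0.35))
  expect_equal(f$surface, rep(0, 100))
  expect_equal(f$corrected, rep(0, 100))
})

test_that("a single median step flattens an unggapped two-level series away from the transition", {
  d <- c(rep(0, 40), rep(3, 40))
  f <- depth_filter(d, k = 5, probs = 0.5)
  zone <- 38:43  # within ceiling(k/2) samples of the transition
  expect_equal(f$corrected[-zone], rep(0, 80 - length(zone)))
  expect_equal(f$surface, brute_force_quantile(d, 5, 0.5))
})

test_that("out-of-bounds interpolation follows the stated edge rules", {
  expect_equal(interpolate_out_of_bounds(c(0, 9, 9, 3), c(TRUE, FALSE, FALSE, TRUE)),
               c(0, 1, 2, 3))
  x <- rnorm(6)
  expect_equal(interpolate_out_of_bounds(x, rep(TRUE, 6)), x)
  expect_equal(interpolate_out_of_bounds(c(7, 0, 0), c(FALSE, TRUE, TRUE)),
               c(0, 0, 0))
  expect_equal(interpolate_out_of_bounds(c(5, 5, 2), c(FALSE, FALSE, TRUE)),
               c(2, 2, 2))
  expect_error(interpolate_out_of_bounds(1:3, rep(FALSE, 3)),
               class = "divezoc_data_error")
  expect_error(interpolate_out_of_bounds(1:3, c(TRUE, TRUE)),
               class = "divezoc_usage_error")
})

test_that("filtering fails cleanly when no sample lies within the surface band", {
  expect_error(depth_filter(rep(50, 100), k = 5, probs = 0.5,
                            depth_bounds = c(-6, 8)),
               class = "divezoc_data_error")
})

test_that("samples outside the surface band cannot influence the estimate", {
  set.seed(33)
  clean <- simulate_dives(n_samples = 4000, seed = 5)
  d <- clean$depth + rnorm(4000, 0, 0.3)
  f0 <- depth_filter(d, k = c(12, 240), probs = c(0.5, 0.35),
                     depth_bounds = c(-6, 8))
  deep <- which(d > 8)
  expect_gt(length(deep), 100)
  d2 <- d
  d2[deep] <- d2[deep] + runif(length(deep), 10, 500)  # still out of band
  f2 <- depth_filter(d2, k = c(12, 240), probs = c(0.5, 0.35),
                     depth_bounds = c(-6, 8))
  expect_identical(f2$surface, f0$surface)
})

test_that("na_rm compacts, filters, reinserts, and keeps missing positions missing", {
  set.seed(34)
  d <- rnorm(200)
  gap <- 60:90
  d[gap] <- NA
  f <- depth_filter(d, k = c(5, 11), probs = c(0.5, 0.35), na_rm = TRUE)
  expect_true(all(is.na(f$surface[gap])))
  expect_true(all(is.na(f$corrected[gap])))
  manual <- run_quantile(run_quantile(d[-gap], 5, 0.5), 11, 0.35)
  expect_equal(f$surface[-gap], manual)
  # and combined with bounds, the band is evaluated on the compacted series
  d2 <- d
  d2[120:130] <- 50
  f2 <- depth_filter(d2, k = c(5, 11), probs = c(0.5, 0.35),
                     depth_bounds = c(-6, 8), na_rm = TRUE)
  expect_true(all(is.na(f2$surface[gap])))
  expect_true(all(!is.na(f2$surface[-gap])))
})

test_that("a level shift hidden by a long-enough gap is recovered outside a short transition zone", {
  k2 <- 100
  n <- 1500
  d <- rep(0, n)
  d[700:n] <- d[700:n] + 3          # shift
  d[640:699] <- NA                  # gap of 60 >= k2/2 samples just before it
  f <- depth_filter(d, k = c(5, k2), probs = c(0.5, 0.35))
  zone <- (700 - ceiling(k2 / 2)):(700 + ceiling(k2 / 2))
  ok <- setdiff(which(!is.na(d)), zone)
  expect_lt(max(abs(f$corrected[ok])), 0.1)
})

test_that("clamping zeroes negative corrected depths and nothing else", {
  set.seed(35)
  d <- rnorm(300)
  f <- depth_filter(d, k = c(5, 25), probs = c(0.5, 0.35))
  expect_lt(min(f$corrected, na.rm = TRUE), 0)
  fc <- depth_filter(d, k = c(5, 25), probs = c(0.5, 0.35),
                     clamp_negative = TRUE)
  expect_equal(min(fc$corrected), 0)
  pos <- which(f$corrected > 0)
  expect_equal(fc$corrected[pos], f$corrected[pos])
})

test_that("correct_depth swaps in corrected depth and leaves everything else alone", {
  r <- tdr_record(seq(0, by = 5, length.out = 200),
                  rep(c(0, 0, 0, 4, 9, 4, 0, 0, 0, 0), 20) + 1,
                  light = seq_len(200))
  out <- correct_depth(r, k = c(3, 21), probs = c(0.5, 0.25),
                       depth_bounds = c(-3, 3))
  expect_s3_class(out, "tdr_tbl")
  expect_identical(out$time, r$time)
  expect_identical(out$light, r$light)
  fit <- zoc_fit(out)
  expect_s3_class(fit, "zoc_filter")
  expect_equal(out$depth, fit$corrected)
  # constant-zero record: unchanged
  z <- tiny_record(rep(0, 50))
  expect_equal(correct_depth(z, k = 5, probs = 0.5)$depth, rep(0, 50))
})

test_that("mismatched or invalid parameters are usage errors", {
  expect_error(depth_filter(1:10, k = c(5, 7), probs = 0.5),
               class = "divezoc_usage_error")
  expect_error(depth_filter(1:10, k = integer(0), probs = numeric(0)),
               class = "divezoc_usage_error")
  expect_error(depth_filter(1:10, k = 5, probs = 0.5, depth_bounds = c(8, -6)),
               class = "divezoc_usage_error")
  expect_error(depth_filter(numeric(0), k = 5, probs = 0.5),
               class = "divezoc_usage_error")
})

test_that("RMSE against clean truth does not decrease as injected noise grows", {
  sigmas <- c(0, 0.5, 1, 2)
  mean_rmse <- sapply(sigmas, function(sig) {
    mean(sapply(1:10, function(s) {
      clean <- simulate_dives(n_samples = 12000, seed = s)
      ops <- list(op_gap(7000, 8000), op_noise(sig),
                  op_drift(2000, 7000, -2), op_shift(7000, 12000, 3))
      corrupted <- corrupt_tdr(clean, ops, seed = 500 + s)
      ref <- corrupt_tdr(clean, list(op_gap(7000, 8000)))
      f <- depth_filter(corrupted$depth, k = c(12, 720), probs = c(0.5, 0.35),
                        depth_bounds = c(-6, 8))
      rmse(f$corrected, ref$depth)
    }))
  })
  expect_true(all(diff(mean_rmse) >= 0))
})

test_that("fit tidiers and audit export expose the full stack", {
  set.seed(36)
  d <- rnorm(100)
  f <- depth_filter(d, k = c(5, 11), probs = c(0.5, 0.35))
  td <- tidy(f)
  expect_equal(nrow(td), 2)
  expect_equal(td$k, c(5L, 11L))
  gl <- glance(f)
  expect_equal(gl$n, 100)
  expect_equal(gl$n_steps, 2)
  aug <- augment(f)
  expect_identical(names(aug),
                   c("index", "input", "step_1", "step_2", "surface", "corrected"))
  expect_equal(aug$input, d)
  expect_equal(aug$corrected + aug$surface, d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_filter_csv(f, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(aug))
  expect_s3_class(autoplot(f), "ggplot")
})
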