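test_that("binning matches the standard intervals and percentage rounding", {
  # single late event
  one <- bin_onsets(400)
  expect_identical(one$pct[one$bin == "> 365 d"], 100)
  expect_identical(sum(one$n), 1L)

  set.seed(5)
  days <- sample(0:500, 400, replace = TRUE)
  bins <- bin_onsets(days)
  expect_identical(sum(bins$n), length(days))
  expect_lte(abs(sum(bins$pct) - 100), 0.05)   # rounding slack only
  expect_identical(attr(bins, "cum30_pct"), round_half_up(100 * mean(days <= 30), 2))
  expect_error(bin_onsets(numeric()), "no onset")
})

test_that("median and IQR use type-7 interpolation", {
  expect_identical(onset_median_iqr(c(1, 3, 7))$median, 3)
  expect_identical(onset_median_iqr(c(0, 0, 0, 10))$median, 0)
  set.seed(9)
  x <- rweibull(1000, 1.3, 12)
  m <- onset_median_iqr(x)
  # sort-based oracle for the type-7 quantile: interpolate order statistics
  oracle_q <- function(x, p) {
    s <- sort(x); h <- (length(s) - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  }
  expect_equal(m$median, oracle_q(x, 0.5))
  expect_equal(m$q1, oracle_q(x, 0.25))
  expect_equal(m$q3, oracle_q(x, 0.75))
})

test_that("Weibull MLE recovers known parameters", {
  set.seed(14)
  x <- rweibull(5000, 1, 10)          # exponential special case
  f <- weibull_fit(x)
  expect_true(f$converged)
  expect_gt(f$shape, 0.95); expect_lt(f$shape, 1.05)

  y <- rweibull(5000, 1.5, 10)
  g <- weibull_fit(y)
  expect_lt(abs(g$shape - 1.5) / 1.5, 0.05)
  expect_lt(abs(g$scale - 10) / 10, 0.05)
})

test_that("Weibull fit is scale-equivariant and matches an independent fitter", {
  set.seed(15)
  x <- rweibull(800, 0.9, 6) + 0.01
  f1 <- weibull_fit(x)
  f10 <- weibull_fit(x * 10)
  expect_equal(f10$shape, f1$shape, tolerance = 1e-6)
  expect_equal(f10$scale, 10 * f1$scale, tolerance = 1e-6)

  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(f1$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f1$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("zero-day handling follows the declared policy", {
  set.seed(16)
  x <- c(rep(0, 40), rweibull(200, 1.2, 8))
  shifted <- weibull_fit(x, "shift_half_day")
  dropped <- weibull_fit(x, "drop_zeros")
  expect_identical(shifted$n_used, length(x))
  expect_identical(dropped$n_used, length(x) - 40L)
  expect_identical(shifted$n_zeros, 40L)
  expect_error(weibull_fit(rep(0, 20), "drop_zeros"), "positive")
})

test_that("cumulative incidence is a proper step function matching the fit", {
  ci <- cumulative_incidence(c(0, 0, 1))
  expect_equal(ci$cum_frac, c(2 / 3, 1))
  expect_identical(ci$day, c(0, 1))

  set.seed(18)
  x <- floor(rweibull(1000, 1.4, 20))
  ci2 <- cumulative_incidence(x)
  expect_true(all(diff(ci2$cum_frac) > 0))
  expect_identical(ci2$cum_frac[nrow(ci2)], 1)
  fit <- weibull_fit(x)
  ks <- max(abs(ci2$cum_frac - pweibull(ci2$day + 0.5, fit$shape, fit$scale)))
  expect_lt(ks, 0.05)
})

test_that("onset collection separates usable samples from excluded reasons", {
  b <- generate_quarter(small_config(n_cases = 2000, seed = 25,
                                     onset_missing_rate = 0.3,
                                     false_date_rate = 0.05, partial_date_rate = 0.05))
  rep <- assemble_reports(b)
  col <- collect_onsets(rep)
  expect_setequal(col$exclusions$reason, c("missing", "negative", "partial"))
  expect_identical(nrow(col$samples) + sum(col$exclusions$n), nrow(rep$cases))
  expect_true(all(col$samples$onset_days >= 0))
  # generated truth: retained versions' usable onsets match the generator
  truth <- b$truth$onset_days[col$samples$caseid]
  expect_identical(unname(truth), col$samples$onset_days)
})
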