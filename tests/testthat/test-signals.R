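test_that("ROR closed form, symmetry, and zero-cell correction", {
  r <- ror_estimate(10, 20, 30, 240)
  expect_equal(r$ror, 4.0)
  expect_false(r$haldane)

  r1 <- ror_estimate(5, 5, 5, 5)
  expect_equal(r1$ror, 1.0)
  expect_equal(log(r1$ror_hi), -log(r1$ror_lo))  # CI symmetric about 1 on log scale

  r0 <- ror_estimate(0, 10, 10, 100)
  expect_true(r0$haldane)
  expect_equal(r0$ror, (0.5 * 100.5) / (10.5 * 10.5))
  expect_true(is.finite(r0$ror_lo) && r0$ror_lo > 0)
})

test_that("PRR closed form and Yates chi-squared against chisq.test", {
  p <- prr_estimate(10, 20, 30, 240)
  expect_equal(p$prr, (10 / 30) / (30 / 270))
  expect_equal(p$prr, 3.0)

  null <- prr_estimate(5, 5, 5, 5)
  expect_equal(null$prr, 1.0)
  expect_equal(null$chi2, 0)  # correction degeneracy clamps at zero

  for (tb in list(c(20, 80, 10, 890), c(10, 20, 30, 240), c(3, 7, 11, 500))) {
    ours <- prr_estimate(tb[1], tb[2], tb[3], tb[4])$chi2
    ref <- unname(suppressWarnings(
      stats::chisq.test(matrix(tb, 2, 2, byrow = TRUE), correct = TRUE))$statistic)
    expect_equal(ours, ref, tolerance = 1e-12, label = paste(tb, collapse = ","))
  }

  und <- prr_estimate(5, 5, 0, 100)
  expect_true(und$prr_undefined)
  expect_true(is.na(und$prr))
})

test_that("information component vanishes at independence and is finite at a = 0", {
  # large balanced table with a = (a+b)(a+c)/N exactly
  ic0 <- ic_bate(100, 900, 900, 8100)
  expect_lt(abs(ic0$ic), 0.05)
  icz <- ic_bate(0, 50, 80, 1000)
  expect_true(is.finite(icz$ic) && is.finite(icz$ic025))
  expect_lt(icz$ic025, icz$ic)
})

test_that("all four estimators increase strictly with a (b, c, d fixed)", {
  prior <- fit_gps_prior(make_null_tables(300, seed = 71))
  avals <- c(1, 3, 8, 20, 50)
  tabs <- data.table::data.table(a = avals, b = 200, c = 40, d = 5000)
  ror <- ror_estimate(tabs$a, tabs$b, tabs$c, tabs$d)$ror
  prr <- prr_estimate(tabs$a, tabs$b, tabs$c, tabs$d)$prr
  ic <- ic_bate(tabs$a, tabs$b, tabs$c, tabs$d)$ic
  eb <- ebgm_score(tabs$a, expected_counts(tabs), prior)$ebgm
  for (v in list(ror, prr, ic, eb)) expect_true(all(diff(v) > 0))
})

test_that("EBGM shrinks toward 1 and approaches a/E for large counts", {
  prior <- fit_gps_prior(make_null_tables(500, seed = 72))
  # a/E = 5 with growing a: shrinkage vanishes
  for (a in c(50, 5000)) {
    E <- a / 5
    eb <- ebgm_score(a, E, prior)
    expect_true(eb$ebgm > 1 && eb$ebgm < 5 + 0.5)
    expect_true(eb$ebgm05 < eb$ebgm)
  }
  eb_big <- ebgm_score(50000, 10000, prior)
  expect_lt(abs(eb_big$ebgm - 5), 0.05)
  # a = 0: shrunk below the null
  expect_lt(ebgm_score(0, 10, prior)$ebgm, 1)
  # shrinkage direction on clearly non-null tables: ebgm lands between the
  # null value and the raw observed-to-expected ratio
  set.seed(31)
  for (i in 1:20) {
    E <- runif(1, 2, 20)
    ratio <- if (i %% 2) runif(1, 2.5, 6) else runif(1, 0.05, 0.4)
    a <- max(0, round(E * ratio))
    eb <- ebgm_score(a, E, prior)$ebgm
    expect_true((eb >= 1 - 0.1 & eb <= a / E + 1e-6) |
                  (eb <= 1 + 0.1 & eb >= a / E - 1e-6),
                label = sprintf("a=%d E=%.2f ebgm=%.3f", a, E, eb))
  }
  expect_true(ebgm_score(3, 0, prior)$ebgm_undefined)
})

test_that("the empirical-Bayes prior recovers a known truth's likelihood", {
  set.seed(91)
  truth <- list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, pi = 1/3)
  n <- 5000
  E <- exp(runif(n, log(0.5), log(50)))
  comp <- runif(n) < truth$pi
  lambda <- ifelse(comp, rgamma(n, truth$alpha1, rate = truth$beta1),
                   rgamma(n, truth$alpha2, rate = truth$beta2))
  a <- rpois(n, lambda * E)
  tabs <- data.table::data.table(a = a, b = 1000, c = round(E * 1000), d = 1e6)
  tabs <- tabs[tabs$c > 0, ]
  E2 <- expected_counts(tabs)
  ll <- function(p) {
    l1 <- dnbinom(tabs$a, size = p$alpha1, prob = p$beta1 / (p$beta1 + E2), log = TRUE)
    l2 <- dnbinom(tabs$a, size = p$alpha2, prob = p$beta2 / (p$beta2 + E2), log = TRUE)
    m <- pmax(l1, l2)
    sum(m + log(p$pi * exp(l1 - m) + (1 - p$pi) * exp(l2 - m)))
  }
  fit <- fit_gps_prior(tabs)
  expect_gte(fit$loglik, ll(truth) - 2)
  # deterministic under fixed data and start
  fit2 <- fit_gps_prior(tabs)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("on pure Poisson-null counts the fitted prior concentrates near 1", {
  tabs <- make_null_tables(2000, seed = 47)
  fit <- fit_gps_prior(tabs)
  prior_mean <- fit$pi * fit$alpha1 / fit$beta1 + (1 - fit$pi) * fit$alpha2 / fit$beta2
  expect_gt(prior_mean, 0.5)
  expect_lt(prior_mean, 2)
  expect_error(fit_gps_prior(tabs[1:5, ]), "at least 10")
})

test_that("classification thresholds: minimum count, inclusive MHRA, strict Bayesian", {
  res <- data.table::data.table(
    a = c(2, 3, 3, 3),
    ror_lo = c(10, 10, 0.5, 0.5),
    prr = c(5, 2.0, 1.0, 5),
    chi2 = c(100, 4.0, 1, 100),
    ic025 = c(1, 0, 0, -1),
    ebgm05 = c(5, 2, 2.5, 2))
  out <- classify_signals(res)
  expect_identical(out$ror_pos, c(FALSE, TRUE, FALSE, FALSE))   # a >= 3 gate
  expect_identical(out$prr_pos, c(FALSE, TRUE, FALSE, TRUE))    # boundaries inclusive
  expect_identical(out$bcpnn_pos, c(TRUE, FALSE, FALSE, FALSE)) # ic025 > 0 strict
  expect_identical(out$mgps_pos, c(TRUE, FALSE, TRUE, FALSE))   # ebgm05 > 2 strict
  all_rule <- classify_signals(res, signal_criteria(composite = "all"))
  expect_identical(all_rule$signal, rep(FALSE, 4))
})

test_that("estimators rank terms like the raw observed-to-expected ratio", {
  b <- generate_quarter(small_config(n_cases = 3000, seed = 23))
  rep <- code_events(assemble_reports(b), toy_meddra_map())
  sig <- detect_signals(rep, "CHOLESTYRAMINE", level = "pt")
  oe <- sig$a / expected_counts(sig)
  for (col in c("ror", "prr", "ic", "ebgm")) {
    rho <- cor(oe, sig[[col]], method = "spearman", use = "complete.obs")
    expect_gt(rho, 0.9)
  }
})
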