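# Independent oracles used to cross-check the estimator implementations.

# Monte-Carlo oracle for the BCPNN information component: simulates the
# independent Beta posteriors of the joint and marginal reporting
# probabilities and estimates log2 of the ratio of their posterior means
# (the quantity the closed form computes), with a delta-method SE.
ic_mc_oracle <- function(a, b, c, d, ndraws = 1e6,
                         alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1) {
  N <- a + b + c + d; n1 <- a + b; n2 <- a + c
  gam <- gamma11 * (N + alpha) * (N + beta) / ((n1 + alpha1) * (n2 + beta1))
  p11 <- rbeta(ndraws, a + gamma11, N - a + gam - gamma11)
  p1 <- rbeta(ndraws, n1 + alpha1, N - n1 + alpha - alpha1)
  p2 <- rbeta(ndraws, n2 + beta1, N - n2 + beta - beta1)
  m11 <- mean(p11); m1 <- mean(p1); m2 <- mean(p2)
  se <- sqrt(stats::var(p11) / (ndraws * m11^2) +
               stats::var(p1) / (ndraws * m1^2) +
               stats::var(p2) / (ndraws * m2^2)) / log(2)
  list(ic = log2(m11 / (m1 * m2)), se = se)
}

# Quadrature oracle for the EBGM lower percentile: posterior mixture
# weights as in the model, but the quantile is located by bisection on a
# CDF obtained by adaptive quadrature of the mixture density (independent
# of pgamma-based root finding).
ebgm05_quad_oracle <- function(a, E, prior, q = 0.05) {
  a1s <- prior$alpha1 + a; b1s <- prior$beta1 + E
  a2s <- prior$alpha2 + a; b2s <- prior$beta2 + E
  lw1 <- log(prior$pi) + dnbinom(a, size = prior$alpha1,
                                 prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  lw2 <- log(1 - prior$pi) + dnbinom(a, size = prior$alpha2,
                                     prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  q1 <- 1 / (1 + exp(lw2 - lw1)); q2 <- 1 - q1
  # integrate on the log scale: the substitution l = exp(t) removes the
  # integrable singularity at 0 when a gamma shape is below 1
  dens_log <- function(t) {
    l <- exp(t)
    v <- (q1 * dgamma(l, a1s, rate = b1s) + q2 * dgamma(l, a2s, rate = b2s)) * l
    v[l == 0 | !is.finite(v)] <- 0    # exp(t) underflow: integrand tends to 0
    v
  }
  cdf <- function(x) stats::integrate(dens_log, -Inf, log(x), rel.tol = 1e-12,
                                      subdivisions = 1000L)$value
  hi <- max(qgamma(0.9999, a1s, rate = b1s), qgamma(0.9999, a2s, rate = b2s))
  lo <- hi * 1e-12
  for (i in 1:100) {                     # bisection to ~1e-13 relative
    mid <- sqrt(lo * hi)                 # geometric bisection spans scales
    if (cdf(mid) < q) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# Null-consistent contingency tables: counts Poisson around the expected
# count implied by their own margins (O/E ~ 1), for prior-fitting fixtures.
make_null_tables <- function(n = 500, seed = 1, b0 = 1000, d0 = 5e5) {
  set.seed(seed)
  E <- exp(runif(n, log(0.5), log(50)))
  cc <- pmax(1, round(E * d0 / b0))
  a <- rpois(n, E)
  data.table::data.table(a = a, b = b0 - a, c = cc, d = d0)
}

# Small fixed demo record builder for deduplication tests.
demo_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(caseid = r[[1]], primaryid = r[[2]], fda_dt = r[[3]],
               stringsAsFactors = FALSE)))
}

# Compact synthetic configuration for fast tests.
small_config <- function(n_cases = 500, seed = 1, ...) {
  synth_config(n_cases = n_cases, seed = seed, ...)
}

# Bundle table equality ignoring ancillary attributes.
expect_bundle_tables_equal <- function(b1, b2) {
  for (tab in c("demo", "drug", "reac", "outc", "ther")) {
    expect_equal(as.data.frame(b1[[tab]]), as.data.frame(b2[[tab]]),
                 ignore_attr = TRUE, label = tab)
  }
  expect_identical(b1$deleted, b2$deleted)
}
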