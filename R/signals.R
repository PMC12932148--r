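# Disproportionality estimators: ROR, PRR with the MHRA composite
# criterion, the BCPNN information component (Bate's closed form), and the
# multi-item gamma-Poisson shrinker (DuMouchel's empirical-Bayes model).
#
# All estimator functions are vectorized over tables; every conventional
# constant (the 1.96 normal quantile, the Yates 0.5 continuity correction,
# the BCPNN priors, the IC025 = E - 2*SD rule, the EBGM 5th-percentile
# bound, the MHRA thresholds) is exposed as an argument with its de-facto
# default.

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a*d)/(b*c)` with
#' `CI = exp(log(ROR) +/- z*sqrt(1/a + 1/b + 1/c + 1/d))`. Tables with any
#' zero cell receive the Haldane-Anscombe +0.5 correction on all four cells
#' before estimation; the `haldane` flag records it.
#'
#' @param a,b,c,d 2x2 cell counts (vectorized): target-with-event,
#'   target-without, background-with, background-without
#' @param z normal quantile for the interval (1.96 for 95%)
#' @return data.table with `ror`, `ror_lo`, `ror_hi`, `haldane`
#' @examples
#' ror_estimate(10, 20, 30, 240)   # ROR = 4
#' @export
ror_estimate <- function(a, b, c, d, z = 1.96) {
  haldane <- (a == 0 | b == 0 | c == 0 | d == 0)
  k <- 0.5 * haldane
  a2 <- a + k; b2 <- b + k; c2 <- c + k; d2 <- d + k
  ror <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  data.table::data.table(ror = ror,
                         ror_lo = exp(log(ror) - z * se),
                         ror_hi = exp(log(ror) + z * se),
                         haldane = haldane)
}

#' Proportional reporting ratio and Yates-corrected chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` and the continuity-corrected Pearson
#' statistic `sum((max(|O-E| - yates, 0))^2 / E)` over the four cells of
#' the 2x2 table (the corrected deviation is clamped at zero, so a table
#' exactly at independence scores 0). Tables with a zero margin needed by
#' the ratio (`a+b`, `c`, or `c+d` zero) return `NA` with
#' `prr_undefined = TRUE`.
#'
#' @inheritParams ror_estimate
#' @param yates continuity correction subtracted from each |O-E|
#' @return data.table with `prr`, `chi2`, `prr_undefined`
#' @examples
#' prr_estimate(10, 20, 30, 240)   # PRR = 3
#' @export
prr_estimate <- function(a, b, c, d, yates = 0.5) {
  n <- a + b + c + d
  undef <- (a + b) == 0 | c == 0 | (c + d) == 0
  prr <- ifelse(undef, NA_real_, (a / (a + b)) / (c / (c + d)))
  e_a <- (a + b) * (a + c) / n
  e_b <- (a + b) * (b + d) / n
  e_c <- (c + d) * (a + c) / n
  e_d <- (c + d) * (b + d) / n
  dev <- pmax(abs(a - e_a) - yates, 0)  # |O-E| is equal across the 4 cells
  chi2 <- dev^2 * (1 / e_a + 1 / e_b + 1 / e_c + 1 / e_d)
  chi2[!is.finite(chi2)] <- NA_real_
  data.table::data.table(prr = prr, chi2 = chi2, prr_undefined = undef)
}

#' BCPNN information component (closed form)
#'
#' Posterior expectation and variance of the information component
#' `IC = log2(p11 / (p1. * p.1))` under independent Beta priors on the
#' joint and marginal reporting probabilities, with `alpha1 = beta1 = 1`,
#' `alpha = beta = 2`, `gamma11 = 1` and the joint prior weight `gamma`
#' calibrated so the prior IC expectation is zero:
#' `gamma = gamma11 * (N+alpha) * (N+beta) / ((a+b+alpha1) * (a+c+beta1))`.
#' The lower bound is `ic025 = E(IC) - sd_mult * sqrt(V(IC))`.
#'
#' The priors regularize empty cells, so `a = 0` still yields finite
#' values.
#'
#' @inheritParams ror_estimate
#' @param alpha1,beta1 marginal Beta prior parameters (numerators)
#' @param alpha,beta marginal Beta prior totals
#' @param gamma11 joint Beta prior numerator
#' @param sd_mult multiplier on the posterior SD for the lower bound
#' @return data.table with `ic` (bits) and `ic025` (bits)
#' @export
ic_bate <- function(a, b, c, d, alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                    gamma11 = 1, sd_mult = 2) {
  n <- a + b + c + d
  n1 <- a + b   # target margin
  n2 <- a + c   # event margin
  gamma <- gamma11 * (n + alpha) * (n + beta) / ((n1 + alpha1) * (n2 + beta1))
  eic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
                ((n + gamma) * (n1 + alpha1) * (n2 + beta1)))
  vic <- ((n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
            (n - n1 + alpha - alpha1) / ((n1 + alpha1) * (1 + n + alpha)) +
            (n - n2 + beta - beta1) / ((n2 + beta1) * (1 + n + beta))) / log(2)^2
  data.table::data.table(ic = eic, ic025 = eic - sd_mult * sqrt(vic))
}

#' Fit the gamma-Poisson mixture prior (MGPS)
#'
#' Observed counts `a` are modelled as Poisson with mean `lambda * E`,
#' where `E = (a+b)(a+c)/N` is the expected count under independence and
#' `lambda` follows a two-component gamma mixture prior. Marginally each
#' `a` is a mixture of negative binomials; the five hyperparameters are
#' fitted by maximizing that marginal likelihood across all tables of one
#' level, started from DuMouchel's defaults. If the optimizer fails to
#' return a finite optimum the defaults are kept and `fallback` is set.
#'
#' @param tables a data.table of contingency tables (columns `a,b,c,d`),
#'   e.g. from [build_contingency()]; at least 10 rows
#' @param start named start values `alpha1, beta1, alpha2, beta2, pi`
#' @param tol relative convergence tolerance on the log-likelihood
#' @return a `gps_prior`: list with the five hyperparameters plus
#'   `loglik`, `converged`, `fallback`, `n_tables`
#' @export
fit_gps_prior <- function(tables,
                          start = c(alpha1 = 0.2, beta1 = 0.1,
                                    alpha2 = 2, beta2 = 4, pi = 1/3),
                          tol = 1e-6) {
  if (nrow(tables) < 10)
    stop("empirical-Bayes prior fitting needs at least 10 tables, got ", nrow(tables),
         call. = FALSE)
  a <- tables$a
  E <- expected_counts(tables)
  negll <- function(theta) {
    p <- c(exp(theta[1:4]), stats::plogis(theta[5]))
    l1 <- stats::dnbinom(a, size = p[1], prob = p[2] / (p[2] + E), log = TRUE)
    l2 <- stats::dnbinom(a, size = p[3], prob = p[4] / (p[4] + E), log = TRUE)
    m <- pmax(l1, l2)
    -sum(m + log(p[5] * exp(l1 - m) + (1 - p[5]) * exp(l2 - m)))
  }
  theta0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  fit <- tryCatch(
    stats::nlminb(theta0, negll,
                  control = list(rel.tol = tol * 1e-2, iter.max = 500, eval.max = 1000)),
    error = function(e) NULL)
  fallback <- is.null(fit) || !is.finite(fit$objective)
  if (fallback) {
    warning("gamma-Poisson prior fit failed; falling back to default hyperparameters",
            call. = FALSE)
    par <- theta0
    obj <- negll(theta0)
    conv <- FALSE
  } else {
    par <- fit$par
    obj <- fit$objective
    conv <- fit$convergence == 0
  }
  p <- c(exp(par[1:4]), stats::plogis(par[5]))
  structure(list(alpha1 = p[1], beta1 = p[2], alpha2 = p[3], beta2 = p[4],
                 pi = p[5], loglik = -obj, converged = conv, fallback = fallback,
                 n_tables = nrow(tables)),
            class = "gps_prior")
}

default_gps_prior <- function() {
  structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, pi = 1/3,
                 loglik = NA_real_, converged = NA, fallback = TRUE, n_tables = 0L),
            class = "gps_prior")
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf("<gps_prior> alpha1=%.4g beta1=%.4g alpha2=%.4g beta2=%.4g pi=%.4g\n",
              x$alpha1, x$beta1, x$alpha2, x$beta2, x$pi))
  cat(sprintf("  fitted on %d tables, loglik %.4f%s%s\n", x$n_tables, x$loglik,
              if (isTRUE(x$converged)) ", converged" else "",
              if (isTRUE(x$fallback)) " [fallback defaults]" else ""))
  invisible(x)
}

#' Expected counts under independence
#'
#' `E = (a+b)(a+c)/N` per table: the count the target drug would accrue for
#' the term if reporting were proportional to its overall share.
#'
#' @param tables data.frame with columns `a`, `b`, `c`, `d`
#' @return numeric vector of expected counts
#' @export
expected_counts <- function(tables) {
  n <- tables$a + tables$b + tables$c + tables$d
  (tables$a + tables$b) * (tables$a + tables$c) / n
}

#' Empirical-Bayes geometric mean and lower posterior percentile
#'
#' Given the fitted prior, the posterior of the relative reporting rate
#' `lambda` is again a two-gamma mixture with updated parameters and
#' weights. `EBGM = 2^{E[log2 lambda | a]}` (the geometric posterior mean)
#' and `EBGM05` is the `q`-quantile of the posterior, located by monotone
#' root-finding on the mixture CDF.
#'
#' @param a observed counts (vectorized)
#' @param E expected counts under independence (same length)
#' @param prior a `gps_prior`
#' @param q lower posterior quantile to report
#' @param tol absolute root-finding tolerance on the quantile
#' @return data.table with `ebgm`, `ebgm05`, `ebgm_undefined`
#' @export
ebgm_score <- function(a, E, prior, q = 0.05, tol = 1e-8) {
  stopifnot(inherits(prior, "gps_prior"), length(a) == length(E))
  undef <- !(E > 0)
  a1s <- prior$alpha1 + a; b1s <- prior$beta1 + E
  a2s <- prior$alpha2 + a; b2s <- prior$beta2 + E
  lw1 <- log(prior$pi) +
    stats::dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  lw2 <- log(1 - prior$pi) +
    stats::dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  q1 <- 1 / (1 + exp(lw2 - lw1))
  q2 <- 1 - q1
  elog <- q1 * (digamma(a1s) - log(b1s)) + q2 * (digamma(a2s) - log(b2s))
  ebgm <- exp(elog)
  ebgm05 <- rep(NA_real_, length(a))
  for (i in seq_along(a)) {
    if (undef[i]) next
    cdf <- function(x) q1[i] * stats::pgamma(x, a1s[i], rate = b1s[i]) +
      q2[i] * stats::pgamma(x, a2s[i], rate = b2s[i]) - q
    # bracket the quantile between the component quantiles, widened until
    # the CDF changes sign (guards against extreme posterior weights)
    q1i <- stats::qgamma(q, a1s[i], rate = b1s[i])
    q2i <- stats::qgamma(q, a2s[i], rate = b2s[i])
    lo <- min(q1i, q2i); hi <- max(q1i, q2i)
    k <- 0
    while (cdf(lo) > 0 && k < 100) { lo <- lo / 2; k <- k + 1 }
    while (cdf(hi) < 0 && k < 200) { hi <- hi * 2; k <- k + 1 }
    if (hi <= lo || cdf(lo) > 0 || cdf(hi) < 0) { ebgm05[i] <- lo; next }
    # scale the tolerance to the bracket so tiny quantiles keep relative
    # accuracy
    tol_i <- max(tol * min(1, lo), 1e-280)
    ebgm05[i] <- stats::uniroot(cdf, c(lo, hi), tol = tol_i,
                                f.lower = cdf(lo), f.upper = cdf(hi))$root
  }
  ebgm[undef] <- NA_real_
  data.table::data.table(ebgm = ebgm, ebgm05 = ebgm05, ebgm_undefined = undef)
}

#' Signal classification criteria
#'
#' Threshold set for per-method positive-signal flags: the common
#' literature defaults are a reported-case minimum of 3 with a lower ROR
#' confidence bound above 1; the MHRA composite (`a >= 3`, `PRR >= 2`,
#' `chi2 >= 4`, boundaries inclusive); `IC025 > 0` (strict); and
#' `EBGM05 > 2` (strict).
#'
#' @param min_count minimum `a` for ROR/PRR flags
#' @param ror_lo_min ROR flag requires `ror_lo >` this
#' @param prr_min,chi2_min MHRA composite thresholds (inclusive)
#' @param ic025_min BCPNN flag requires `ic025 >` this (strict)
#' @param ebgm05_min MGPS flag requires `ebgm05 >` this (strict)
#' @param composite `"any"` (default) or `"all"`: how the per-method flags
#'   combine into the overall positive-signal flag
#' @return a `signal_criteria` list
#' @export
signal_criteria <- function(min_count = 3, ror_lo_min = 1, prr_min = 2, chi2_min = 4,
                            ic025_min = 0, ebgm05_min = 2,
                            composite = c("any", "all")) {
  composite <- match.arg(composite)
  stopifnot(min_count >= 0, prr_min > 0, chi2_min >= 0)
  structure(list(min_count = min_count, ror_lo_min = ror_lo_min, prr_min = prr_min,
                 chi2_min = chi2_min, ic025_min = ic025_min, ebgm05_min = ebgm05_min,
                 composite = composite),
            class = "signal_criteria")
}

#' Apply positive-signal classification
#'
#' Adds the per-method logical flags `ror_pos`, `prr_pos`, `bcpnn_pos`,
#' `mgps_pos` and the composite `signal` column to an estimator results
#' table. Missing estimates never flag positive.
#'
#' @param results data.table with columns `a`, `ror_lo`, `prr`, `chi2`,
#'   `ic025`, `ebgm05`
#' @param criteria a [signal_criteria()]
#' @return `results` with flag columns added
#' @export
classify_signals <- function(results, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  results <- data.table::as.data.table(results)
  isT <- function(x) !is.na(x) & x
  results[, ror_pos := isT(a >= criteria$min_count & ror_lo > criteria$ror_lo_min)]
  results[, prr_pos := isT(a >= criteria$min_count & prr >= criteria$prr_min &
                             chi2 >= criteria$chi2_min)]
  results[, bcpnn_pos := isT(ic025 > criteria$ic025_min)]
  results[, mgps_pos := isT(ebgm05 > criteria$ebgm05_min)]
  results[, signal := if (criteria$composite == "any")
    ror_pos | prr_pos | bcpnn_pos | mgps_pos
    else ror_pos & prr_pos & bcpnn_pos & mgps_pos]
  results[]
}

#' Run all four estimators over a report corpus
#'
#' Builds the contingency tables for the target drug at the requested
#' level, computes ROR, PRR/chi-squared, the BCPNN information component
#' and EBGM (with the empirical-Bayes prior fitted on all tables of the
#' level, unless supplied), and classifies each term.
#'
#' @inheritParams build_contingency
#' @param criteria a [signal_criteria()]
#' @param prior optionally a pre-fitted `gps_prior`; when `NULL` it is
#'   fitted on the level's tables (corpora with fewer than 10 terms fall
#'   back to the default prior with a warning)
#' @return a data.table, one row per term, ordered by decreasing case
#'   count: counts, all estimator columns, interval bounds and flags;
#'   attribute `gps_prior` carries the prior used
#' @export
detect_signals <- function(reports, target, level = c("pt", "soc"),
                           criteria = signal_criteria(), prior = NULL) {
  level <- match.arg(level)
  tab <- build_contingency(reports, target, level)
  if (is.null(prior)) {
    prior <- if (nrow(tab) >= 10) fit_gps_prior(tab) else {
      warning("fewer than 10 terms; using default gamma-Poisson prior", call. = FALSE)
      default_gps_prior()
    }
  }
  res <- cbind(tab,
               ror_estimate(tab$a, tab$b, tab$c, tab$d),
               prr_estimate(tab$a, tab$b, tab$c, tab$d),
               ic_bate(tab$a, tab$b, tab$c, tab$d),
               ebgm_score(tab$a, expected_counts(tab), prior))
  res <- classify_signals(res, criteria)
  data.table::setattr(res, "gps_prior", prior)
  data.table::setattr(res, "n_target", attr(tab, "n_target"))
  data.table::setattr(res, "n_total", attr(tab, "n_total"))
  res[]
}

#' Format signal results as a publication-style table
#'
#' Renders the standard column layout of FAERS disproportionality reports:
#' term, case reports, `ROR (95% CI)`, `PRR (chi2)`, `IC (IC025)`,
#' `EBGM (EBGM05)`.
#'
#' @param results output of [detect_signals()]
#' @param digits significant digits for estimates
#' @return a data.frame of formatted character columns
#' @export
format_signal_table <- function(results, digits = 3) {
  f <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
  data.frame(
    term = results$term,
    `Case reports` = results$a,
    `ROR (95% CI)` = sprintf("%s (%s-%s)", f(results$ror), f(results$ror_lo), f(results$ror_hi)),
    `PRR (chi2)` = sprintf("%s (%s)", f(results$prr), f(results$chi2)),
    `IC (IC025)` = sprintf("%s (%s)", f(results$ic), f(results$ic025)),
    `EBGM (EBGM05)` = sprintf("%s (%s)", f(results$ebgm), f(results$ebgm05)),
    check.names = FALSE)
}
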