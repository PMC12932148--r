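# Time-to-onset: collection, binning, quantiles, Weibull maximum
# likelihood, and the empirical cumulative incidence curve.
#
# Onset is measured in whole days from the earliest primary-suspect
# therapy start to the event date; day 0 means the event was reported as
# immediate. The Weibull shape parameter separates early-failure (< 1)
# from wear-out (> 1) hazard profiles.

#' Collect usable onset samples from a report corpus
#'
#' Extracts per-case onset days for cases whose dates were complete, day
#' precise and non-negative; everything else is tallied by exclusion
#' reason (`missing`, `partial`, `negative`).
#'
#' @param reports a `report_set`
#' @return list with `samples` (data.table `caseid`, `onset_days`) and
#'   `exclusions` (data.table `reason`, `n`)
#' @export
collect_onsets <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  cs <- reports$cases
  samples <- cs[onset_status == "ok", .(caseid, onset_days)]
  excl <- cs[onset_status != "ok", .(n = .N), by = .(reason = onset_status)]
  data.table::setorder(excl, reason)
  list(samples = samples[], exclusions = excl[])
}

ONSET_BREAKS <- c(-0.5, 0.5, 1.5, 2.5, 3.5, 30.5, 60.5, 90.5, 120.5, 150.5, 180.5, 365.5, Inf)
ONSET_LABELS <- c("0 d (immediate)", "1 d", "2 d", "3 d", "4-30 d", "31-60 d",
                  "61-90 d", "91-120 d", "121-150 d", "151-180 d", "181-365 d", "> 365 d")

#' Bin onset days into the standard reporting intervals
#'
#' Bins: immediate (day 0), days 1, 2, 3, 4-30, then monthly up to 180
#' days, 181-365 days, and beyond one year. Percentages of `n` are rounded
#' half-up to two decimals; the cumulative percentage within 30 days is
#' also reported.
#'
#' @param onset_days integer vector of onset days (>= 0)
#' @return an `onset_bins` object: data.frame `bin`, `n`, `pct`, with
#'   attributes `n_total` and `cum30_pct` (percentage with onset <= 30 d)
#' @export
bin_onsets <- function(onset_days) {
  onset_days <- onset_days[!is.na(onset_days)]
  if (!length(onset_days)) stop("no onset samples to bin", call. = FALSE)
  stopifnot(all(onset_days >= 0))
  counts <- table(cut(onset_days, ONSET_BREAKS, labels = ONSET_LABELS))
  n <- length(onset_days)
  out <- data.frame(bin = ONSET_LABELS, n = as.integer(counts),
                    pct = pct2(as.integer(counts), n))
  structure(out, class = c("onset_bins", "data.frame"),
            n_total = n, cum30_pct = pct2(sum(onset_days <= 30), n))
}

#' @export
print.onset_bins <- function(x, ...) {
  cat(sprintf("Time-to-onset distribution (n = %d):\n", attr(x, "n_total")))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("Cumulative within 30 d: %.2f%%\n", attr(x, "cum30_pct")))
  invisible(x)
}

#' Median and interquartile range of onset days
#'
#' Linear-interpolation quantiles (type 7).
#'
#' @param onset_days numeric vector
#' @return list with `median`, `q1`, `q3` (days)
#' @export
onset_median_iqr <- function(onset_days) {
  onset_days <- onset_days[!is.na(onset_days)]
  q <- stats::quantile(onset_days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Weibull maximum-likelihood fit of onset times
#'
#' Fits shape and scale by Newton iteration on the profile likelihood
#' equation for the shape,
#' `g(k) = sum(x^k log x)/sum(x^k) - 1/k - mean(log x) = 0`,
#' to a tolerance of 1e-10, then `scale = (mean(x^k))^(1/k)`. The Weibull
#' support is positive, so day-0 ("immediate") events are handled by
#' policy: shifted to 0.5 days (default) or dropped.
#'
#' @param onset_days numeric vector of onset days (>= 0)
#' @param zero_policy `"shift_half_day"` (default) or `"drop_zeros"`
#' @param tol convergence tolerance on the profile equation
#' @param max_iter Newton iteration cap
#' @return a `weibull_fit`: list with `shape`, `scale` (days),
#'   `log_likelihood`, `n_used`, `n_zeros`, `zero_policy`, `iterations`,
#'   `converged`
#' @examples
#' fit <- weibull_fit(rweibull(500, 1.5, 10))
#' c(fit$shape, fit$scale)
#' @export
weibull_fit <- function(onset_days, zero_policy = c("shift_half_day", "drop_zeros"),
                        tol = 1e-10, max_iter = 200) {
  zero_policy <- match.arg(zero_policy)
  x <- onset_days[!is.na(onset_days)]
  stopifnot(all(x >= 0))
  n_zeros <- sum(x == 0)
  x <- switch(zero_policy,
              shift_half_day = ifelse(x == 0, 0.5, x),
              drop_zeros = x[x > 0])
  if (!length(x))
    stop("no positive onset values remain under policy 'drop_zeros'", call. = FALSE)
  if (length(x) < 10)
    stop("Weibull fitting needs at least 10 positive values, got ", length(x), call. = FALSE)
  lx <- log(x)
  lbar <- mean(lx)
  profile_g <- function(k) {
    w <- x^k
    sum(w * lx) / sum(w) - 1 / k - lbar
  }
  # moment-based start from the log-scale dispersion
  k <- max(0.05, pi / (sqrt(6) * stats::sd(lx)))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- x^k
    s0 <- sum(w); s1 <- sum(w * lx); s2 <- sum(w * lx^2)
    g <- s1 / s0 - 1 / k - lbar
    gp <- (s2 / s0 - (s1 / s0)^2) + 1 / k^2
    step <- g / gp
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2   # stay in the admissible region
    if (abs(k_new - k) < tol * max(1, k) && abs(g) < 1e-8) {
      k <- k_new; converged <- TRUE; break
    }
    k <- k_new
  }
  if (!converged && abs(profile_g(k)) < 1e-6) converged <- TRUE
  lambda <- (mean(x^k))^(1 / k)
  ll <- sum(stats::dweibull(x, shape = k, scale = lambda, log = TRUE))
  structure(list(shape = k, scale = lambda, log_likelihood = ll,
                 n_used = length(x), n_zeros = n_zeros, zero_policy = zero_policy,
                 iterations = iter, converged = converged),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> shape = %.4f, scale = %.4f d (n = %d, %d zero-day %s; logLik %.2f)\n",
              x$shape, x$scale, x$n_used, x$n_zeros,
              if (x$zero_policy == "shift_half_day") "shifted to 0.5 d" else "dropped",
              x$log_likelihood))
  invisible(x)
}

#' Empirical cumulative incidence over onset days
#'
#' Step function of the fraction of events occurring on or before each
#' observed day; reaches 1 at the maximum observed day.
#'
#' @param onset_days numeric vector of onset days
#' @return data.frame with `day` and `cum_frac`, one row per distinct day
#' @export
cumulative_incidence <- function(onset_days) {
  x <- sort(onset_days[!is.na(onset_days)])
  if (!length(x)) stop("no onset samples", call. = FALSE)
  days <- unique(x)
  data.frame(day = days, cum_frac = cumsum(tabulate(match(x, days))) / length(x))
}
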