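# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages in
#' pharmacovigilance tables use conventional half-up rounding, so a 0.5
#' remainder always rounds away from zero.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  # nudge by a relative epsilon so values that are exactly .5 after decimal
  # representation error (e.g. 22.525000000000002 vs 22.524999...) behave
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# percentage of count over denom, half-up to 2 dp
pct2 <- function(count, denom) round_half_up(100 * count / denom, 2)

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed_preserved <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- date handling -------------------------------------------------------
# FAERS dates are digit strings: yyyymmdd (day precision), yyyymm (month),
# yyyy (year). Precision is recorded rather than imputed.

date_precision <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("missing", length(x))
  out[grepl("^[0-9]{4}$", x)] <- "year"
  out[grepl("^[0-9]{6}$", x)] <- "month"
  full <- grepl("^[0-9]{8}$", x)
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    out[full] <- ifelse(is.na(d), "invalid", "day")
  }
  out[!is.na(x) & nzchar(x) & out == "missing" &
        !grepl("^[0-9]{4}([0-9]{2}([0-9]{2})?)?$", x)] <- "invalid"
  out
}

# yyyymmdd string -> Date (NA unless day precision and valid)
date8_to_date <- function(x) {
  x <- trimws(as.character(x))
  d <- rep(as.Date(NA), length(x))
  full <- grepl("^[0-9]{8}$", x)
  d[full] <- as.Date(x[full], format = "%Y%m%d")
  d
}

date8_year <- function(x) {
  x <- trimws(as.character(x))
  y <- rep(NA_integer_, length(x))
  ok <- grepl("^[0-9]{4}", x)
  y[ok] <- as.integer(substr(x[ok], 1, 4))
  y
}

stop_stage <- function(stage, e) {
  stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
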