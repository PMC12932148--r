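# 2x2 disproportionality tables: target drug x event term against the rest
# of the ingested corpus.
#
# Counting unit is the report (case): a case reporting the same term twice
# contributes once (presence/absence), so `a` can never exceed the target
# case total and the margins a+b, c+d are identical across terms of a
# level.

#' Build 2x2 contingency tables per term
#'
#' For every term observed at least once in the corpus, counts
#' `a` = target cases with the term, `b` = target cases without it,
#' `c` = background cases with it, `d` = background cases without it.
#' Background is every other report in the same corpus (whole-database
#' comparator).
#'
#' @param reports a `report_set`; must be SOC-coded (see [code_events()])
#'   when `level = "soc"`
#' @param target either a character vector of drug-name patterns (cases
#'   whose primary-suspect drug matches are the target) or a logical vector
#'   aligned with `reports$cases`
#' @param level `"pt"` (preferred term) or `"soc"` (system organ class)
#' @return a data.table with columns `term`, `level`, `a`, `b`, `c`, `d`,
#'   ordered by decreasing `a`; attributes `n_target` and `n_total`
#' @export
build_contingency <- function(reports, target, level = c("pt", "soc")) {
  stopifnot(inherits(reports, "report_set"))
  level <- match.arg(level)
  n_total <- nrow(reports$cases)
  if (n_total == 0) stop("cannot build contingency tables from zero reports", call. = FALSE)
  if (is.logical(target)) {
    stopifnot(length(target) == n_total)
    target_pid <- reports$cases$primaryid[target]
  } else {
    target_pid <- target_case_ids(reports, target)
  }
  if (!length(target_pid)) stop("target set is empty: no case matches", call. = FALSE)

  rx <- reports$reactions
  if (level == "soc") {
    if (!isTRUE(reports$coded) || is.null(rx$soc))
      stop("reactions are not SOC-coded; run code_events() first", call. = FALSE)
    pairs <- unique(rx[, .(primaryid, term = soc)])
  } else {
    pairs <- unique(rx[, .(primaryid, term = pt)])
  }
  pairs <- pairs[nzchar(term)]
  pairs[, is_target := primaryid %in% target_pid]
  n_target <- sum(reports$cases$primaryid %in% target_pid)

  tab <- pairs[, .(a = sum(is_target), ac = .N), by = term]
  tab[, `:=`(level = toupper(level),
             b = n_target - a,
             c = ac - a,
             d = (n_total - n_target) - (ac - a))]
  tab[, ac := NULL]
  data.table::setcolorder(tab, c("term", "level", "a", "b", "c", "d"))
  data.table::setorder(tab, -a, term)
  data.table::setattr(tab, "n_target", n_target)
  data.table::setattr(tab, "n_total", n_total)
  tab[]
}
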