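# Case curation: hierarchical deduplication, deletion-list removal,
# MedDRA PT -> SOC coding, and assembly of per-case report records.

#' Hierarchical case deduplication
#'
#' Per CASEID, keeps the report version with the most recent receipt date
#' (FDA_DT); when CASEID and FDA_DT are identical, the version with the
#' larger PRIMARYID wins (numeric comparison when all PRIMARYIDs parse as
#' numbers, else lexicographic). CASEIDs on the deletion list are then
#' dropped entirely. Missing FDA_DT sorts before any valid date.
#'
#' @param demo a data.frame/data.table with columns `caseid`, `primaryid`,
#'   `fda_dt`
#' @param deletion_list character vector of CASEIDs to remove
#' @return character vector of retained PRIMARYIDs, ordered by CASEID
#' @export
deduplicate_reports <- function(demo, deletion_list = character()) {
  demo <- data.table::as.data.table(demo)
  if (!nrow(demo)) return(character())
  stopifnot(all(c("caseid", "primaryid", "fda_dt") %in% names(demo)))
  d <- demo[, .(caseid = as.character(caseid), primaryid = as.character(primaryid),
                fda_dt = as.character(fda_dt))]
  d[, dt_num := suppressWarnings(as.numeric(fda_dt))]
  d[is.na(dt_num), dt_num := -Inf]
  pid_num <- suppressWarnings(as.numeric(d$primaryid))
  if (!anyNA(pid_num)) d[, pid_ord := pid_num] else d[, pid_ord := rank(primaryid, ties.method = "min")]
  data.table::setorder(d, caseid, -dt_num, -pid_ord)
  kept <- d[, .SD[1], by = caseid]
  kept <- kept[!caseid %in% as.character(deletion_list)]
  data.table::setorder(kept, caseid)
  kept$primaryid
}

#' Normalize a drug name for matching
#'
#' Uppercases, trims, and collapses punctuation and repeated whitespace to
#' single spaces, so `"Cholestyramine  Light "` matches `"CHOLESTYRAMINE"`
#' by substring.
#'
#' @param x character vector of drug names
#' @return normalized character vector
#' @export
normalize_drugname <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Read a PT -> SOC mapping file
#'
#' The mapping is two-column delimited text (tab or the file's detected
#' delimiter) with a header, one row per preferred term, mapping each PT to
#' exactly one primary system organ class. MedDRA itself is licensed and is
#' not shipped; a small synthetic dictionary for examples and tests is
#' available via [toy_meddra_map()].
#'
#' @param path path to the mapping file
#' @param version version label stored on the map
#' @return a `meddra_map`: named character vector (PT -> SOC) with a
#'   `version` attribute
#' @export
read_meddra_map <- function(path, version = basename(path)) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "auto", header = TRUE, quote = "",
                          colClasses = "character", data.table = TRUE)
  if (ncol(dt) < 2) stop("mapping file must have two columns (PT, SOC)", call. = FALSE)
  pt <- trimws(dt[[1]]); soc <- trimws(dt[[2]])
  keep <- nzchar(pt) & nzchar(soc)
  pt <- pt[keep]; soc <- soc[keep]
  if (anyDuplicated(pt))
    stop("mapping file assigns multiple SOCs to PT(s): ",
         paste(unique(pt[duplicated(pt)]), collapse = ", "), call. = FALSE)
  structure(stats::setNames(soc, pt), class = "meddra_map", version = version)
}

#' Toy PT -> SOC dictionary
#'
#' A small synthetic stand-in for the licensed MedDRA dictionary, covering
#' the preferred terms used by the synthetic generator plus common
#' gastrointestinal and product-issue terms.
#'
#' @return a `meddra_map`
#' @export
toy_meddra_map <- function() {
  path <- system.file("extdata", "toy_meddra_pt_soc.tsv", package = "pvsignal")
  read_meddra_map(path, version = "toy-synthetic")
}

#' @export
print.meddra_map <- function(x, ...) {
  cat(sprintf("<meddra_map '%s'> %d preferred terms, %d system organ classes\n",
              attr(x, "version"), length(x), length(unique(unname(x)))))
  invisible(x)
}

#' Annotate reactions with their primary SOC
#'
#' Every reaction row gains a `soc` column. PTs absent from the map are
#' kept with `soc = "UNMAPPED"` and listed, with counts, in the
#' `unmapped` attribute of the result — never silently dropped.
#'
#' @param reports a `report_set` from [assemble_reports()]
#' @param map a `meddra_map`
#' @return the `report_set` with coded reactions; `attr(, "unmapped")` is a
#'   data.table of unmapped PTs and their row counts
#' @export
code_events <- function(reports, map) {
  stopifnot(inherits(reports, "report_set"), inherits(map, "meddra_map"))
  rx <- reports$reactions
  soc <- unname(map[rx$pt])
  soc[is.na(soc)] <- "UNMAPPED"
  rx[, soc := soc]
  unmapped <- rx[soc == "UNMAPPED", .(n = .N), by = .(pt)][order(-n, pt)]
  reports$reactions <- rx
  reports$coded <- TRUE
  attr(reports, "unmapped") <- unmapped
  reports
}

#' Assemble deduplicated per-case reports from quarter bundles
#'
#' Applies [deduplicate_reports()] across all supplied quarters (deletion
#' lists from every quarter are honored), then joins demographics, drugs,
#' reactions, outcomes and therapy dates for the retained report versions.
#' Time-to-onset is computed per case as event date minus the earliest
#' therapy start of a primary-suspect drug row, in whole days; negative
#' intervals, sub-day-precision dates and missing dates are recorded with a
#' status instead of a value.
#'
#' @param bundles a `quarter_bundle` or list of them
#' @return a `report_set`: list of data.tables `cases` (one row per
#'   retained case: demographics, `onset_days`, `onset_status`), `drugs`,
#'   `reactions`, `outcomes`, keyed by `primaryid`
#' @export
assemble_reports <- function(bundles) {
  if (inherits(bundles, "quarter_bundle")) bundles <- list(bundles)
  stopifnot(length(bundles) > 0, all(vapply(bundles, inherits, logical(1), "quarter_bundle")))
  demo <- data.table::rbindlist(lapply(bundles, `[[`, "demo"), use.names = TRUE)
  drug <- data.table::rbindlist(lapply(bundles, `[[`, "drug"), use.names = TRUE)
  reac <- data.table::rbindlist(lapply(bundles, `[[`, "reac"), use.names = TRUE)
  outc <- data.table::rbindlist(lapply(bundles, `[[`, "outc"), use.names = TRUE)
  ther <- data.table::rbindlist(lapply(bundles, `[[`, "ther"), use.names = TRUE)
  deleted <- sort(unique(unlist(lapply(bundles, `[[`, "deleted"))))

  retained <- deduplicate_reports(demo, deleted)
  demo <- demo[primaryid %in% retained]
  drug <- drug[primaryid %in% retained]
  reac <- unique(reac[primaryid %in% retained])
  outc <- unique(outc[primaryid %in% retained])
  ther <- ther[primaryid %in% retained]

  cases <- demo[, .(
    caseid = caseid, primaryid = primaryid, fda_dt = fda_dt,
    event_year = date8_year(fda_dt),
    sex = ifelse(toupper(trimws(sex)) %in% c("M", "F"), toupper(trimws(sex)), "missing"),
    age_group = age_to_group(age, age_cod),
    reporter = reporter_label(occp_cod),
    country = ifelse(nzchar(trimws(occr_country)), trimws(occr_country), "missing"),
    event_dt = event_dt)]

  onset <- compute_onsets(cases, drug, ther)
  cases[, onset_days := onset$onset_days]
  cases[, onset_status := onset$onset_status]
  cases[, event_dt := NULL]

  structure(list(cases = cases, drugs = drug, reactions = reac, outcomes = outc,
                 deleted = deleted, coded = FALSE),
            class = "report_set")
}

# onset = event date - earliest primary-suspect therapy start, whole days.
# Strict precision policy: a month-/year-precision date on either side
# makes the interval ambiguous, so the case is excluded with status
# "partial" rather than imputed.
compute_onsets <- function(cases, drug, ther) {
  ps <- drug[toupper(role_cod) == "PS", .(primaryid, drug_seq)]
  th <- ther[ps, on = c("primaryid", dsg_drug_seq = "drug_seq"), nomatch = NULL]
  th <- th[nzchar(trimws(start_dt))]
  if (nrow(th)) {
    th[, prec := date_precision(start_dt)]
    th[, d := date8_to_date(start_dt)]
    first <- th[, .(start = if (any(prec %in% c("month", "year")) ||
                                !any(prec == "day")) as.Date(NA)
                            else min(d[prec == "day"], na.rm = TRUE),
                    partial = any(prec %in% c("month", "year"))), by = primaryid]
  } else {
    first <- data.table::data.table(primaryid = character(),
                                    start = as.Date(character()), partial = logical())
  }
  m <- first[match(cases$primaryid, primaryid)]
  ev_prec <- date_precision(cases$event_dt)
  ev_date <- date8_to_date(cases$event_dt)
  days <- as.integer(ev_date - m$start)

  status <- rep("missing", nrow(cases))
  has_ther <- !is.na(m$primaryid)
  has_ev <- ev_prec %in% c("day", "month", "year")
  partial <- has_ther & has_ev & (ev_prec != "day" | m$partial)
  status[partial] <- "partial"
  ok <- has_ther & !partial & ev_prec == "day" & !is.na(days)
  status[ok & days < 0] <- "negative"
  status[ok & days >= 0] <- "ok"
  list(onset_days = ifelse(status == "ok", days, NA_integer_),
       onset_status = status)
}

#' Restrict a report set to a target drug
#'
#' Keeps cases having at least one drug row with role code `PS` whose
#' normalized name contains any of the given patterns as a substring.
#'
#' @param reports a `report_set`
#' @param name_patterns character vector of drug-name patterns (matched as
#'   substrings after [normalize_drugname()] normalization of both sides)
#' @return the filtered `report_set`
#' @export
select_primary_suspect <- function(reports, name_patterns) {
  stopifnot(inherits(reports, "report_set"))
  if (!length(name_patterns) || !any(nzchar(name_patterns)))
    stop("invalid 'name_patterns': at least one non-empty pattern is required", call. = FALSE)
  keep_pid <- target_case_ids(reports, name_patterns)
  subset_report_set(reports, keep_pid)
}

target_case_ids <- function(reports, name_patterns) {
  pats <- normalize_drugname(name_patterns)
  pats <- pats[nzchar(pats)]
  ps <- reports$drugs[toupper(role_cod) == "PS"]
  nm <- normalize_drugname(ps$drugname)
  hit <- rep(FALSE, nrow(ps))
  for (p in pats) hit <- hit | grepl(p, nm, fixed = TRUE)
  unique(ps$primaryid[hit])
}

subset_report_set <- function(reports, pids) {
  reports$cases <- reports$cases[primaryid %in% pids]
  reports$drugs <- reports$drugs[primaryid %in% pids]
  reports$reactions <- reports$reactions[primaryid %in% pids]
  reports$outcomes <- reports$outcomes[primaryid %in% pids]
  reports
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d cases, %d drug rows, %d reactions%s, %d outcome rows\n",
              nrow(x$cases), nrow(x$drugs), nrow(x$reactions),
              if (isTRUE(x$coded)) " (SOC-coded)" else "", nrow(x$outcomes)))
  invisible(x)
}
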