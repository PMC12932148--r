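# Synthetic FAERS-like quarter generator with known ground truth.
#
# Emulates the structure of the quarterly ASCII extracts: multi-table case
# reports keyed by PRIMARYID/CASEID, duplicate case versions, a deletion
# list, per-case demographics with explicit missingness, one primary-suspect
# drug row (plus optional concomitants), reaction rows carrying MedDRA PTs,
# and therapy/event dates yielding Weibull-distributed onset intervals.
# Drug-event reporting-rate ratios can be planted so that downstream signal
# detection has known truth.

# Default PT -> primary SOC assignments used by the generator; a subset of
# the toy dictionary shipped in inst/extdata.
default_synth_events <- function() {
  c("Diarrhoea"                 = "Gastrointestinal disorders",
    "Constipation"              = "Gastrointestinal disorders",
    "Nausea"                    = "Gastrointestinal disorders",
    "Vomiting"                  = "Gastrointestinal disorders",
    "Abdominal discomfort"      = "Gastrointestinal disorders",
    "Product taste abnormal"    = "Product issues",
    "Product solubility abnormal" = "Product issues",
    "Throat irritation"         = "Respiratory, thoracic and mediastinal disorders",
    "Cough"                     = "Respiratory, thoracic and mediastinal disorders",
    "Headache"                  = "Nervous system disorders",
    "Dizziness"                 = "Nervous system disorders",
    "Rash"                      = "Skin and subcutaneous tissue disorders",
    "Pruritus"                  = "Skin and subcutaneous tissue disorders",
    "Arthralgia"                = "Musculoskeletal and connective tissue disorders",
    "Fatigue"                   = "General disorders and administration site conditions",
    "Drug ineffective"          = "General disorders and administration site conditions",
    "Blood glucose increased"   = "Investigations",
    "Weight decreased"          = "Investigations",
    "Anxiety"                   = "Psychiatric disorders",
    "Insomnia"                  = "Psychiatric disorders",
    "Night blindness"           = "Eye disorders",
    "Haematuria"                = "Renal and urinary disorders")
}

# Reaction assigned when no configured event fires, so every case carries at
# least one reaction row (as in the real database).
FILLER_PT <- "Unevaluable event"
FILLER_SOC <- "General disorders and administration site conditions"

#' Configuration for the synthetic report generator
#'
#' Builds and validates a [generate_quarter()] configuration. Categorical
#' defaults follow the demographic mix typical of consumer-dominated
#' spontaneous-report corpora (mostly female, mostly age-unknown, mostly US,
#' mostly consumer-reported); the onset distribution defaults to an
#' early-weighted Weibull (shape < 1) as seen for acute drug reactions.
#'
#' @param n_cases number of unique cases (CASEIDs) to generate
#' @param drugs character vector of drug names
#' @param target_drug name of the drug of interest; must be in `drugs`
#' @param drug_probs probability of each drug being the case's primary
#'   suspect; named like `drugs`, sums to 1
#' @param events named character vector mapping each preferred term (name)
#'   to its primary system organ class (value)
#' @param background_event_probs per-event reporting probability under a
#'   rate ratio of 1; named like `events`, each in \[0,1\], sum <= 1
#' @param rr_matrix drugs x events matrix of reporting-rate ratios (>= 0);
#'   the per-case event probability is `min(1, rr * background)`
#' @param duplicate_rate fraction of cases emitted as two report versions
#' @param deletion_rate fraction of cases put on the deletion list
#' @param sex_probs,age_probs,country_probs,reporter_probs,outcome_probs
#'   categorical distributions with an explicit `"missing"` category, each
#'   summing to 1
#' @param onset_shape,onset_scale Weibull shape (dimensionless) and scale
#'   (days) of the time-to-onset distribution
#' @param onset_missing_rate fraction of cases lacking usable therapy/event
#'   dates (most spontaneous reports omit them)
#' @param false_date_rate fraction of dated cases whose event date precedes
#'   therapy start (a data-entry error downstream code must exclude)
#' @param partial_date_rate fraction of dated cases whose therapy start has
#'   only month precision
#' @param quarter quarter label, e.g. `"24Q1"`
#' @param seed integer RNG seed; identical configs give identical bundles
#' @return an object of class `synth_config`
#' @seealso [generate_quarter()], [plant_signal()]
#' @export
synth_config <- function(n_cases = 20000,
                         drugs = c("CHOLESTYRAMINE", sprintf("COMPARATOR %02d", 1:9)),
                         target_drug = drugs[[1]],
                         drug_probs = NULL,
                         events = default_synth_events(),
                         background_event_probs = NULL,
                         rr_matrix = NULL,
                         duplicate_rate = 0.10,
                         deletion_rate = 0.02,
                         sex_probs = c(M = 341, F = 878, missing = 195) / 1414,
                         age_probs = c("<18" = 7, "18-65" = 258, ">65" = 340, missing = 809) / 1414,
                         country_probs = c(US = 1271, FR = 7, DE = 7, GB = 5, DK = 3, missing = 121) / 1414,
                         reporter_probs = c(CN = 988, HP = 36, OT = 42, PH = 123, MD = 183, missing = 42) / 1414,
                         outcome_probs = c(LT = 10, HO = 57, DS = 12, DE = 5, RI = 8, CA = 10, OT = 151,
                                           missing = 1161) / 1414,
                         onset_shape = 0.8,
                         onset_scale = 10,
                         onset_missing_rate = 0.75,
                         false_date_rate = 0.01,
                         partial_date_rate = 0.02,
                         quarter = "24Q1",
                         seed = 1L) {
  if (!is_count(n_cases)) stop("invalid 'n_cases': must be a nonnegative integer", call. = FALSE)
  drugs <- as.character(drugs)
  if (anyDuplicated(drugs)) stop("invalid 'drugs': names must be unique", call. = FALSE)
  if (!target_drug %in% drugs) stop("invalid 'target_drug': not in 'drugs'", call. = FALSE)
  if (is.null(drug_probs)) {
    drug_probs <- stats::setNames(rep((1 - 0.1) / (length(drugs) - 1), length(drugs)), drugs)
    drug_probs[target_drug] <- if (length(drugs) == 1) 1 else 0.1
  }
  if (is.null(background_event_probs)) {
    # heterogeneous baseline rates, frequent GI terms down to rare ones
    background_event_probs <- stats::setNames(
      rep(c(0.06, 0.04, 0.03, 0.02, 0.01), length.out = length(events)), names(events))
  }
  if (is.null(rr_matrix)) {
    rr_matrix <- matrix(1, length(drugs), length(events),
                        dimnames = list(drugs, names(events)))
  }

  cfg <- structure(list(
    n_cases = as.integer(n_cases), drugs = drugs, target_drug = target_drug,
    drug_probs = drug_probs, events = events,
    background_event_probs = background_event_probs, rr_matrix = rr_matrix,
    duplicate_rate = duplicate_rate, deletion_rate = deletion_rate,
    sex_probs = sex_probs, age_probs = age_probs, country_probs = country_probs,
    reporter_probs = reporter_probs, outcome_probs = outcome_probs,
    onset_shape = onset_shape, onset_scale = onset_scale,
    onset_missing_rate = onset_missing_rate, false_date_rate = false_date_rate,
    partial_date_rate = partial_date_rate,
    quarter = quarter, seed = as.integer(seed)), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  check_prob_vec <- function(p, field) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
      stop(sprintf("invalid '%s': probabilities must be in [0,1]", field), call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop(sprintf("invalid '%s': probabilities must sum to 1 (got %.12g)", field, sum(p)),
           call. = FALSE)
    if (is.null(names(p)) || !"missing" %in% names(p) && field != "drug_probs")
      stop(sprintf("invalid '%s': must be named and include a 'missing' category", field),
           call. = FALSE)
  }
  for (f in c("sex_probs", "age_probs", "country_probs", "reporter_probs", "outcome_probs"))
    check_prob_vec(cfg[[f]], f)
  p <- cfg$drug_probs
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9 ||
      !identical(sort(names(p)), sort(cfg$drugs)))
    stop("invalid 'drug_probs': must be named by drug and sum to 1", call. = FALSE)
  b <- cfg$background_event_probs
  if (!is.numeric(b) || anyNA(b) || any(b < 0) || any(b > 1) ||
      !identical(sort(names(b)), sort(names(cfg$events))))
    stop("invalid 'background_event_probs': must be named by event, each in [0,1]", call. = FALSE)
  if (sum(b) > 1 + 1e-9)
    stop("invalid 'background_event_probs': sum must be <= 1", call. = FALSE)
  rr <- cfg$rr_matrix
  if (!is.matrix(rr) || !all(is.finite(rr)) || any(rr < 0) ||
      !identical(rownames(rr), cfg$drugs) || !identical(colnames(rr), names(cfg$events)))
    stop("invalid 'rr_matrix': must be a finite nonnegative drugs x events matrix", call. = FALSE)
  for (f in c("duplicate_rate", "deletion_rate", "onset_missing_rate",
              "false_date_rate", "partial_date_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("invalid '%s': must be a fraction in [0,1]", f), call. = FALSE)
  }
  if (!is.numeric(cfg$onset_shape) || cfg$onset_shape <= 0)
    stop("invalid 'onset_shape': must be > 0", call. = FALSE)
  if (!is.numeric(cfg$onset_scale) || cfg$onset_scale <= 0)
    stop("invalid 'onset_scale': must be > 0", call. = FALSE)
  if (!grepl("^[0-9]{2}Q[1-4]$", cfg$quarter))
    stop("invalid 'quarter': expected a label like '24Q1'", call. = FALSE)
  invisible(cfg)
}

#' Plant a drug-event signal in a synthetic configuration
#'
#' Sets the reporting-rate ratio for one drug-event pair, leaving the rest
#' of the configuration untouched.
#'
#' @param config a [synth_config()]
#' @param drug,event names of the pair
#' @param rr reporting-rate ratio (>= 0)
#' @return the modified `synth_config`
#' @export
plant_signal <- function(config, drug = config$target_drug,
                         event = names(config$events)[[1]], rr = 5) {
  stopifnot(inherits(config, "synth_config"))
  if (!drug %in% rownames(config$rr_matrix)) stop("unknown drug: ", drug, call. = FALSE)
  if (!event %in% colnames(config$rr_matrix)) stop("unknown event: ", event, call. = FALSE)
  config$rr_matrix[drug, event] <- rr
  validate_synth_config(config)
  config
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  cases: %d  quarter: %s  seed: %d\n", x$n_cases, x$quarter, x$seed))
  cat(sprintf("  drugs: %d (target: %s)  events: %d\n",
              length(x$drugs), x$target_drug, length(x$events)))
  planted <- which(x$rr_matrix != 1, arr.ind = TRUE)
  if (nrow(planted)) {
    cat("  planted rate ratios:\n")
    for (i in seq_len(nrow(planted)))
      cat(sprintf("    %s / %s: rr = %g\n", rownames(x$rr_matrix)[planted[i, 1]],
                  colnames(x$rr_matrix)[planted[i, 2]],
                  x$rr_matrix[planted[i, 1], planted[i, 2]]))
  }
  cat(sprintf("  onset: Weibull(shape=%g, scale=%g d), %.0f%% missing dates\n",
              x$onset_shape, x$onset_scale, 100 * x$onset_missing_rate))
  cat(sprintf("  duplicates: %.0f%%  deletions: %.0f%%\n",
              100 * x$duplicate_rate, 100 * x$deletion_rate))
  invisible(x)
}

quarter_dates <- function(quarter) {
  yy <- as.integer(substr(quarter, 1, 2))
  q <- as.integer(substr(quarter, 4, 4))
  year <- 2000L + yy
  start <- as.Date(sprintf("%d-%02d-01", year, (q - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1
  seq(start, end, by = "day")
}

sample_cat <- function(probs, n) {
  if (n == 0) return(character())
  sample(names(probs), n, replace = TRUE, prob = probs)
}

empty_bundle_tables <- function() {
  chr0 <- character()
  list(
    demo = data.table::data.table(primaryid = chr0, caseid = chr0, fda_dt = chr0,
                                  event_dt = chr0, age = chr0, age_cod = chr0, sex = chr0,
                                  occp_cod = chr0, occr_country = chr0),
    drug = data.table::data.table(primaryid = chr0, caseid = chr0, drug_seq = chr0,
                                  role_cod = chr0, drugname = chr0),
    reac = data.table::data.table(primaryid = chr0, caseid = chr0, pt = chr0),
    outc = data.table::data.table(primaryid = chr0, caseid = chr0, outc_cod = chr0),
    ther = data.table::data.table(primaryid = chr0, caseid = chr0, dsg_drug_seq = chr0,
                                  start_dt = chr0))
}

#' Generate one synthetic FAERS-like quarter
#'
#' Draws `n_cases` unique safety reports under the configured demographic,
#' drug and event distributions, then emits older duplicate versions for a
#' fraction of cases and a deletion list. Duplicate versions share the
#' CASEID and have either an earlier FDA receipt date or (for half of them)
#' the same date with a smaller PRIMARYID, so the keep-latest deduplication
#' rule has unambiguous ground truth.
#'
#' @param config a [synth_config()]
#' @return a `quarter_bundle`: list with data.tables `demo`, `drug`, `reac`,
#'   `outc`, `ther`, a `deleted` character vector of CASEIDs, the `quarter`
#'   label, and a `truth` list (retained version per case, per-case onset
#'   days, target drug, the rate-ratio matrix) for use in tests
#' @examples
#' b <- generate_quarter(synth_config(n_cases = 100, seed = 42))
#' nrow(b$demo)
#' @export
generate_quarter <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  with_seed_preserved(config$seed, generate_quarter_impl(config))
}

generate_quarter_impl <- function(config) {
  n <- config$n_cases
  if (n == 0) {
    tabs <- empty_bundle_tables()
    return(structure(c(tabs, list(deleted = character(), quarter = config$quarter,
                                  truth = list(retained = data.table::data.table(
                                    caseid = character(), primaryid = character()),
                                    onset_days = integer(), target_drug = config$target_drug,
                                    rr_matrix = config$rr_matrix))),
                     class = "quarter_bundle"))
  }
  caseid <- as.character(10000000 + seq_len(n))
  primaryid <- paste0(caseid, "2")           # latest version carries suffix 2
  qdays <- quarter_dates(config$quarter)
  fda_date <- sample(qdays, n, replace = TRUE)

  sex <- sample_cat(config$sex_probs, n)
  sex[sex == "missing"] <- ""
  agegrp <- sample_cat(config$age_probs, n)
  age_val <- rep("", n); age_cod <- rep("", n)
  lo <- c("<18" = 1, "18-65" = 18, ">65" = 66)
  hi <- c("<18" = 17, "18-65" = 65, ">65" = 95)
  for (g in names(lo)) {
    idx <- which(agegrp == g)
    if (!length(idx)) next
    yrs <- sample(lo[[g]]:hi[[g]], length(idx), replace = TRUE)
    age_val[idx] <- as.character(yrs)
    age_cod[idx] <- "YR"
    # a sprinkle of month-coded adult ages exercises unit conversion
    mon <- idx[stats::runif(length(idx)) < 0.05]
    age_val[match(mon, seq_len(n))] <- as.character(
      as.integer(age_val[mon]) * 12L)
    age_cod[mon] <- "MON"
  }
  country <- sample_cat(config$country_probs, n)
  country[country == "missing"] <- ""
  reporter <- sample_cat(config$reporter_probs, n)
  reporter[reporter == "missing"] <- ""

  # primary-suspect drug and concomitants
  drug_idx <- sample(seq_along(config$drugs), n, replace = TRUE, prob = config$drug_probs)
  ps_name <- config$drugs[drug_idx]
  n_con <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))

  # reactions: independent Bernoulli per configured event, probability
  # min(1, rr * background); cases with no hit get the filler reaction
  ev <- names(config$events)
  bg <- config$background_event_probs[ev]
  P <- config$rr_matrix[drug_idx, ev, drop = FALSE] *
    matrix(bg, n, length(ev), byrow = TRUE)
  P <- pmin(P, 1)
  hit <- matrix(stats::runif(n * length(ev)), n, length(ev)) < P

  # onset: continuous Weibull floored to whole days; day 0 = immediate
  has_dates <- stats::runif(n) >= config$onset_missing_rate
  onset <- as.integer(floor(stats::rweibull(n, config$onset_shape, config$onset_scale)))
  lag <- sample(0:30, n, replace = TRUE)            # event-to-receipt lag
  start_date <- fda_date - lag - onset
  event_date <- start_date + onset
  is_false <- has_dates & stats::runif(n) < config$false_date_rate
  event_date[is_false] <- start_date[is_false] - sample(1:30, sum(is_false), replace = TRUE)
  is_partial <- has_dates & !is_false & stats::runif(n) < config$partial_date_rate
  start_dt <- format(start_date, "%Y%m%d")
  start_dt[is_partial] <- substr(start_dt[is_partial], 1, 6)
  event_dt <- format(event_date, "%Y%m%d")
  event_dt[!has_dates] <- ""

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format(fda_date, "%Y%m%d"), event_dt = event_dt,
    age = age_val, age_cod = age_cod, sex = sex,
    occp_cod = reporter, occr_country = country)

  hits <- which(hit, arr.ind = TRUE)
  reac <- data.table::data.table(
    primaryid = primaryid[hits[, 1]], caseid = caseid[hits[, 1]], pt = ev[hits[, 2]])
  no_event <- setdiff(seq_len(n), unique(hits[, 1]))
  if (length(no_event))
    reac <- rbind(reac, data.table::data.table(
      primaryid = primaryid[no_event], caseid = caseid[no_event], pt = FILLER_PT))

  con_rows <- rep(seq_len(n), n_con)
  con_drug <- config$drugs[sample(seq_along(config$drugs), length(con_rows), replace = TRUE)]
  drug <- rbind(
    data.table::data.table(primaryid = primaryid, caseid = caseid, drug_seq = "1",
                           role_cod = "PS", drugname = ps_name),
    data.table::data.table(primaryid = primaryid[con_rows], caseid = caseid[con_rows],
                           drug_seq = as.character(1L + sequence(n_con[n_con > 0])),
                           role_cod = "C", drugname = con_drug))

  outcome <- sample_cat(config$outcome_probs, n)
  has_outc <- outcome != "missing"
  outc <- data.table::data.table(primaryid = primaryid[has_outc], caseid = caseid[has_outc],
                                 outc_cod = outcome[has_outc])

  ther <- data.table::data.table(primaryid = primaryid[has_dates], caseid = caseid[has_dates],
                                 dsg_drug_seq = "1", start_dt = start_dt[has_dates])

  # older duplicate versions: suffix 1 (smaller PRIMARYID); half get an
  # earlier FDA_DT, half tie on FDA_DT so the PRIMARYID rule is exercised
  n_dup <- floor(config$duplicate_rate * n)
  dup_idx <- sort(sample(seq_len(n), n_dup))
  if (n_dup) {
    tie <- stats::runif(n_dup) < 0.5
    old_date <- fda_date[dup_idx] - ifelse(tie, 0L, sample(1:30, n_dup, replace = TRUE))
    old_pid <- paste0(caseid[dup_idx], "1")
    demo_old <- demo[dup_idx]
    demo_old[, `:=`(primaryid = old_pid, fda_dt = format(old_date, "%Y%m%d"))]
    demo <- rbind(demo, demo_old)
    dup_pids <- primaryid[dup_idx]
    reattach <- function(tab) {
      old <- tab[tab$primaryid %in% dup_pids]
      if (!nrow(old)) return(tab)
      old[, primaryid := paste0(caseid, "1")]
      rbind(tab, old)
    }
    drug <- reattach(drug); reac <- reattach(reac)
    outc <- reattach(outc); ther <- reattach(ther)
  }

  deleted <- sort(sample(caseid, floor(config$deletion_rate * n)))

  for (tab in list(demo, drug, reac, outc, ther)) data.table::setkey(tab, NULL)
  data.table::setorder(demo, primaryid)
  data.table::setorder(drug, primaryid, drug_seq, role_cod, drugname)
  data.table::setorder(reac, primaryid, pt)
  data.table::setorder(outc, primaryid, outc_cod)
  data.table::setorder(ther, primaryid, dsg_drug_seq)

  onset_truth <- onset
  onset_truth[!has_dates | is_false | is_partial] <- NA_integer_
  truth <- list(
    retained = data.table::data.table(caseid = caseid, primaryid = primaryid),
    duplicated_caseids = caseid[dup_idx],
    deleted_caseids = deleted,
    onset_days = stats::setNames(onset_truth, caseid),
    ps_drug = stats::setNames(ps_name, caseid),
    event_hits = hit,
    target_drug = config$target_drug,
    rr_matrix = config$rr_matrix)

  structure(list(demo = demo, drug = drug, reac = reac, outc = outc, ther = ther,
                 deleted = deleted, quarter = config$quarter, truth = truth),
            class = "quarter_bundle")
}

#' @export
print.quarter_bundle <- function(x, ...) {
  cat(sprintf("<quarter_bundle %s> demo: %d rows (%d cases), drug: %d, reac: %d, outc: %d, ther: %d, deleted: %d\n",
              x$quarter, nrow(x$demo), length(unique(x$demo$caseid)), nrow(x$drug),
              nrow(x$reac), nrow(x$outc), nrow(x$ther), length(x$deleted)))
  invisible(x)
}

#' Write a quarter bundle as FAERS-dialect ASCII files
#'
#' Emits one '$'-delimited UTF-8 text file per table (`DEMOyyQq.txt`, ...)
#' with a single header line, plus a deletion list (`DELETEDyyQq.txt`, one
#' CASEID per line). The dialect has no quoting, so fields containing a
#' literal `'$'` are rejected with an error rather than silently corrupting
#' the column structure.
#'
#' @param bundle a `quarter_bundle`
#' @param directory output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_faers_ascii <- function(bundle, directory) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)
  paths <- character()
  for (tab in names(faers_schemas())) {
    dt <- bundle[[tab]]
    bad <- vapply(dt, function(col) any(grepl("$", col, fixed = TRUE)), logical(1))
    if (any(bad))
      stop(sprintf("table '%s' column '%s' contains the field delimiter '$'; the FAERS dialect has no quoting",
                   tab, names(dt)[which(bad)[1]]), call. = FALSE)
    path <- file.path(directory, paste0(toupper(tab), bundle$quarter, ".txt"))
    header <- paste(toupper(names(dt)), collapse = "$")
    body <- do.call(paste, c(unname(as.list(dt)), sep = "$"))
    con <- file(path, open = "wb")
    writeLines(c(header, body), con, useBytes = TRUE)
    close(con)
    paths <- c(paths, path)
  }
  del_path <- file.path(directory, paste0("DELETED", bundle$quarter, ".txt"))
  con <- file(del_path, open = "wb")
  writeLines(bundle$deleted, con, useBytes = TRUE)
  close(con)
  invisible(c(paths, del_path))
}
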