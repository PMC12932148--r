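# Reading FAERS-style quarterly ASCII extracts.
#
# Dialect: '$'-delimited, one header line, no quoting. Real extracts carry
# more columns than the pipeline needs; tables are accepted as long as the
# schema columns are present (case-insensitive) and extra columns are
# ignored. Dates are kept as digit strings with recorded precision; nothing
# is imputed at read time.

faers_schemas <- function() {
  list(
    demo = list(cols = c("primaryid", "caseid", "fda_dt", "event_dt", "age",
                         "age_cod", "sex", "occp_cod", "occr_country"),
                mandatory = c("primaryid", "caseid", "fda_dt")),
    drug = list(cols = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
                mandatory = c("primaryid", "role_cod", "drugname")),
    reac = list(cols = c("primaryid", "caseid", "pt"),
                mandatory = c("primaryid", "pt")),
    outc = list(cols = c("primaryid", "caseid", "outc_cod"),
                mandatory = c("primaryid", "outc_cod")),
    ther = list(cols = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"),
                mandatory = c("primaryid", "start_dt")))
}

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Read one FAERS ASCII table
#'
#' Parses a '$'-delimited table against the named schema. Lines with extra
#' fields (an unescaped '$' inside free text) are truncated to the header
#' width with a warning; lines with fewer fields are padded with empties.
#' Both are tallied in the parse report rather than aborting the read.
#'
#' @param path file path
#' @param table schema name: one of `"demo"`, `"drug"`, `"reac"`, `"outc"`,
#'   `"ther"`
#' @return a data.table with the schema's columns (all character, trimmed;
#'   empty string = missing) and attribute `"parse_report"` holding line
#'   counts: `n_lines`, `n_records`, `n_truncated`, `n_padded`
#' @export
read_faers_table <- function(path, table) {
  schemas <- faers_schemas()
  if (!table %in% names(schemas)) stop("unknown table schema: ", table, call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- schemas[[table]]
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop(sprintf("file '%s' is empty (no header line)", path), call. = FALSE)
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  if (length(header) < 2)
    stop(sprintf("format error in '%s': header line %s is not '$'-delimited",
                 path, shQuote(lines[[1]])), call. = FALSE)
  missing_cols <- setdiff(schema$mandatory, header)
  if (length(missing_cols))
    stop(sprintf("schema error in '%s': missing mandatory column(s) %s",
                 path, paste(toupper(missing_cols), collapse = ", ")), call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  nf <- length(header)
  n_truncated <- 0L; n_padded <- 0L
  if (length(body)) {
    # exact field count per line: delimiters + 1 (strsplit drops trailing
    # empty fields, so count '$' characters instead)
    n_fields <- nchar(body) - nchar(gsub("$", "", body, fixed = TRUE)) + 1L
    n_truncated <- sum(n_fields > nf)
    n_padded <- sum(n_fields < nf)
    if (n_truncated)
      warning(sprintf("%s: %d line(s) with extra '$'-delimited fields truncated to %d columns",
                      basename(path), n_truncated, nf), call. = FALSE)
    parts <- data.table::tstrsplit(body, "$", fixed = TRUE)
    if (length(parts) > nf) parts <- parts[seq_len(nf)]
    if (length(parts) < nf)
      parts <- c(parts, rep(list(rep(NA_character_, length(body))), nf - length(parts)))
    dt <- data.table::setDT(parts)
    data.table::setnames(dt, header)
    for (j in seq_along(dt)) {
      col <- trimws(dt[[j]])
      col[is.na(col)] <- ""
      data.table::set(dt, j = j, value = col)
    }
  } else {
    dt <- data.table::setnames(
      data.table::as.data.table(rep(list(character()), nf)), header)
  }
  keep <- intersect(schema$cols, names(dt))
  dt <- dt[, keep, with = FALSE]
  for (col in setdiff(schema$cols, names(dt)))
    dt[, (col) := ""]
  data.table::setcolorder(dt, schema$cols)
  data.table::setattr(dt, "parse_report",
                      list(n_lines = length(lines), n_records = nrow(dt),
                           n_truncated = n_truncated, n_padded = n_padded))
  dt[]
}

#' Read a quarterly directory into a bundle
#'
#' Locates the five tables (`DEMO*.txt`, `DRUG*.txt`, `REAC*.txt`,
#' `OUTC*.txt`, `THER*.txt`) plus an optional deletion list
#' (`DELETED*.txt`, one CASEID per line), validates referential integrity,
#' and drops child rows whose PRIMARYID has no DEMO parent, counting them as
#' orphans in the parse report.
#'
#' @param directory path containing the quarterly files
#' @return a `quarter_bundle` with a `parse_report` attribute: per-table
#'   line counts and orphan counts
#' @export
read_quarter <- function(directory) {
  if (!dir.exists(directory)) stop("directory not found: ", directory, call. = FALSE)
  files <- list.files(directory)
  find1 <- function(prefix) {
    # DELETED also starts with DE; anchor table names before digits
    hits <- files[grepl(paste0("^", prefix, "[0-9]{2}Q[1-4].*\\.(txt|TXT)$"), files)]
    if (!length(hits)) hits <- files[grepl(paste0("^", prefix, ".*\\.(txt|TXT)$"), files, ignore.case = TRUE)]
    hits
  }
  tabs <- c("demo", "drug", "reac", "outc", "ther")
  found <- lapply(toupper(tabs), find1)
  names(found) <- tabs
  missing_tabs <- tabs[lengths(found) == 0]
  if (length(missing_tabs))
    stop("missing mandatory table file(s): ", paste(toupper(missing_tabs), collapse = ", "),
         call. = FALSE)
  bundle <- list()
  report <- list(tables = list(), orphans = list())
  for (tab in tabs) {
    dt <- read_faers_table(file.path(directory, found[[tab]][[1]]), tab)
    report$tables[[tab]] <- attr(dt, "parse_report")
    bundle[[tab]] <- dt
  }
  del_file <- files[grepl("^DELETE.*\\.(txt|TXT)$", files, ignore.case = TRUE)]
  bundle$deleted <- if (length(del_file)) {
    d <- trimws(readLines(file.path(directory, del_file[[1]]), warn = FALSE))
    sort(unique(d[nzchar(d)]))
  } else character()

  parents <- bundle$demo$primaryid
  for (tab in c("drug", "reac", "outc", "ther")) {
    orphan <- !(bundle[[tab]]$primaryid %in% parents)
    report$orphans[[tab]] <- sum(orphan)
    if (any(orphan)) bundle[[tab]] <- bundle[[tab]][!orphan]
  }
  # recover the CASEID of child rows from DEMO when the file omitted it
  case_of <- stats::setNames(bundle$demo$caseid, bundle$demo$primaryid)
  for (tab in c("drug", "reac", "outc", "ther")) {
    blank <- !nzchar(bundle[[tab]]$caseid)
    if (any(blank))
      data.table::set(bundle[[tab]], which(blank), "caseid",
                      unname(case_of[bundle[[tab]]$primaryid[blank]]))
  }

  qlab <- regmatches(found$demo[[1]], regexpr("[0-9]{2}Q[1-4]", found$demo[[1]]))
  bundle$quarter <- if (length(qlab)) qlab else "00Q0"
  structure(c(bundle, list(parse_report = report)), class = "quarter_bundle")
}

#' Convert a reported age to an age group
#'
#' Converts the FAERS AGE/AGE_COD pair to years (DEC x10, MON /12, WK /52,
#' DY /365.25) and bins into `<18`, `18-65` (both boundaries inclusive) and
#' `>65`. A missing unit with a plausible year value (0 < v < 120) is taken
#' as years; negative or unparseable ages are flagged missing.
#'
#' @param age_value numeric age or digit string (empty = missing)
#' @param age_unit FAERS unit code: `YR`, `MON`, `WK`, `DY`, `DEC`, or empty
#' @return character vector in `c("<18", "18-65", ">65", "missing")`
#' @export
age_to_group <- function(age_value, age_unit = "") {
  v <- suppressWarnings(as.numeric(age_value))
  u <- toupper(trimws(as.character(age_unit)))
  u <- rep_len(u, length(v))
  years <- rep(NA_real_, length(v))
  years[u == "YR"] <- v[u == "YR"]
  years[u == "DEC"] <- v[u == "DEC"] * 10
  years[u == "MON"] <- v[u == "MON"] / 12
  years[u == "WK"] <- v[u == "WK"] / 52
  years[u == "DY"] <- v[u == "DY"] / 365.25
  fallback <- !(u %in% c("YR", "DEC", "MON", "WK", "DY")) & !is.na(v) & v > 0 & v < 120
  years[fallback] <- v[fallback]
  years[!is.na(v) & v < 0] <- NA_real_
  out <- rep("missing", length(v))
  out[!is.na(years) & years < 18] <- "<18"
  out[!is.na(years) & years >= 18 & years <= 65] <- "18-65"
  out[!is.na(years) & years > 65] <- ">65"
  out
}

REPORTER_LABELS <- c(CN = "Consumer", MD = "Physician", PH = "Pharmacist",
                     OT = "Other health professional", HP = "health-professor")

reporter_label <- function(code) {
  code <- toupper(trimws(code))
  out <- unname(REPORTER_LABELS[code])
  out[is.na(out) | !nzchar(code)] <- "missing"
  out
}
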