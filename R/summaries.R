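# Descriptive characteristics tables: sex, age group, reporter, reporting
# year, top reporting countries, and outcome distribution.

#' Frequency table with fixed denominator
#'
#' Counts categories and reports percentages of the given denominator,
#' rounded half-up to two decimals.
#'
#' @param categories character vector of category values (`"missing"` is
#'   relabelled `"Not specified"`)
#' @param denominator count to divide by (defaults to `length(categories)`)
#' @param label dimension label stored on the table
#' @return data.frame `category`, `n`, `pct` with attributes `label` and
#'   `denominator`
#' @export
freq_table <- function(categories, denominator = length(categories), label = "") {
  categories <- as.character(categories)
  categories[categories == "missing"] <- "Not specified"
  counts <- table(categories)
  out <- data.frame(category = names(counts), n = as.integer(counts),
                    pct = pct2(as.integer(counts), denominator))
  # most frequent first, "Not specified" last
  ns <- out$category == "Not specified"
  out <- rbind(out[!ns, ][order(-out$n[!ns], out$category[!ns]), ], out[ns, ])
  rownames(out) <- NULL
  structure(out, label = label, denominator = denominator)
}

OUTCOME_LABELS <- c(DE = "Death", LT = "Life-threatening",
                    HO = "Hospitalization—initial or prolonged",
                    DS = "Disability", CA = "Congenital anomaly",
                    RI = "Required intervention to prevent permanent impairment/damage",
                    OT = "Other")

#' Clinical characteristics of a report corpus
#'
#' Builds the standard descriptive tables for a curated, drug-filtered
#' corpus. Sex, age group, reporter, reporting year and country use the
#' case count as denominator (missing shown as "Not specified"); the
#' country table keeps the top five countries. The outcome table counts
#' each outcome code once per case and uses the total number of reported
#' outcome codes as denominator, so its percentages describe the mix of
#' reported outcomes rather than their prevalence among cases.
#'
#' @param reports a `report_set`
#' @return named list of frequency tables: `sex`, `age`, `reporter`,
#'   `year`, `country`, `outcome`; attribute `n_cases` is the case count
#' @export
characteristics_table <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  cs <- reports$cases
  if (!nrow(cs)) stop("no cases to describe", call. = FALSE)
  n <- nrow(cs)

  year <- ifelse(is.na(cs$event_year), "missing", as.character(cs$event_year))
  yr_tab <- freq_table(year, n, "Reporting year")
  yr_tab <- yr_tab[order(yr_tab$category == "Not specified", yr_tab$category), ]
  rownames(yr_tab) <- NULL

  country_tab <- freq_table(cs$country, n, "Top 5 reporting countries")
  known <- country_tab[country_tab$category != "Not specified", ]
  country_tab <- utils::head(known, 5)

  oc <- unique(reports$outcomes[, .(primaryid, outc_cod = toupper(trimws(outc_cod)))])
  oc <- oc[outc_cod %in% names(OUTCOME_LABELS)]
  outcome_tab <- freq_table(unname(OUTCOME_LABELS[oc$outc_cod]), nrow(oc), "Outcome")

  structure(list(
    sex = freq_table(ifelse(cs$sex == "M", "Male", ifelse(cs$sex == "F", "Female", "missing")),
                     n, "Sex"),
    age = freq_table(cs$age_group, n, "Age"),
    reporter = freq_table(cs$reporter, n, "Reporter"),
    year = yr_tab,
    country = country_tab,
    outcome = outcome_tab),
    n_cases = n, class = "characteristics_table")
}

#' @export
print.characteristics_table <- function(x, ...) {
  cat(sprintf("Clinical characteristics (n = %d cases)\n", attr(x, "n_cases")))
  for (nm in names(x)) {
    cat(sprintf("\n%s (denominator %d):\n", attr(x[[nm]], "label"),
                attr(x[[nm]], "denominator")))
    print.data.frame(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Stack characteristics tables into one exportable data.frame
#'
#' @param ct a `characteristics_table`
#' @return data.frame `dimension`, `category`, `n`, `pct`
#' @export
flatten_characteristics <- function(ct) {
  do.call(rbind, lapply(names(ct), function(nm) {
    data.frame(dimension = attr(ct[[nm]], "label"), ct[[nm]], row.names = NULL)
  }))
}
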