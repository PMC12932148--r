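# End-to-end pipeline: ingest -> deduplicate -> code -> describe ->
# detect (PT, SOC) -> onset, with a machine-readable run manifest.

#' Pipeline run configuration
#'
#' @param quarter_dirs character vector of directories, each holding one
#'   quarter's ASCII tables
#' @param target_patterns drug-name patterns defining the target drug
#' @param meddra_map a `meddra_map`, or path to a two-column PT/SOC mapping
#'   file; `NULL` uses the shipped toy dictionary
#' @param criteria a [signal_criteria()]
#' @param zero_policy Weibull zero-day policy, see [weibull_fit()]
#' @param out_dir output directory for the artifact files
#' @return a `pv_config` list
#' @export
pv_config <- function(quarter_dirs, target_patterns, meddra_map = NULL,
                      criteria = signal_criteria(),
                      zero_policy = "shift_half_day", out_dir = tempfile("pvrun")) {
  stopifnot(length(quarter_dirs) >= 1, length(target_patterns) >= 1)
  missing_dirs <- quarter_dirs[!dir.exists(quarter_dirs)]
  if (length(missing_dirs))
    stop("quarter directories not found: ", paste(missing_dirs, collapse = ", "),
         call. = FALSE)
  if (is.character(meddra_map)) meddra_map <- read_meddra_map(meddra_map)
  structure(list(quarter_dirs = quarter_dirs, target_patterns = target_patterns,
                 meddra_map = meddra_map, criteria = criteria,
                 zero_policy = zero_policy, out_dir = out_dir),
            class = "pv_config")
}

#' All tunable defaults of the signal-detection pipeline
#'
#' Returns every convention the pipeline relies on where the published
#' methodology leaves a choice open, so a run can be audited: estimator
#' constants, classification thresholds, prior start values, date and
#' zero-day policies.
#'
#' @return a named list
#' @export
pv_defaults <- function() {
  list(ror_z = 1.96, yates_correction = 0.5,
       bcpnn_priors = c(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1),
       ic025_rule = "E(IC) - 2*sqrt(V(IC))",
       gps_prior_start = c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, pi = 1/3),
       ebgm_lower_quantile = 0.05,
       criteria = unclass(signal_criteria()),
       dedup_rule = "per CASEID keep max FDA_DT, tie -> max PRIMARYID; then deletion list",
       primaryid_comparison = "numeric when all parse, else lexicographic",
       age_boundaries = "18 and 65 both inclusive in 18-65",
       age_unit_fallback = "missing unit treated as years when 0 < value < 120",
       onset_definition = "event date - earliest primary-suspect therapy start (day precision only)",
       zero_policy = "shift_half_day",
       quantile_type = 7,
       counting_unit = "case-level presence/absence per term")
}

#' Run the full analysis pipeline
#'
#' Executes ingest, deduplication, SOC coding, descriptive
#' characterization, PT- and SOC-level signal detection, and the
#' time-to-onset analysis; writes all output tables as tab-delimited text
#' plus a JSON run manifest (input file hashes, configuration echo,
#' package and R versions). Any stage failure aborts with the stage name.
#'
#' @param config a [pv_config()]
#' @return invisibly, a named list of output file paths
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pv_config"))
  stage <- function(name, expr) tryCatch(expr, error = function(e) stop_stage(name, e))

  bundles <- stage("ingest", lapply(config$quarter_dirs, read_quarter))
  reports <- stage("dedup", assemble_reports(bundles))
  map <- config$meddra_map %||% toy_meddra_map()
  reports <- stage("code", code_events(reports, map))
  target <- stage("filter", select_primary_suspect(reports, config$target_patterns))

  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  wtsv <- function(x, path) utils::write.table(x, path, sep = "\t", quote = FALSE,
                                               row.names = FALSE)

  chars <- stage("describe", characteristics_table(target))
  wtsv(flatten_characteristics(chars), out("characteristics.tsv"))

  sig_pt <- stage("detect_pt", detect_signals(reports, config$target_patterns,
                                              level = "pt", criteria = config$criteria))
  wtsv(format_signal_table(sig_pt), out("signals_pt.tsv"))
  sig_soc <- stage("detect_soc", detect_signals(reports, config$target_patterns,
                                                level = "soc", criteria = config$criteria))
  wtsv(format_signal_table(sig_soc), out("signals_soc.tsv"))

  onsets <- stage("onset", collect_onsets(target))
  onset_paths <- character()
  if (nrow(onsets$samples)) {
    bins <- bin_onsets(onsets$samples$onset_days)
    wtsv(as.data.frame(bins), out("onset_bins.tsv"))
    wtsv(cumulative_incidence(onsets$samples$onset_days), out("onset_curve.tsv"))
    fit <- tryCatch(weibull_fit(onsets$samples$onset_days, config$zero_policy),
                    error = function(e) NULL)
    mi <- onset_median_iqr(onsets$samples$onset_days)
    onset_summary <- data.frame(
      n = nrow(onsets$samples), median = mi$median, q1 = mi$q1, q3 = mi$q3,
      weibull_shape = if (is.null(fit)) NA else fit$shape,
      weibull_scale = if (is.null(fit)) NA else fit$scale,
      cum30_pct = attr(bins, "cum30_pct"))
    wtsv(onset_summary, out("onset_summary.tsv"))
  }
  wtsv(onsets$exclusions, out("onset_exclusions.tsv"))

  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    r_version = R.version.string,
    quarter_dirs = config$quarter_dirs,
    input_md5 = as.list(tools::md5sum(unlist(lapply(config$quarter_dirs, function(d)
      list.files(d, full.names = TRUE))))),
    target_patterns = config$target_patterns,
    meddra_map_version = attr(map, "version"),
    criteria = unclass(config$criteria),
    zero_policy = config$zero_policy,
    defaults = pv_defaults(),
    n_cases_total = nrow(reports$cases),
    n_cases_target = nrow(target$cases))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  paths <- list.files(config$out_dir, full.names = TRUE)
  invisible(stats::setNames(as.list(paths), basename(paths)))
}
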