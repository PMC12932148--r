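test_that("configuration validation names the offending field", {
  expect_error(synth_config(sex_probs = c(M = 0.5, F = 0.6, missing = 0.1)), "sex_probs")
  expect_error(synth_config(duplicate_rate = 1.5), "duplicate_rate")
  expect_error(synth_config(onset_shape = -1), "onset_shape")
  cfg <- synth_config(n_cases = 10)
  cfg$rr_matrix[1, 1] <- -2
  expect_error(generate_quarter(cfg), "rr_matrix")
})

test_that("an empty configuration yields an empty bundle with valid headers", {
  b <- generate_quarter(synth_config(n_cases = 0))
  expect_s3_class(b, "quarter_bundle")
  expect_identical(nrow(b$demo), 0L)
  d <- withr::local_tempdir()
  write_faers_ascii(b, d)
  expect_identical(length(readLines(file.path(d, "DEMO24Q1.txt"))), 1L)
  b2 <- read_quarter(d)
  expect_identical(nrow(b2$reac), 0L)
})

test_that("generation is deterministic: same seed gives byte-identical files", {
  cfg <- small_config(n_cases = 300, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_faers_ascii(generate_quarter(cfg), d1)
  write_faers_ascii(generate_quarter(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("generated bundles have referential integrity and duplicate structure", {
  b <- generate_quarter(small_config(n_cases = 400, seed = 5))
  pids <- b$demo$primaryid
  for (tab in c("drug", "reac", "outc", "ther"))
    expect_true(all(b[[tab]]$primaryid %in% pids), label = tab)
  # every case has at least one reaction and exactly one PS drug row per version
  expect_true(all(pids %in% b$reac$primaryid))
  ps <- b$drug[b$drug$role_cod == "PS", ]
  expect_identical(sort(ps$primaryid), sort(pids))
  # duplicate versions share CASEID and differ in FDA_DT or PRIMARYID
  dup <- b$truth$duplicated_caseids
  expect_gt(length(dup), 0)
  for (cid in dup) {
    versions <- b$demo[b$demo$caseid == cid, ]
    expect_identical(nrow(versions), 2L)
    expect_true(max(versions$fda_dt) == versions$fda_dt[versions$primaryid == max(versions$primaryid)][1] ||
                  versions$fda_dt[1] != versions$fda_dt[2])
  }
})

test_that("with rr = 1 everywhere the target drug's event rates match background", {
  cfg <- synth_config(n_cases = 50000, seed = 13, duplicate_rate = 0, deletion_rate = 0)
  b <- generate_quarter(cfg)
  ps <- b$drug[b$drug$role_cod == "PS", ]
  target_pid <- ps$primaryid[ps$drugname == cfg$target_drug]
  n_t <- length(target_pid)
  reac_t <- b$reac[b$reac$primaryid %in% target_pid, ]
  for (ev in names(cfg$events)[c(1, 5, 10, 20)]) {
    p0 <- cfg$background_event_probs[[ev]]
    se <- sqrt(p0 * (1 - p0) / n_t)
    phat <- length(unique(reac_t$primaryid[reac_t$pt == ev])) / n_t
    expect_lt(abs(phat - p0), 3 * se, label = ev)
  }
})

test_that("writing rejects fields containing the '$' delimiter", {
  b <- generate_quarter(small_config(n_cases = 5, seed = 2))
  b$drug$drugname[1] <- "BAD$NAME"
  expect_error(write_faers_ascii(b, withr::local_tempdir()), "\\$")
})

test_that("file line counts equal record counts plus one header", {
  b <- generate_quarter(small_config(n_cases = 50, seed = 9))
  d <- withr::local_tempdir()
  write_faers_ascii(b, d)
  for (tab in c("demo", "drug", "reac", "outc", "ther")) {
    f <- file.path(d, paste0(toupper(tab), b$quarter, ".txt"))
    expect_identical(length(readLines(f)), nrow(b[[tab]]) + 1L, label = tab)
  }
})

test_that("write then read round-trips the bundle losslessly", {
  for (seed in c(1, 4)) {
    b <- generate_quarter(small_config(n_cases = 250, seed = seed))
    d <- withr::local_tempdir()
    write_faers_ascii(b, d)
    expect_bundle_tables_equal(b, read_quarter(d))
  }
})

test_that("under a null corpus the ROR criterion flags at most 5% of pairs", {
  # nominal bound: the flag requires the lower 95% bound above 1, a
  # one-sided 2.5% event under independence; 0.05 is the documented bound
  flagged <- 0L; total <- 0L
  for (seed in 1:50) {
    b <- generate_quarter(synth_config(n_cases = 4000, seed = 1000 + seed))
    rep <- code_events(assemble_reports(b), toy_meddra_map())
    tab <- build_contingency(rep, "CHOLESTYRAMINE", level = "pt")
    est <- cbind(tab, ror_estimate(tab$a, tab$b, tab$c, tab$d))
    est <- classify_signals(cbind(est,
                                  prr_estimate(tab$a, tab$b, tab$c, tab$d),
                                  ic_bate(tab$a, tab$b, tab$c, tab$d),
                                  data.frame(ebgm = NA_real_, ebgm05 = NA_real_)))
    flagged <- flagged + sum(est$ror_pos)
    total <- total + nrow(est)
  }
  expect_lte(flagged / total, 0.05)
})
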