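test_that("deduplication keeps the latest receipt date, breaking ties by PRIMARYID", {
  demo <- demo_rows(list("1", "10", "20230101"), list("1", "11", "20230301"),
                    list("2", "5", "20230101"), list("2", "9", "20230101"))
  expect_identical(deduplicate_reports(demo), c("11", "9"))
})

test_that("caseids on the deletion list are removed", {
  demo <- demo_rows(list("1", "10", "20230101"), list("3", "30", "20230201"))
  expect_identical(deduplicate_reports(demo, deletion_list = "3"), "10")
  expect_identical(deduplicate_reports(demo[0, ]), character())
})

test_that("PRIMARYID tie-break compares numerically when numeric, else lexicographically", {
  demo <- demo_rows(list("1", "9", "20230101"), list("1", "10", "20230101"))
  expect_identical(deduplicate_reports(demo), "10")  # numeric: 10 > 9
  demo2 <- demo_rows(list("1", "A9", "20230101"), list("1", "B10", "20230101"))
  expect_identical(deduplicate_reports(demo2), "B10")
})

test_that("deduplication is idempotent and loses only deleted caseids", {
  b <- generate_quarter(small_config(n_cases = 300, seed = 21))
  kept <- deduplicate_reports(b$demo, b$deleted)
  sub <- b$demo[b$demo$primaryid %in% kept, ]
  expect_identical(deduplicate_reports(sub, b$deleted), kept)
  expect_setequal(sub$caseid, setdiff(unique(b$demo$caseid), b$deleted))
})

test_that("on synthetic corpora dedup retains exactly the designated latest versions", {
  for (seed in c(2, 8)) {
    b <- generate_quarter(small_config(n_cases = 400, seed = seed, duplicate_rate = 0.3))
    kept <- deduplicate_reports(b$demo, b$deleted)
    truth <- b$truth$retained
    expected <- sort(truth$primaryid[!truth$caseid %in% b$truth$deleted_caseids])
    expect_identical(sort(kept), expected)
  }
})

test_that("primary-suspect selection normalizes names and respects role codes", {
  b <- generate_quarter(small_config(n_cases = 200, seed = 4))
  rep <- assemble_reports(b)
  rep$drugs$drugname[rep$drugs$role_cod == "PS" &
                       rep$drugs$drugname == "CHOLESTYRAMINE"] <- "Cholestyramine Light "
  sel <- select_primary_suspect(rep, "CHOLESTYRAMINE")
  ps <- sel$drugs[sel$drugs$role_cod == "PS", ]
  expect_true(all(grepl("CHOLESTYRAMINE", normalize_drugname(ps$drugname))))
  expect_gt(nrow(sel$cases), 0)
  # a case carrying the drug only as concomitant is excluded
  only_c <- rep$drugs$primaryid[rep$drugs$role_cod == "C" &
                                  rep$drugs$drugname == "CHOLESTYRAMINE"]
  ps_match <- rep$drugs$primaryid[rep$drugs$role_cod == "PS" &
                                    grepl("CHOLESTYRAMINE", normalize_drugname(rep$drugs$drugname))]
  stray <- setdiff(only_c, ps_match)
  expect_false(any(stray %in% sel$cases$primaryid))
  expect_error(select_primary_suspect(rep, character()), "pattern")
})

test_that("event coding maps PTs to SOCs and reports unmapped terms", {
  b <- generate_quarter(small_config(n_cases = 100, seed = 6))
  rep <- assemble_reports(b)
  rep$reactions$pt[1] <- "Completely novel reaction"
  coded <- code_events(rep, toy_meddra_map())
  expect_identical(coded$reactions$soc[coded$reactions$pt == "Constipation"][1],
                   "Gastrointestinal disorders")
  expect_identical(coded$reactions$soc[1], "UNMAPPED")
  um <- attr(coded, "unmapped")
  expect_true("Completely novel reaction" %in% um$pt)
  # cases without reactions pass through unchanged
  expect_identical(nrow(coded$cases), nrow(rep$cases))
})

test_that("mapping files reject duplicate PT assignments", {
  d <- withr::local_tempdir()
  p <- file.path(d, "map.tsv")
  writeLines(c("PT\tSOC", "Nausea\tGastrointestinal disorders", "Nausea\tInvestigations"), p)
  expect_error(read_meddra_map(p), "Nausea")
})

test_that("onset assembly computes day differences and excludes bad intervals", {
  mk_bundle <- function(event_dt, start_dt) {
    b <- generate_quarter(synth_config(n_cases = 0))
    b$demo <- data.table::data.table(
      primaryid = "11", caseid = "1", fda_dt = "20230301", event_dt = event_dt,
      age = "40", age_cod = "YR", sex = "F", occp_cod = "MD", occr_country = "US")
    b$drug <- data.table::data.table(primaryid = "11", caseid = "1", drug_seq = "1",
                                     role_cod = "PS", drugname = "CHOLESTYRAMINE")
    b$reac <- data.table::data.table(primaryid = "11", caseid = "1", pt = "Nausea")
    b$ther <- data.table::data.table(primaryid = "11", caseid = "1",
                                     dsg_drug_seq = "1", start_dt = start_dt)
    b
  }
  ok <- assemble_reports(mk_bundle("20230104", "20230101"))
  expect_identical(ok$cases$onset_days, 3L)
  expect_identical(ok$cases$onset_status, "ok")
  neg <- assemble_reports(mk_bundle("20221230", "20230101"))
  expect_identical(neg$cases$onset_status, "negative")
  part <- assemble_reports(mk_bundle("20230104", "202301"))
  expect_identical(part$cases$onset_status, "partial")
  miss <- assemble_reports(mk_bundle("", "20230101"))
  expect_identical(miss$cases$onset_status, "missing")
})
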