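# The synthetic report generator and its ground-truth guarantees.

test_that("configuration validation names every offending field", {
  expect_s3_class(synthetic_config(n_reports = 10), "synthetic_config")
  err <- tryCatch(
    synthetic_config(n_reports = 0, duplicate_rate = 1.5,
                     tto = list(scale = -1, shape = 0.8,
                                fraction_with_dates = 0.1)),
    error = function(e) conditionMessage(e))
  expect_match(err, "n_reports")
  expect_match(err, "duplicate_rate")
  expect_match(err, "tto")
  expect_error(
    synthetic_config(planted_signals = data.frame(drug = "drug_001",
                                                  event = "evt_001", rr = -2)),
    class = "pv_invalid_config")
})

test_that("duplicates deduplicate back to exactly the generated case set", {
  cfg <- synthetic_config(n_reports = 100, duplicate_rate = 0.2, seed = 9)
  sim <- generate_reports(cfg)
  expect_equal(n_reports(sim$store), 120)  # 100 cases + 20 clone versions
  expect_equal(nrow(sim$manifest$duplicates), 20)

  dd <- deduplicate(sim$store)
  expect_equal(n_reports(dd), 100)
  expect_setequal(dd$reports$case_key, sim$manifest$case_keys)
  # the later version (larger key, incremented date) survives
  expect_true(all(sim$manifest$duplicates$report_key_v2 %in%
                    dd$reports$report_key))
})

test_that("generation is reproducible from the seed", {
  cfg <- synthetic_config(n_reports = 200, seed = 123)
  s1 <- generate_reports(cfg)
  s2 <- generate_reports(cfg)
  expect_identical(s1$store$reports, s2$store$reports)
  expect_identical(s1$store$events, s2$store$events)
  s3 <- generate_reports(synthetic_config(n_reports = 200, seed = 124))
  expect_false(identical(s1$store$events, s3$store$events))
})

test_that("planted relative risk surfaces as elevated disproportionality", {
  cfg <- synthetic_config(
    n_reports = 50000, n_events = 100,
    background_event_probs = rep(1 / 100, 100),
    planted_signals = data.frame(drug = "drug_001", event = "evt_050", rr = 5),
    duplicate_rate = 0, tto = list(scale = 27, shape = 0.8,
                                   fraction_with_dates = 0),
    seed = 77)
  sim <- generate_reports(cfg)
  parts <- partition_reports(deduplicate(sim$store), drug_query("drug_001"))
  tabs <- contingency_tables(parts$target, parts$background, level = "pt")
  sig <- disproportionality(tabs, seed = 1)
  planted <- sig[sig$event == "evt_050", ]
  expect_gt(planted$ror, 3.5)
  expect_lt(planted$ror, 7)
  expect_true(planted$positive_any)
})

test_that("demographic marginals land near their configured rates", {
  sim <- generate_reports(synthetic_config(n_reports = 20000, seed = 15))
  rep <- deduplicate(sim$store)$reports
  expect_equal(mean(is.na(rep$age_years)), 0.516, tolerance = 0.02)
  expect_equal(mean(is.na(rep$weight_kg)), 0.73, tolerance = 0.02)
  expect_equal(mean(rep$gender == "male", na.rm = TRUE) * (1 - 0.131),
               0.457, tolerance = 0.03)
  expect_equal(mean(rep$route == "oral", na.rm = TRUE), 0.895,
               tolerance = 0.01)
})

test_that("FAERS-dialect serialization round-trips the store", {
  cfg <- synthetic_config(n_reports = 100, duplicate_rate = 0.15, seed = 5)
  sim <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(sim$store, dir)

  # emitted DEMO row count equals the raw (pre-dedup) record count
  expect_equal(length(readLines(paths["demo"])) - 1, n_reports(sim$store))

  back <- parse_faers_quarter(paths["demo"], paths["drug"], paths["reac"],
                              indi_path = paths["indi"],
                              ther_path = paths["ther"])
  ord <- function(df) dplyr::arrange(as.data.frame(df), report_key)
  expect_equal(ord(back$reports), ord(sim$store$reports), tolerance = 1e-9)
  ev <- function(df) dplyr::arrange(as.data.frame(df), report_key, pt)
  expect_equal(ev(back$events), ev(sim$store$events))
  expect_equal(ev(back$indications), ev(sim$store$indications))
  dr <- function(df) {
    dplyr::arrange(as.data.frame(df[c("report_key", "name_normalized",
                                      "role", "start_date")]), report_key)
  }
  expect_equal(dr(back$drugs), dr(sim$store$drugs))
})

test_that("marginal reconstruction reproduces its count table exactly", {
  marg <- readr::read_tsv(fixture_path("faers_demo_marginals.tsv"),
                          show_col_types = FALSE)
  store <- reports_from_marginals(marg)
  expect_equal(n_reports(store), 2962)
  demo <- summarize_demographics(store, top_k = 5)
  expect_equal(demo$n[demo$variable == "gender" & demo$category == "male"],
               1354L)
  expect_equal(demo$n[demo$variable == "route" & demo$category == "oral"],
               2650L)
})
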