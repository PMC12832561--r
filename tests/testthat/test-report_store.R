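# Ingestion, selection, deduplication, noise exclusion, demographics.

make_quarter <- function(dir) {
  write_faers_tables(
    dir,
    demo = tibble::tibble(
      PRIMARYID = c("101", "102"), CASEID = c("c1", "c2"),
      FDA_DT = c("20130301", "201305"), EVENT_DT = c("20130118", NA),
      SEX = c("M", "F"), AGE = c("780", "154"), AGE_COD = c("MON", "YR"),
      WT = c("154", NA), WT_COD = c("LBS", NA),
      OCCP_COD = c("MD", "CN"), REPORTER_COUNTRY = c("US", "DE")
    ),
    drug = tibble::tibble(
      PRIMARYID = c("101", "101", "102", "999"),
      DRUG_SEQ = c("1", "2", "1", "1"),
      ROLE_COD = c("PS", "C", "PS", "PS"),
      DRUGNAME = c("DALIRESP", "BUDESONIDE/FORMOTEROL", "ROFLUMILAST", "ASPIRIN"),
      PROD_AI = c("ROFLUMILAST", "BUDESONIDE\\FORMOTEROL FUMARATE", "ROFLUMILAST", "ASPIRIN"),
      ROUTE = c("Oral", "Respiratory (inhalation)", "Topical", "Oral")
    ),
    reac = tibble::tibble(
      PRIMARYID = c("101", "101", "102"),
      PT = c("Diarrhoea", "Insomnia", "Headache")
    ),
    ther = tibble::tibble(
      PRIMARYID = c("101"), DSG_DRUG_SEQ = c("1"), START_DT = c("20130101")
    )
  )
}

test_that("FAERS quarter parsing joins tables and converts units", {
  paths <- make_quarter(withr::local_tempdir())
  store <- parse_faers_quarter(paths$demo, paths$drug, paths$reac,
                               ther_path = paths$ther)

  expect_equal(n_reports(store), 2)
  counts <- table(store$events$report_key)
  expect_equal(as.integer(counts[c("101", "102")]), c(2L, 1L))

  # AGE=780 MON -> 65 years; AGE=154 YR exceeds the plausibility bound
  expect_equal(store$reports$age_years[store$reports$report_key == "101"], 65)
  expect_true(is.na(store$reports$age_years[store$reports$report_key == "102"]))
  # WT=154 LBS -> 69.85 kg
  expect_equal(store$reports$weight_kg[store$reports$report_key == "101"],
               154 * 0.45359237, tolerance = 1e-10)

  # orphan DRUG row for report 999 dropped and logged
  expect_false("999" %in% store$drugs$report_key)
  expect_match(paste(store$log, collapse = "\n"), "without a DEMO parent")

  # partial receipt date retained at month precision
  expect_equal(store$reports$receipt_date[store$reports$report_key == "102"],
               "201305")
  # start date attached to the matching drug sequence only
  d101 <- store$drugs[store$drugs$report_key == "101", ]
  expect_equal(d101$start_date[d101$name_normalized == "daliresp"], "20130101")
  expect_true(is.na(d101$start_date[d101$name_normalized != "daliresp"]))
  # report route from the primary-suspect entry
  expect_equal(store$reports$route, c("oral", "topical"))
})

test_that("FAERS parser reports format errors precisely", {
  dir <- withr::local_tempdir()
  paths <- write_faers_tables(
    dir,
    demo = tibble::tibble(PRIMARYID = "1"),  # no CASEID
    drug = tibble::tibble(PRIMARYID = "1", DRUGNAME = "X"),
    reac = tibble::tibble(PRIMARYID = "1", PT = "nausea")
  )
  expect_error(parse_faers_quarter(paths$demo, paths$drug, paths$reac),
               "CASEID", class = "pv_format_error")

  paths2 <- write_faers_tables(
    file.path(dir, "empty"),
    demo = tibble::tibble(PRIMARYID = character(), CASEID = character()),
    drug = tibble::tibble(PRIMARYID = "1", DRUGNAME = "X"),
    reac = tibble::tibble(PRIMARYID = "1", PT = "nausea")
  )
  expect_error(parse_faers_quarter(paths2$demo, paths2$drug, paths2$reac),
               class = "pv_empty_store")
})

test_that("CVARD extract parsing normalizes roles and partial dates", {
  dir <- withr::local_tempdir()
  w <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_delim(df, path, delim = "$", na = "")
    path
  }
  rp <- w(tibble::tibble(
    REPORT_ID = c("r1", "r2"), DATRECEIVED = c("2013-05", "2014-07-01"),
    GENDER_ENG = c("Female", "Male"), AGE = c("68", NA),
    AGE_UNIT_ENG = c("Years", NA), WEIGHT = c("70", NA),
    WEIGHT_UNIT_ENG = c("Kilograms", NA),
    REPORTER_TYPE_ENG = c("Physician", "Consumer"),
    COUNTRY = c("CA", "CA"), EVENT_DATE = c(NA, NA)
  ), "reports.txt")
  dr <- w(tibble::tibble(
    REPORT_ID = c("r1", "r2"), DRUGNAME = c("DAXAS", "DAXAS"),
    DRUGINVOLV_ENG = c("Suspect", "Concomitant"),
    ROUTEADMIN_ENG = c("Oral", "Oral"), START_DATE = c("2013-01-01", NA),
    INDICATION_NAME_ENG = c("COPD", NA)
  ), "drugs.txt")
  re <- w(tibble::tibble(
    REPORT_ID = c("r1", "r1", "r2"),
    PT_NAME_ENG = c("Dyspnoea", "Cough", "Headache")
  ), "reactions.txt")

  store <- parse_cvard_extract(rp, dr, re)
  expect_equal(n_reports(store), 2)
  expect_equal(as.integer(table(store$events$report_key)[c("r1", "r2")]),
               c(2L, 1L))
  expect_equal(store$drugs$role, c("suspect", "concomitant"))
  expect_equal(store$reports$source_db, c("cvard", "cvard"))
  # partial receipt date: month precision, no fabricated day
  r1 <- store$reports[store$reports$report_key == "r1", ]
  expect_equal(r1$receipt_date, "201305")
  expect_equal(r1$age_years, 68)
})

test_that("drug selection honors names, roles, and set containment", {
  store <- tiny_store(list(c("nausea"), c("headache"), c("rash")))
  store$drugs$name_raw <- c("DALIRESP", "ROFLUMILAST", "ASPIRIN")
  store$drugs$name_normalized <- c("daliresp", "roflumilast", "aspirin")
  store$drugs$ai_normalized <- c("roflumilast", "roflumilast", "aspirin")
  store$drugs$role <- c("primary_suspect", "secondary_suspect", "primary_suspect")

  q <- drug_query("roflumilast", c("daliresp", "daxas", "zoryve"),
                  roles = "primary_suspect")
  sel <- select_drug_reports(store, q)
  expect_equal(sel$reports$report_key, "1")  # trade-name match, PS role

  # role filter excludes: same drug in concomitant-only filter
  q2 <- drug_query("roflumilast", roles = "concomitant")
  expect_equal(n_reports(select_drug_reports(store, q2)), 0)
  # secondary suspect not included under the PS filter
  expect_false("2" %in% sel$reports$report_key)

  # subset and role-filter monotonicity
  q_wide <- drug_query("roflumilast", c("daliresp"),
                       roles = c("primary_suspect", "secondary_suspect"))
  sel_wide <- select_drug_reports(store, q_wide)
  expect_true(all(sel$reports$report_key %in% sel_wide$reports$report_key))
  expect_true(all(sel_wide$reports$report_key %in% store$reports$report_key))
})

test_that("deduplication keeps the latest version with deterministic ties", {
  reports <- tibble::tibble(
    report_key = c("5", "9", "3", "12"),
    case_key = c("100", "100", "200", "200"),
    receipt_date = c("20130101", "20130101", "20130101", "20130301"),
    gender = NA_character_, age_years = NA_real_, weight_kg = NA_real_,
    route = NA_character_, reporter = NA_character_, country = NA_character_,
    event_date = NA_character_, source_db = "faers"
  )
  store <- report_store(reports)
  dd <- deduplicate(store)
  expect_equal(dd$reports$report_key, c("9", "12"))  # tie -> larger key; else later date
  expect_equal(dd$reports$case_key, c("100", "200"))

  # idempotence and non-increase
  dd2 <- deduplicate(dd)
  expect_equal(dd2$reports, dd$reports)
  expect_lte(n_reports(dd), n_reports(store))
})

test_that("numeric tie-break compares report keys as numbers, not strings", {
  reports <- tibble::tibble(
    report_key = c("9", "10"), case_key = c("c", "c"),
    receipt_date = "20200101",
    gender = NA_character_, age_years = NA_real_, weight_kg = NA_real_,
    route = NA_character_, reporter = NA_character_, country = NA_character_,
    event_date = NA_character_, source_db = "faers"
  )
  dd <- deduplicate(report_store(reports))
  expect_equal(dd$reports$report_key, "10")
})

test_that("noise-term exclusion strips terms and drops emptied reports", {
  store <- tiny_store(list(
    c("diarrhoea", "off-label use"),
    c("psoriasis"),
    c("nausea")
  ))
  out <- exclude_noise_terms(store)
  expect_equal(sort(out$events$pt), c("diarrhoea", "nausea"))
  expect_false("2" %in% out$reports$report_key)  # only-psoriasis report dropped
  # empty exclusion set is the identity
  out2 <- exclude_noise_terms(store, character())
  expect_equal(out2$events, store$events)
  expect_equal(n_reports(out2), n_reports(store))
})

test_that("demographic summary uses half-up percentages that close to 100", {
  store <- tiny_store(list(c("a"), c("b"), c("c")))
  store$reports$gender <- c("male", "female", NA)
  demo <- summarize_demographics(store)
  g <- demo[demo$variable == "gender", ]
  expect_equal(g$pct[g$category == "male"], 33.3)  # 1/3 -> 33.3 half-up
  expect_equal(sum(g$pct), 99.9, tolerance = 0.21)

  # every closed variable's percentages sum to 100 +/- 0.2
  sim <- generate_reports(synthetic_config(n_reports = 500, seed = 7))
  demo2 <- summarize_demographics(deduplicate(sim$store))
  for (v in c("gender", "age", "route", "weight", "reporter")) {
    expect_equal(sum(demo2$pct[demo2$variable == v]), 100, tolerance = 0.2)
  }
  empty <- report_store(store$reports[0, ])
  expect_error(summarize_demographics(empty), class = "pv_empty_store")
})

test_that("normalized store round-trips through TSV serialization", {
  sim <- generate_reports(synthetic_config(n_reports = 60, seed = 3,
                                           duplicate_rate = 0.2))
  dir <- withr::local_tempdir()
  write_store(sim$store, dir)
  back <- read_store(dir)
  expect_equal(as.data.frame(back$reports), as.data.frame(sim$store$reports))
  expect_equal(as.data.frame(back$events),
               as.data.frame(sim$store$events))
  expect_equal(as.data.frame(back$drugs),
               as.data.frame(sim$store$drugs[names(back$drugs)]))
})
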