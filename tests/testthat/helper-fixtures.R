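# Shared fixture builders. Everything is constructed in code at test time;
# the only files read are the plain-text tables shipped under extdata.

fixture_path <- function(name) {
  system.file("extdata", name, package = "pvsignal", mustWork = TRUE)
}

fixture_vocab <- function() {
  load_vocabulary(fixture_path("pt_soc_fixture.tsv"))
}

fixture_label_dicts <- function() {
  list(load_label_dictionary(fixture_path("label_fda.tsv"), "fda"),
       load_label_dictionary(fixture_path("label_canada.tsv"), "canada"))
}

# Write '$'-delimited FAERS-style tables from row lists and return the paths.
write_faers_tables <- function(dir, demo, drug = NULL, reac = NULL,
                               indi = NULL, ther = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (is.null(df)) return(NULL)
    path <- file.path(dir, name)
    readr::write_delim(df, path, delim = "$", na = "")
    path
  }
  list(demo = w(demo, "DEMO.txt"), drug = w(drug, "DRUG.txt"),
       reac = w(reac, "REAC.txt"), indi = w(indi, "INDI.txt"),
       ther = w(ther, "THER.txt"))
}

# Minimal hand-built store: n reports with given per-report event lists and
# one primary-suspect drug entry each.
tiny_store <- function(event_lists, drug = "drug_a",
                       keys = as.character(seq_along(event_lists)),
                       source_db = "faers") {
  reports <- tibble::tibble(
    report_key = keys, case_key = keys, receipt_date = "20200101",
    gender = NA_character_, age_years = NA_real_, weight_kg = NA_real_,
    route = NA_character_, reporter = NA_character_, country = NA_character_,
    event_date = NA_character_, source_db = source_db
  )
  drugs <- tibble::tibble(
    report_key = keys, name_raw = toupper(drug), name_normalized = drug,
    ai_normalized = drug, role = "primary_suspect",
    route_raw = NA_character_, start_date = NA_character_
  )
  events <- tibble::tibble(
    report_key = rep(keys, lengths(event_lists)),
    pt = unlist(event_lists, use.names = FALSE)
  )
  report_store(reports, drugs, events)
}
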