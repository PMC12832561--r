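# Reader for Canada Vigilance (CVARD) style extracts: '$'-delimited tables
# for reports, drug involvements, and reactions. CVARD publishes one row per
# report (no case versioning), English category labels rather than code
# letters, and ISO-style dates that may be truncated to year or month.

#' Parse a CVARD-style extract
#'
#' Reads the reports, drugs and reactions tables into a normalized
#' [report_store()]. Drug involvement "Suspect" maps to the `suspect` role
#' (CVARD does not distinguish primary from secondary suspects). Partial
#' dates such as `"2013-05"` are retained at their stated precision.
#' Indication terms, when present on drug rows, populate the indications
#' table.
#'
#' @param reports_path Path to the reports table (columns `REPORT_ID`,
#'   `DATRECEIVED`, `GENDER_ENG`, `AGE`, `AGE_UNIT_ENG`, `WEIGHT`,
#'   `WEIGHT_UNIT_ENG`, `REPORTER_TYPE_ENG`, `COUNTRY`, `EVENT_DATE`).
#' @param drugs_path Path to the drug table (columns `REPORT_ID`,
#'   `DRUGNAME`, `DRUGINVOLV_ENG`, `ROUTEADMIN_ENG`, `START_DATE`,
#'   `INDICATION_NAME_ENG`).
#' @param reactions_path Path to the reactions table (columns `REPORT_ID`,
#'   `PT_NAME_ENG`).
#' @return A `report_store` with `source_db = "cvard"`.
#' @export
parse_cvard_extract <- function(reports_path, drugs_path, reactions_path) {
  rep_raw <- resolve_columns(
    faers_read(reports_path),
    spec = list(
      REPORT_ID = "REPORT_ID", DATRECEIVED = "DATRECEIVED",
      GENDER_ENG = "GENDER_ENG", AGE = "AGE", AGE_UNIT_ENG = "AGE_UNIT_ENG",
      WEIGHT = "WEIGHT", WEIGHT_UNIT_ENG = "WEIGHT_UNIT_ENG",
      REPORTER_TYPE_ENG = "REPORTER_TYPE_ENG", COUNTRY = "COUNTRY",
      EVENT_DATE = "EVENT_DATE"
    ),
    file = reports_path, required = "REPORT_ID"
  )
  if (nrow(rep_raw) == 0) {
    stop_pv(sprintf("reports file '%s' holds no reports", reports_path),
            "pv_empty_store")
  }
  drug_raw <- resolve_columns(
    faers_read(drugs_path),
    spec = list(
      REPORT_ID = "REPORT_ID", DRUGNAME = "DRUGNAME",
      DRUGINVOLV_ENG = "DRUGINVOLV_ENG", ROUTEADMIN_ENG = "ROUTEADMIN_ENG",
      START_DATE = "START_DATE", INDICATION_NAME_ENG = "INDICATION_NAME_ENG"
    ),
    file = drugs_path, required = c("REPORT_ID", "DRUGNAME")
  )
  reac_raw <- resolve_columns(
    faers_read(reactions_path),
    spec = list(REPORT_ID = "REPORT_ID", PT_NAME_ENG = "PT_NAME_ENG"),
    file = reactions_path, required = c("REPORT_ID", "PT_NAME_ENG")
  )

  keys <- unique(rep_raw$REPORT_ID)
  log <- character()
  for (nm in c("drug", "reaction")) {
    df <- if (nm == "drug") drug_raw else reac_raw
    n <- sum(!(df$REPORT_ID %in% keys))
    if (n > 0) {
      log <- c(log, sprintf("parse_cvard_extract: dropped %d %s rows without a report parent", n, nm))
    }
  }
  drug_raw <- drug_raw[drug_raw$REPORT_ID %in% keys, ]
  reac_raw <- reac_raw[reac_raw$REPORT_ID %in% keys, ]

  drugs <- drug_raw |>
    dplyr::transmute(
      report_key = .data$REPORT_ID,
      name_raw = .data$DRUGNAME,
      name_normalized = normalize_name(.data$DRUGNAME),
      ai_normalized = NA_character_,
      role = normalize_role(.data$DRUGINVOLV_ENG),
      route_raw = .data$ROUTEADMIN_ENG,
      start_date = clean_date_string(.data$START_DATE)
    )

  route_tbl <- drugs |>
    dplyr::mutate(route_norm = normalize_route(.data$route_raw)) |>
    dplyr::filter(!is.na(.data$route_norm)) |>
    dplyr::arrange(.data$report_key, .data$role != "suspect") |>
    dplyr::distinct(.data$report_key, .keep_all = TRUE) |>
    dplyr::select("report_key", "route_norm")

  reports <- rep_raw |>
    dplyr::transmute(
      report_key = .data$REPORT_ID,
      case_key = .data$REPORT_ID,  # CVARD has no case versioning
      receipt_date = clean_date_string(.data$DATRECEIVED),
      gender = normalize_gender(.data$GENDER_ENG),
      age_years = convert_age_years(.data$AGE, .data$AGE_UNIT_ENG),
      weight_kg = convert_weight_kg(.data$WEIGHT, .data$WEIGHT_UNIT_ENG),
      reporter = normalize_reporter(.data$REPORTER_TYPE_ENG),
      country = .data$COUNTRY,
      event_date = clean_date_string(.data$EVENT_DATE),
      source_db = "cvard"
    ) |>
    dplyr::left_join(route_tbl, by = "report_key") |>
    dplyr::rename(route = "route_norm") |>
    dplyr::select("report_key", "case_key", "receipt_date", "gender",
                  "age_years", "weight_kg", "route", "reporter", "country",
                  "event_date", "source_db")

  events <- reac_raw |>
    dplyr::transmute(report_key = .data$REPORT_ID,
                     pt = normalize_name(.data$PT_NAME_ENG)) |>
    dplyr::filter(!is.na(.data$pt) & nzchar(.data$pt)) |>
    dplyr::distinct()

  indications <- drug_raw |>
    dplyr::transmute(report_key = .data$REPORT_ID,
                     pt = normalize_name(.data$INDICATION_NAME_ENG)) |>
    dplyr::filter(!is.na(.data$pt) & nzchar(.data$pt)) |>
    dplyr::distinct()

  report_store(reports, drugs, events, indications, log = log)
}

# --- serialization of the normalized store ---------------------------------

#' Write a normalized store as tab-separated tables
#'
#' Emits `reports.tsv`, `drugs.tsv`, `events.tsv` and `indications.tsv` in
#' the documented normalized schema. [read_store()] is its inverse.
#'
#' @param store A `report_store`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_store <- function(store, dir) {
  stopifnot(inherits(store, "report_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(store$reports, file.path(dir, "reports.tsv"), na = "")
  drugs <- store$drugs[, setdiff(names(store$drugs), "drug_seq")]
  readr::write_tsv(drugs, file.path(dir, "drugs.tsv"), na = "")
  readr::write_tsv(store$events, file.path(dir, "events.tsv"), na = "")
  readr::write_tsv(store$indications, file.path(dir, "indications.tsv"), na = "")
  invisible(dir)
}

#' Read a normalized store written by [write_store()]
#'
#' @param dir Directory holding the four TSV tables.
#' @return A `report_store`.
#' @export
read_store <- function(dir) {
  read1 <- function(f, date_cols = character(), num_cols = character()) {
    df <- readr::read_tsv(file.path(dir, f), na = "",
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE)
    for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    df
  }
  report_store(
    reports = read1("reports.tsv", num_cols = c("age_years", "weight_kg")),
    drugs = read1("drugs.tsv"),
    events = read1("events.tsv"),
    indications = read1("indications.tsv")
  )
}
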