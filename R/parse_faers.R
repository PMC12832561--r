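# Reader for FAERS-style quarterly ASCII tables: '$'-delimited text with a
# header row, one file per table (DEMO, DRUG, REAC, INDI, THER). The modern
# (post-2014Q3) column names are canonical; a small alias map accepts legacy
# spellings so a study window spanning the schema change parses uniformly.

faers_read <- function(path) {
  readr::read_delim(
    path, delim = "$", quote = "", trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE,
    name_repair = "minimal"
  )
}

# Rename columns to canonical names using an alias map; error on missing
# required columns, naming the file and the column.
resolve_columns <- function(df, spec, file, required) {
  names(df) <- toupper(names(df))
  for (canon in names(spec)) {
    hits <- intersect(spec[[canon]], names(df))
    if (length(hits) > 0) {
      names(df)[names(df) == hits[1]] <- canon
    } else if (canon %in% required) {
      stop_pv(sprintf("file '%s' lacks required column %s", file, canon),
              "pv_format_error")
    } else {
      df[[canon]] <- NA_character_
    }
  }
  df[names(spec)]
}

#' Parse one quarter of FAERS-style tables
#'
#' Reads the '$'-delimited DEMO/DRUG/REAC/INDI/THER tables and joins them into
#' a normalized [report_store()]. The DEMO table defines the report universe;
#' rows in child tables without a DEMO parent are dropped (with a logged
#' count). Ages are converted to years from their unit codes (DEC, YR, MON,
#' WK, DY, HR), weights to kilograms (LBS x 0.45359237), free-text routes to
#' oral/topical/other; unparseable values become missing, as do ages above
#' 120 years. A report's route is taken from its primary-suspect drug entry
#' when available.
#'
#' @param demo_path,drug_path,reac_path Paths to the DEMO, DRUG and REAC
#'   tables (required).
#' @param indi_path,ther_path Optional paths to the INDI (indications) and
#'   THER (therapy dates) tables.
#' @return A `report_store` with `source_db = "faers"`.
#' @export
parse_faers_quarter <- function(demo_path, drug_path, reac_path,
                                indi_path = NULL, ther_path = NULL) {
  demo <- resolve_columns(
    faers_read(demo_path),
    spec = list(
      PRIMARYID = c("PRIMARYID", "ISR"), CASEID = c("CASEID", "CASE"),
      FDA_DT = "FDA_DT", EVENT_DT = "EVENT_DT",
      SEX = c("SEX", "GNDR_COD"), AGE = "AGE", AGE_COD = "AGE_COD",
      WT = "WT", WT_COD = "WT_COD", OCCP_COD = "OCCP_COD",
      REPORTER_COUNTRY = c("REPORTER_COUNTRY", "OCCR_COUNTRY")
    ),
    file = demo_path, required = c("PRIMARYID", "CASEID")
  )
  if (nrow(demo) == 0) {
    stop_pv(sprintf("DEMO file '%s' holds no reports", demo_path),
            "pv_empty_store")
  }

  drug <- resolve_columns(
    faers_read(drug_path),
    spec = list(
      PRIMARYID = c("PRIMARYID", "ISR"),
      DRUG_SEQ = c("DRUG_SEQ", "DSG_DRUG_SEQ"),
      ROLE_COD = "ROLE_COD", DRUGNAME = "DRUGNAME", PROD_AI = "PROD_AI",
      ROUTE = "ROUTE"
    ),
    file = drug_path, required = c("PRIMARYID", "DRUGNAME")
  )
  reac <- resolve_columns(
    faers_read(reac_path),
    spec = list(PRIMARYID = c("PRIMARYID", "ISR"), PT = "PT"),
    file = reac_path, required = c("PRIMARYID", "PT")
  )
  indi <- if (!is.null(indi_path)) {
    resolve_columns(
      faers_read(indi_path),
      spec = list(PRIMARYID = c("PRIMARYID", "ISR"),
                  INDI_DRUG_SEQ = "INDI_DRUG_SEQ", INDI_PT = "INDI_PT"),
      file = indi_path, required = c("PRIMARYID", "INDI_PT")
    )
  } else {
    tibble(PRIMARYID = character(), INDI_DRUG_SEQ = character(),
           INDI_PT = character())
  }
  ther <- if (!is.null(ther_path)) {
    resolve_columns(
      faers_read(ther_path),
      spec = list(PRIMARYID = c("PRIMARYID", "ISR"),
                  DSG_DRUG_SEQ = c("DSG_DRUG_SEQ", "DRUG_SEQ"),
                  START_DT = "START_DT"),
      file = ther_path, required = c("PRIMARYID", "START_DT")
    )
  } else {
    tibble(PRIMARYID = character(), DSG_DRUG_SEQ = character(),
           START_DT = character())
  }

  keys <- unique(demo$PRIMARYID)
  log <- character()
  orphan <- function(df, nm) {
    n <- sum(!(df$PRIMARYID %in% keys))
    if (n > 0) {
      log <<- c(log, sprintf("parse_faers_quarter: dropped %d %s rows without a DEMO parent", n, nm))
    }
    df[df$PRIMARYID %in% keys, ]
  }
  drug <- orphan(drug, "DRUG")
  reac <- orphan(reac, "REAC")
  indi <- orphan(indi, "INDI")
  ther <- orphan(ther, "THER")

  # therapy start dates attach to the matching drug sequence
  ther_first <- ther |>
    dplyr::mutate(start_clean = clean_date_string(.data$START_DT)) |>
    dplyr::filter(!is.na(.data$start_clean)) |>
    dplyr::distinct(.data$PRIMARYID, .data$DSG_DRUG_SEQ, .keep_all = TRUE)

  drugs <- drug |>
    dplyr::left_join(ther_first,
                     by = c("PRIMARYID", "DRUG_SEQ" = "DSG_DRUG_SEQ")) |>
    dplyr::transmute(
      report_key = .data$PRIMARYID,
      name_raw = .data$DRUGNAME,
      name_normalized = normalize_name(.data$DRUGNAME),
      ai_normalized = normalize_name(.data$PROD_AI),
      role = normalize_role(.data$ROLE_COD),
      route_raw = .data$ROUTE,
      start_date = .data$start_clean,
      drug_seq = .data$DRUG_SEQ
    )
  drugs$ai_normalized[is.na(drug$PROD_AI)] <- NA_character_

  # report-level route: primary-suspect entry first, then any entry
  route_tbl <- drugs |>
    dplyr::mutate(route_norm = normalize_route(.data$route_raw)) |>
    dplyr::filter(!is.na(.data$route_norm)) |>
    dplyr::arrange(.data$report_key,
                   .data$role != "primary_suspect") |>
    dplyr::distinct(.data$report_key, .keep_all = TRUE) |>
    dplyr::select("report_key", "route_norm")

  reports <- demo |>
    dplyr::transmute(
      report_key = .data$PRIMARYID,
      case_key = .data$CASEID,
      receipt_date = clean_date_string(.data$FDA_DT),
      gender = normalize_gender(.data$SEX),
      age_years = convert_age_years(.data$AGE, .data$AGE_COD),
      weight_kg = convert_weight_kg(.data$WT, .data$WT_COD),
      reporter = normalize_reporter(.data$OCCP_COD),
      country = .data$REPORTER_COUNTRY,
      event_date = clean_date_string(.data$EVENT_DT),
      source_db = "faers"
    ) |>
    dplyr::left_join(route_tbl, by = "report_key") |>
    dplyr::rename(route = "route_norm") |>
    dplyr::select("report_key", "case_key", "receipt_date", "gender",
                  "age_years", "weight_kg", "route", "reporter", "country",
                  "event_date", "source_db")

  events <- reac |>
    dplyr::transmute(report_key = .data$PRIMARYID,
                     pt = normalize_name(.data$PT)) |>
    dplyr::filter(!is.na(.data$pt) & nzchar(.data$pt)) |>
    dplyr::distinct()

  indications <- indi |>
    dplyr::transmute(report_key = .data$PRIMARYID,
                     pt = normalize_name(.data$INDI_PT)) |>
    dplyr::filter(!is.na(.data$pt) & nzchar(.data$pt)) |>
    dplyr::distinct()

  report_store(reports, drugs, events, indications, log = log)
}
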