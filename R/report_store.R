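# Normalized relational model for spontaneous adverse-event reports.
# A report_store holds four tibbles keyed by report_key:
#   reports     one row per report version (pre-dedup) or case (post-dedup)
#   drugs       one row per drug entry on a report
#   events      one row per (report, preferred term), already de-duplicated
#   indications one row per (report, indication preferred term)
# All downstream modules (contingency, signals, TTO, subgroups) consume only
# this form, whichever source dialect the data came from.

#' Construct a report store
#'
#' Assembles the normalized relational form used by every downstream stage.
#' Most users get a store from [parse_faers_quarter()], [parse_cvard_extract()]
#' or [generate_reports()] rather than calling this directly.
#'
#' @param reports Tibble with columns `report_key`, `case_key`,
#'   `receipt_date`, `gender`, `age_years`, `weight_kg`, `route`, `reporter`,
#'   `country`, `event_date`, `source_db`. Dates are digit strings
#'   (`"2013"`, `"201305"`, `"20130518"`) or `NA`.
#' @param drugs Tibble with columns `report_key`, `name_raw`,
#'   `name_normalized`, `ai_normalized`, `role`, `route_raw`, `start_date`.
#' @param events Tibble with columns `report_key`, `pt` (normalized
#'   preferred-term strings). Duplicate (report, PT) rows are collapsed:
#'   the counting unit throughout the package is the report, not the mention.
#' @param indications Tibble with columns `report_key`, `pt`.
#' @param log Character vector of processing messages carried along.
#' @return An object of class `report_store`.
#' @export
report_store <- function(reports,
                         drugs = empty_drugs(),
                         events = empty_events(),
                         indications = empty_events(),
                         log = character()) {
  reports <- as_tibble(reports)
  drugs <- as_tibble(drugs)
  events <- as_tibble(events)
  indications <- as_tibble(indications)

  if (anyDuplicated(reports$report_key) > 0) {
    stop_pv("duplicate report_key values in a report store", "pv_invalid_store")
  }
  if (any(reports$age_years < 0, na.rm = TRUE)) {
    stop_pv("age_years must be non-negative when present", "pv_invalid_store")
  }
  if (any(reports$weight_kg <= 0, na.rm = TRUE)) {
    stop_pv("weight_kg must be positive when present", "pv_invalid_store")
  }
  events <- dplyr::distinct(events, .data$report_key, .data$pt)

  structure(
    list(reports = reports, drugs = drugs, events = events,
         indications = indications, log = log),
    class = "report_store"
  )
}

empty_drugs <- function() {
  tibble(report_key = character(), name_raw = character(),
         name_normalized = character(), ai_normalized = character(),
         role = character(), route_raw = character(), start_date = character())
}

empty_events <- function() {
  tibble(report_key = character(), pt = character())
}

#' @export
print.report_store <- function(x, ...) {
  cat("<report_store> ", nrow(x$reports), " reports (",
      paste(unique(x$reports$source_db), collapse = "+"), "), ",
      nrow(x$drugs), " drug entries, ",
      nrow(x$events), " report-event pairs\n", sep = "")
  invisible(x)
}

#' Number of reports in a store
#' @param store A `report_store`.
#' @return Integer count.
#' @export
n_reports <- function(store) nrow(store$reports)

# Keep only the given report keys, consistently across all four tables.
filter_store <- function(store, keys, log_line = NULL) {
  keys <- unique(keys)
  report_store(
    reports = dplyr::filter(store$reports, .data$report_key %in% keys),
    drugs = dplyr::filter(store$drugs, .data$report_key %in% keys),
    events = dplyr::filter(store$events, .data$report_key %in% keys),
    indications = dplyr::filter(store$indications, .data$report_key %in% keys),
    log = c(store$log, log_line)
  )
}

append_log <- function(store, ...) {
  store$log <- c(store$log, sprintf(...))
  store
}

# --- drug query -------------------------------------------------------------

#' Define a drug query
#'
#' Names are matched case-insensitively as substrings of both the verbatim
#' product name and the active-ingredient field, so combination products
#' containing a queried ingredient are caught.
#'
#' @param generic_names,trade_names Character vectors of names; their union
#'   must be nonempty.
#' @param roles Drug roles accepted, a subset of
#'   `c("primary_suspect", "secondary_suspect", "concomitant", "interacting",
#'   "suspect")`.
#' @return A `drug_query` object.
#' @export
#' @examples
#' drug_query("roflumilast", c("daliresp", "daxas", "zoryve"))
drug_query <- function(generic_names, trade_names = character(),
                       roles = "primary_suspect") {
  names_all <- normalize_name(c(generic_names, trade_names))
  names_all <- names_all[nzchar(names_all)]
  if (length(names_all) == 0) {
    stop_pv("drug query needs at least one name", "pv_invalid_query")
  }
  valid_roles <- c("primary_suspect", "secondary_suspect", "concomitant",
                   "interacting", "suspect")
  bad <- setdiff(roles, valid_roles)
  if (length(bad) > 0) {
    stop_pv(paste0("unknown drug roles: ", paste(bad, collapse = ", ")),
            "pv_invalid_query")
  }
  structure(list(names = unique(names_all), roles = roles),
            class = "drug_query")
}

# Logical vector over the rows of a drugs tibble: does the entry's name or
# active ingredient contain any query name (ignoring the role filter)?
match_drug_names <- function(drugs, names) {
  hit <- rep(FALSE, nrow(drugs))
  for (nm in names) {
    hit <- hit |
      stringr::str_detect(drugs$name_normalized, stringr::fixed(nm)) |
      (!is.na(drugs$ai_normalized) &
         stringr::str_detect(drugs$ai_normalized, stringr::fixed(nm)))
  }
  hit & !is.na(drugs$name_normalized)
}

match_drug_entries <- function(drugs, query) {
  match_drug_names(drugs, query$names) & drugs$role %in% query$roles
}

#' Select reports mentioning a query drug in an accepted role
#'
#' @param store A `report_store`.
#' @param query A [drug_query()].
#' @return A `report_store` restricted to reports with at least one matching
#'   drug entry; possibly empty.
#' @export
select_drug_reports <- function(store, query) {
  stopifnot(inherits(store, "report_store"), inherits(query, "drug_query"))
  keys <- unique(store$drugs$report_key[match_drug_entries(store$drugs, query)])
  filter_store(store, keys,
               sprintf("select_drug_reports: %d of %d reports match",
                       length(keys), n_reports(store)))
}

# --- deduplication ----------------------------------------------------------

#' Deduplicate case versions
#'
#' Spontaneous-report databases carry every follow-up version of a case.
#' Per case identifier this keeps the version with the latest receipt date
#' (partial dates compare in zero-padded numeric form); among ties, the
#' numerically largest report key wins. The operation is idempotent and the
#' output is sorted by case key.
#'
#' @param store A `report_store` from a single source database.
#' @return A deduplicated `report_store`.
#' @export
deduplicate <- function(store) {
  stopifnot(inherits(store, "report_store"))
  if (length(unique(store$reports$source_db)) > 1) {
    stop_pv("deduplicate expects reports from a single source database",
            "pv_mixed_sources")
  }
  before <- n_reports(store)
  keep <- store$reports |>
    dplyr::mutate(
      .date_ord = dplyr::coalesce(date_num(.data$receipt_date), -1),
      .key_ord = dplyr::coalesce(suppressWarnings(as.numeric(.data$report_key)), -1)
    ) |>
    dplyr::arrange(.data$case_key, dplyr::desc(.data$.date_ord),
                   dplyr::desc(.data$.key_ord), dplyr::desc(.data$report_key)) |>
    dplyr::distinct(.data$case_key, .keep_all = TRUE)

  out <- filter_store(store, keep$report_key,
                      sprintf("deduplicate: %d versions -> %d cases",
                              before, nrow(keep)))
  out$reports <- dplyr::arrange(out$reports, .data$case_key)
  out
}

# --- event-term exclusion ---------------------------------------------------

#' Default event-term exclusion list
#'
#' Indication terms commonly co-recorded as reactions (the treated disease
#' itself) and administration/noise terms unrelated to drug therapy. Used by
#' [exclude_noise_terms()].
#'
#' @return Character vector of normalized preferred terms.
#' @export
default_exclusion_terms <- function() {
  c("chronic obstructive pulmonary disease", "bronchitis chronic", "psoriasis",
    "off-label use", "off label use", "intentional product misuse",
    "medication error", "product use in unapproved indication",
    "drug exposure during pregnancy")
}

#' Remove noise terms from event lists
#'
#' Drops matching preferred terms (case-insensitive exact match after
#' normalization) from every report's event list; reports left with no events
#' are dropped entirely.
#'
#' @param store A `report_store`.
#' @param exclusion_terms Character vector of preferred terms; defaults to
#'   [default_exclusion_terms()].
#' @return A filtered `report_store`.
#' @export
exclude_noise_terms <- function(store, exclusion_terms = default_exclusion_terms()) {
  stopifnot(inherits(store, "report_store"))
  terms <- normalize_name(exclusion_terms)
  hit <- normalize_name(store$events$pt) %in% terms
  n_removed <- sum(hit)
  store$events <- store$events[!hit, ]
  keep <- unique(store$events$report_key)
  dropped <- setdiff(store$reports$report_key, keep)
  filter_store(store, keep,
               sprintf("exclude_noise_terms: removed %d event rows, dropped %d empty reports",
                       n_removed, length(dropped)))
}

# --- demographics -----------------------------------------------------------

age_band <- function(age) {
  dplyr::case_when(
    is.na(age) ~ "missing",
    age < 18 ~ "<18",
    age < 65 ~ "18-64",
    TRUE ~ ">=65"
  )
}

weight_band <- function(wt) {
  dplyr::case_when(
    is.na(wt) ~ "missing",
    wt < 50 ~ "<50 kg",
    wt <= 100 ~ "50-100 kg",
    TRUE ~ ">100 kg"
  )
}

#' Summarize report demographics
#'
#' Counts and percentages (of the total report count, one decimal,
#' half-up rounding) for gender, age band, route, weight band, reporter
#' type, top indications, top countries, and top reporting years —
#' the standard "Table 1" of a pharmacovigilance study.
#'
#' @param store A deduplicated `report_store`.
#' @param top_k How many categories to keep for indications, countries and
#'   years.
#' @return A tibble with columns `variable`, `category`, `n`, `pct`.
#' @export
summarize_demographics <- function(store, top_k = 5) {
  stopifnot(inherits(store, "report_store"))
  rep <- store$reports
  if (nrow(rep) == 0) {
    stop_pv("cannot summarize an empty report store", "pv_empty_store")
  }
  total <- nrow(rep)

  count_var <- function(values, variable, levels = NULL, top = NULL) {
    values <- dplyr::coalesce(as.character(values), "missing")
    tab <- tibble(category = values) |>
      dplyr::count(.data$category, name = "n")
    if (!is.null(levels)) {
      tab <- tibble(category = levels) |>
        dplyr::left_join(tab, by = "category") |>
        dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
    }
    if (!is.null(top)) {
      tab <- tab |>
        dplyr::arrange(dplyr::desc(.data$n), .data$category) |>
        head(top)
    }
    tab |>
      dplyr::mutate(variable = variable,
                    pct = round_half_up(100 * .data$n / total, 1)) |>
      dplyr::select("variable", "category", "n", "pct")
  }

  # indications: a report counts once per distinct indication PT; reports
  # without any indication fall in a "missing" row
  ind <- dplyr::distinct(store$indications, .data$report_key, .data$pt)
  ind_vals <- c(ind$pt,
                rep("missing", total - length(unique(ind$report_key))))

  years <- date_year(rep$receipt_date)

  dplyr::bind_rows(
    count_var(rep$gender, "gender", levels = c("male", "female", "missing")),
    count_var(age_band(rep$age_years), "age",
              levels = c("<18", "18-64", ">=65", "missing")),
    count_var(rep$route, "route", levels = c("oral", "topical", "other", "missing")),
    count_var(weight_band(rep$weight_kg), "weight",
              levels = c("<50 kg", "50-100 kg", ">100 kg", "missing")),
    count_var(rep$reporter, "reporter",
              levels = c("healthcare_professional", "consumer", "other", "missing")),
    count_var(ind_vals, "indication", top = top_k),
    count_var(rep$country, "country", top = top_k),
    count_var(years, "year", top = top_k)
  )
}
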