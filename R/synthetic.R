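# Synthetic spontaneous-report generator with known ground truth. Emulates
# the features of a FAERS-style extract that the pipeline must survive:
# case-versioned duplicate reports, heavy demographic missingness, a
# drug-event multinomial background with planted relative-risk signals,
# route/gender/age strata, Weibull-distributed onset dates for a minority of
# reports, and indication terms contaminating event lists.

#' Configuration for the synthetic report generator
#'
#' Defaults describe a mid-sized extract whose demographic marginals mirror
#' a typical oral-respiratory-drug safety profile (heavy age and weight
#' missingness, predominantly oral route), whose event lists average 2.9
#' distinct terms per report, and whose onset times follow an early-failure
#' Weibull regime (shape 0.8, scale 27 days) for the roughly one-sixth of
#' reports carrying complete dates.
#'
#' @param n_reports Number of cases before duplication.
#' @param n_drugs,n_events Vocabulary sizes; drug `i` is named
#'   `drug_<i>`, event `j` `evt_<j>`.
#' @param background_event_probs Probability vector of length `n_events`
#'   (normalized if needed); default a mild power law.
#' @param drug_probs Probability vector of length `n_drugs`; default a mild
#'   power law.
#' @param planted_signals Tibble or data frame with columns `drug`, `event`,
#'   `rr` (relative risk > 0) naming planted drug-event associations.
#' @param events_per_report List `(mean, min)`: truncated-Poisson event
#'   count per report.
#' @param demographics Named list of marginal probability vectors for
#'   `gender`, `age_band`, `route`, `weight_band`, `reporter`; a `missing`
#'   element in each gives the missing fraction.
#' @param duplicate_rate Fraction of cases emitted as two case versions.
#' @param tto List `(scale, shape, fraction_with_dates)` for onset-time
#'   generation.
#' @param indication List `(terms, assign_rate, contaminate_rate)`:
#'   indication preferred terms, the fraction of reports carrying one, and
#'   the fraction whose event list is contaminated by it.
#' @param years Calendar years receipt dates are drawn from.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports = 50000,
                             n_drugs = 25,
                             n_events = 200,
                             background_event_probs = NULL,
                             drug_probs = NULL,
                             planted_signals = NULL,
                             events_per_report = list(mean = 2.9, min = 1),
                             demographics = default_demographics(),
                             duplicate_rate = 0.1,
                             tto = list(scale = 27, shape = 0.8,
                                        fraction_with_dates = 0.167),
                             indication = list(
                               terms = c("chronic obstructive pulmonary disease",
                                         "psoriasis"),
                               assign_rate = 0.5, contaminate_rate = 0.03),
                             years = 2011:2024,
                             seed = 1) {
  if (is.null(background_event_probs)) {
    background_event_probs <- (seq_len(n_events))^(-0.8)
  }
  if (is.null(drug_probs)) {
    drug_probs <- (seq_len(n_drugs))^(-0.5)
  }
  if (is.null(planted_signals)) {
    planted_signals <- tibble(drug = character(), event = character(),
                              rr = numeric())
  }
  planted_signals <- as_tibble(planted_signals)

  cfg <- list(
    n_reports = n_reports, n_drugs = n_drugs, n_events = n_events,
    background_event_probs = background_event_probs / sum(background_event_probs),
    drug_probs = drug_probs / sum(drug_probs),
    planted_signals = planted_signals,
    events_per_report = events_per_report,
    demographics = demographics,
    duplicate_rate = duplicate_rate,
    tto = tto, indication = indication, years = years, seed = seed
  )
  bad <- character()
  if (!is.numeric(n_reports) || n_reports < 1) bad <- c(bad, "n_reports")
  if (n_drugs < 1) bad <- c(bad, "n_drugs")
  if (n_events < 1) bad <- c(bad, "n_events")
  if (length(cfg$background_event_probs) != n_events ||
      any(cfg$background_event_probs < 0)) {
    bad <- c(bad, "background_event_probs")
  }
  if (length(cfg$drug_probs) != n_drugs || any(cfg$drug_probs < 0)) {
    bad <- c(bad, "drug_probs")
  }
  if (nrow(planted_signals) > 0 &&
      (!all(c("drug", "event", "rr") %in% names(planted_signals)) ||
         any(planted_signals$rr <= 0))) {
    bad <- c(bad, "planted_signals")
  }
  if (events_per_report$mean <= 0 || events_per_report$min < 1) {
    bad <- c(bad, "events_per_report")
  }
  if (duplicate_rate < 0 || duplicate_rate > 1) bad <- c(bad, "duplicate_rate")
  if (tto$shape <= 0 || tto$scale <= 0 ||
      tto$fraction_with_dates < 0 || tto$fraction_with_dates > 1) {
    bad <- c(bad, "tto")
  }
  for (nm in names(demographics)) {
    pr <- demographics[[nm]]
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-6) bad <- c(bad, paste0("demographics$", nm))
  }
  if (length(bad) > 0) {
    stop_pv(paste0("invalid synthetic_config field(s): ",
                   paste(unique(bad), collapse = ", ")),
            "pv_invalid_config")
  }
  structure(cfg, class = "synthetic_config")
}

#' Default demographic marginals for the generator
#'
#' Gender near-balanced with a modest missing share; age missing for about
#' half the reports with the known band mostly 65+; route overwhelmingly
#' oral with a topical minority; weight missing for nearly three quarters.
#'
#' @return Named list of normalized probability vectors.
#' @export
default_demographics <- function() {
  list(
    gender = c(male = 0.457, female = 0.412, missing = 0.131),
    age_band = c("<18" = 0.002, "18-64" = 0.133, ">=65" = 0.349,
                 missing = 0.516),
    route = c(oral = 0.895, topical = 0.077, other = 0.028),
    weight_band = c("<50 kg" = 0.030, "50-100 kg" = 0.214, ">100 kg" = 0.026,
                    missing = 0.730),
    reporter = c(healthcare_professional = 0.302, consumer = 0.359,
                 other = 0.232, missing = 0.107)
  )
}

sample_marginal <- function(n, probs) {
  out <- sample(names(probs), n, replace = TRUE, prob = probs)
  out[out == "missing"] <- NA_character_
  out
}

rtrunc_pois <- function(n, mean, min) {
  lo <- stats::ppois(min - 1, mean)
  stats::qpois(lo + runif(n) * (1 - lo), mean)
}

#' Generate a synthetic report store with ground truth
#'
#' Draws reports independently per the configuration: a multinomial drug
#' assignment, event lists from the background probabilities (multiplied by
#' the planted relative risk for planted pairs, then renormalized, for
#' reports of the planted drug), demographics from the marginals with
#' missingness, onset dates with a Weibull event-minus-start interval
#' (rounded up to at least one day) for the configured fraction, and
#' duplicate case versions cloned with an incremented receipt date and a new
#' report key.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_reports`: `store` (the raw
#'   `report_store`, duplicates included) and `manifest` (planted pairs,
#'   injected duplicates, and the pre-duplication case-key set).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed %% .Machine$integer.max)
  n <- config$n_reports
  drug_names <- sprintf("drug_%03d", seq_len(config$n_drugs))
  event_names <- sprintf("evt_%03d", seq_len(config$n_events))

  report_key <- as.character(10000000 + seq_len(n))
  case_key <- as.character(5000000 + seq_len(n))

  drug_idx <- sample.int(config$n_drugs, n, replace = TRUE,
                         prob = config$drug_probs)

  # per-report distinct event lists, with planted relative risks applied to
  # the affected drug's probability vector before renormalization
  k <- rtrunc_pois(n, config$events_per_report$mean,
                   config$events_per_report$min)
  rep_id <- rep(seq_len(n), k)
  rep_drug <- drug_idx[rep_id]
  ev_idx <- integer(length(rep_id))
  planted_drugs <- unique(config$planted_signals$drug)
  plain <- !(drug_names[rep_drug] %in% planted_drugs)
  ev_idx[plain] <- sample.int(config$n_events, sum(plain), replace = TRUE,
                              prob = config$background_event_probs)
  for (dn in planted_drugs) {
    probs <- config$background_event_probs
    rows <- config$planted_signals[config$planted_signals$drug == dn, ]
    probs[match(rows$event, event_names)] <-
      probs[match(rows$event, event_names)] * rows$rr
    probs <- probs / sum(probs)
    sel <- drug_names[rep_drug] == dn
    ev_idx[sel] <- sample.int(config$n_events, sum(sel), replace = TRUE,
                              prob = probs)
  }
  events <- tibble(report_key = report_key[rep_id],
                   pt = event_names[ev_idx]) |>
    dplyr::distinct()

  # indications, occasionally leaking into the event list
  ind_terms <- config$indication$terms
  has_ind <- runif(n) < config$indication$assign_rate & length(ind_terms) > 0
  ind_term <- if (length(ind_terms) > 0) {
    sample(ind_terms, n, replace = TRUE)
  } else {
    rep(NA_character_, n)
  }
  indications <- tibble(report_key = report_key[has_ind],
                        pt = ind_term[has_ind])
  contaminate <- has_ind & runif(n) < config$indication$contaminate_rate /
    max(config$indication$assign_rate, 1e-9)
  if (any(contaminate)) {
    events <- dplyr::bind_rows(
      events,
      tibble(report_key = report_key[contaminate], pt = ind_term[contaminate])
    ) |> dplyr::distinct()
  }

  # demographics
  dm <- config$demographics
  gender <- sample_marginal(n, dm$gender)
  band <- sample_marginal(n, dm$age_band)
  age <- dplyr::case_when(
    is.na(band) ~ NA_real_,
    band == "<18" ~ runif(n, 2, 17.5),
    band == "18-64" ~ runif(n, 18, 64.5),
    TRUE ~ runif(n, 65, 95)
  )
  wband <- sample_marginal(n, dm$weight_band)
  weight <- dplyr::case_when(
    is.na(wband) ~ NA_real_,
    wband == "<50 kg" ~ runif(n, 35, 49.5),
    wband == "50-100 kg" ~ runif(n, 50, 100),
    TRUE ~ runif(n, 101, 150)
  )
  route <- sample_marginal(n, dm$route)
  route_raw <- dplyr::case_when(
    is.na(route) ~ NA_character_,
    route == "oral" ~ "Oral",
    route == "topical" ~ "Topical",
    TRUE ~ "Intravenous"
  )
  reporter <- sample_marginal(n, dm$reporter)
  country <- sample(c("united states", "germany", "canada"), n,
                    replace = TRUE, prob = c(0.8, 0.15, 0.05))

  # receipt and onset dates
  year <- sample(config$years, n, replace = TRUE)
  receipt <- as.Date(sprintf("%d-01-01", year)) +
    sample.int(364, n, replace = TRUE) - 1
  receipt_date <- format(receipt, "%Y%m%d")
  has_dates <- runif(n) < config$tto$fraction_with_dates
  tto <- pmax(1, ceiling(stats::rweibull(n, shape = config$tto$shape,
                                         scale = config$tto$scale)))
  start <- receipt - sample.int(300, n, replace = TRUE)
  start_date <- ifelse(has_dates, format(start, "%Y%m%d"), NA_character_)
  event_date <- ifelse(has_dates, format(start + tto, "%Y%m%d"), NA_character_)

  reports <- tibble(
    report_key = report_key, case_key = case_key,
    receipt_date = receipt_date, gender = gender, age_years = age,
    weight_kg = weight, route = route, reporter = reporter,
    country = country, event_date = event_date, source_db = "faers"
  )
  drugs <- tibble(
    report_key = report_key,
    name_raw = toupper(drug_names[drug_idx]),
    name_normalized = drug_names[drug_idx],
    ai_normalized = drug_names[drug_idx],
    role = "primary_suspect",
    route_raw = route_raw,
    start_date = start_date
  )

  # duplicate case versions: exact clones except report key / receipt date
  n_dup <- floor(config$duplicate_rate * n)
  manifest_dups <- tibble(case_key = character(),
                          report_key_v1 = character(),
                          report_key_v2 = character())
  if (n_dup > 0) {
    dup_i <- sort(sample.int(n, n_dup))
    new_key <- as.character(10000000 + n + seq_len(n_dup))
    dup_reports <- reports[dup_i, ]
    dup_reports$report_key <- new_key
    dup_reports$receipt_date <- format(
      as.Date(dup_reports$receipt_date, "%Y%m%d") + 1, "%Y%m%d")
    clone_child <- function(df) {
      cl <- df[df$report_key %in% report_key[dup_i], ]
      cl$report_key <- new_key[match(cl$report_key, report_key[dup_i])]
      cl
    }
    reports <- dplyr::bind_rows(reports, dup_reports)
    drugs <- dplyr::bind_rows(drugs, clone_child(drugs))
    events <- dplyr::bind_rows(events, clone_child(events))
    indications <- dplyr::bind_rows(indications, clone_child(indications))
    manifest_dups <- tibble(case_key = case_key[dup_i],
                            report_key_v1 = report_key[dup_i],
                            report_key_v2 = new_key)
  }

  store <- report_store(reports, drugs, events, indications,
                        log = sprintf("generate_reports: %d cases, %d duplicate versions",
                                      n, n_dup))
  structure(
    list(store = store,
         manifest = list(planted = config$planted_signals,
                         duplicates = manifest_dups,
                         case_keys = case_key)),
    class = "synthetic_reports"
  )
}

#' @export
print.synthetic_reports <- function(x, ...) {
  cat("<synthetic_reports> ", length(x$manifest$case_keys), " cases, ",
      nrow(x$manifest$duplicates), " duplicates, ",
      nrow(x$manifest$planted), " planted signals\n", sep = "")
  invisible(x)
}

# --- FAERS-dialect serialization -------------------------------------------

role_to_cod <- c(primary_suspect = "PS", secondary_suspect = "SS",
                 concomitant = "C", interacting = "I", suspect = "SS")
reporter_to_cod <- c(healthcare_professional = "MD", consumer = "CN",
                     other = "LW")
gender_to_cod <- c(male = "M", female = "F")

#' Write a store as FAERS-style quarterly files
#'
#' Emits DEMO, DRUG, REAC, INDI and THER files in the '$'-delimited dialect
#' that [parse_faers_quarter()] reads, such that re-parsing reproduces the
#' normalized store (round trip). Partial dates serialize as truncated
#' digit strings.
#'
#' @param store A `report_store`.
#' @param dir Output directory, created if needed.
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_faers_fixture <- function(store, dir) {
  stopifnot(inherits(store, "report_store"))
  if (n_reports(store) == 0) {
    stop_pv("cannot serialize an empty store", "pv_empty_store")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(demo = file.path(dir, "DEMO.txt"),
             drug = file.path(dir, "DRUG.txt"),
             reac = file.path(dir, "REAC.txt"),
             indi = file.path(dir, "INDI.txt"),
             ther = file.path(dir, "THER.txt"))

  rep <- store$reports
  demo <- tibble(
    PRIMARYID = rep$report_key, CASEID = rep$case_key,
    FDA_DT = rep$receipt_date, EVENT_DT = rep$event_date,
    SEX = unname(gender_to_cod[rep$gender]),
    AGE = rep$age_years, AGE_COD = ifelse(is.na(rep$age_years), NA, "YR"),
    WT = rep$weight_kg, WT_COD = ifelse(is.na(rep$weight_kg), NA, "KG"),
    OCCP_COD = unname(reporter_to_cod[rep$reporter]),
    REPORTER_COUNTRY = rep$country
  )
  drugs <- store$drugs |>
    dplyr::group_by(.data$report_key) |>
    dplyr::mutate(DRUG_SEQ = as.character(dplyr::row_number())) |>
    dplyr::ungroup()
  drug_out <- tibble(
    PRIMARYID = drugs$report_key, DRUG_SEQ = drugs$DRUG_SEQ,
    ROLE_COD = unname(role_to_cod[drugs$role]),
    DRUGNAME = drugs$name_raw, PROD_AI = toupper(drugs$ai_normalized),
    ROUTE = drugs$route_raw
  )
  ther <- drugs |>
    dplyr::filter(!is.na(.data$start_date)) |>
    dplyr::transmute(PRIMARYID = .data$report_key,
                     DSG_DRUG_SEQ = .data$DRUG_SEQ,
                     START_DT = .data$start_date)
  reac <- tibble(PRIMARYID = store$events$report_key, PT = store$events$pt)
  indi <- tibble(PRIMARYID = store$indications$report_key,
                 INDI_DRUG_SEQ = "1", INDI_PT = store$indications$pt)

  readr::write_delim(demo, paths["demo"], delim = "$", na = "")
  readr::write_delim(drug_out, paths["drug"], delim = "$", na = "")
  readr::write_delim(reac, paths["reac"], delim = "$", na = "")
  readr::write_delim(indi, paths["indi"], delim = "$", na = "")
  readr::write_delim(ther, paths["ther"], delim = "$", na = "")
  invisible(paths)
}

# --- demographic fixture reconstruction ------------------------------------

#' Reconstruct a report store from published demographic marginals
#'
#' Builds a store whose per-variable category counts match a marginal table
#' (columns `variable`, `category`, `n`) exactly; variables are filled
#' independently, which suffices for marginal summaries. Used to validate
#' [summarize_demographics()] against published "Table 1"-style counts.
#'
#' @param marginals Tibble with columns `variable`, `category`, `n`;
#'   variables `gender`, `age`, `route`, `weight`, `reporter`,
#'   `indication`, `country`, `year` are recognized.
#' @return A `report_store` with one report per case.
#' @export
reports_from_marginals <- function(marginals) {
  marginals <- as_tibble(marginals)
  totals <- marginals |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  if (length(unique(totals$total)) != 1) {
    stop_pv("marginal variables disagree on the report total",
            "pv_invalid_config")
  }
  total <- totals$total[1]

  expand <- function(variable) {
    sub <- marginals[marginals$variable == variable, ]
    if (nrow(sub) == 0) return(rep(NA_character_, total))
    out <- rep(sub$category, sub$n)
    out[out == "missing"] <- NA_character_
    out
  }

  gender <- expand("gender")
  age <- c("<18" = 10, "18-64" = 40, ">=65" = 75)[expand("age")]
  weight <- c("<50 kg" = 45, "50-100 kg" = 75, ">100 kg" = 120)[expand("weight")]
  route <- expand("route")
  reporter <- expand("reporter")
  country <- expand("country")
  year <- expand("year")
  ind <- expand("indication")

  key <- as.character(seq_len(total))
  reports <- tibble(
    report_key = key, case_key = key,
    receipt_date = ifelse(is.na(year), NA_character_, paste0(year, "0601")),
    gender = gender, age_years = unname(age), weight_kg = unname(weight),
    route = route, reporter = reporter, country = country,
    event_date = NA_character_, source_db = "faers"
  )
  indications <- tibble(report_key = key, pt = ind) |>
    dplyr::filter(!is.na(.data$pt))
  report_store(reports, indications = indications)
}
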