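# Field-level normalization shared by the FAERS and CVARD readers: unit
# conversion for age and weight, free-text route mapping, reporter and drug
# role code maps.

# AGE_COD multipliers to years. Values outside [0, 120] become missing.
age_unit_factors <- c(
  "DEC" = 10, "YR" = 1, "MON" = 1 / 12, "WK" = 7 / 365.25,
  "DY" = 1 / 365.25, "HR" = 1 / 8760,
  # CVARD English unit spellings
  "DECADE" = 10, "DECADES" = 10, "YEARS" = 1, "YEAR" = 1,
  "MONTHS" = 1 / 12, "MONTH" = 1 / 12, "WEEKS" = 7 / 365.25,
  "DAYS" = 1 / 365.25, "HOURS" = 1 / 8760
)

convert_age_years <- function(age, unit) {
  age <- suppressWarnings(as.numeric(age))
  unit <- toupper(stringr::str_trim(as.character(unit)))
  unit[is.na(unit) | unit == ""] <- "YR"  # bare values are taken as years
  fac <- unname(age_unit_factors[unit])
  out <- age * fac
  out[is.na(out) | out < 0 | out > 120] <- NA_real_
  out
}

LBS_PER_KG <- 0.45359237

convert_weight_kg <- function(wt, unit) {
  wt <- suppressWarnings(as.numeric(wt))
  unit <- toupper(stringr::str_trim(as.character(unit)))
  unit[is.na(unit) | unit == ""] <- "KG"
  out <- dplyr::case_when(
    unit %in% c("KG", "KGS", "KILOGRAMS", "KILOGRAM") ~ wt,
    unit %in% c("LBS", "LB", "POUNDS", "POUND") ~ wt * LBS_PER_KG,
    unit %in% c("GMS", "GRAMS") ~ wt / 1000,
    TRUE ~ NA_real_
  )
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

#' Route normalization dictionary
#'
#' Maps free-text administration routes onto the three-way split used in
#' demographic tables: oral, topical, other. Unknown non-missing strings map
#' to "other"; absent values stay missing.
#'
#' @return Named character vector (normalized free text -> category).
#' @export
route_dictionary <- function() {
  c(
    "oral" = "oral", "po" = "oral", "by mouth" = "oral", "mouth" = "oral",
    "oral, unspecified" = "oral",
    "topical" = "topical", "cutaneous" = "topical", "dermal" = "topical",
    "transdermal" = "topical", "skin" = "topical"
  )
}

normalize_route <- function(route_raw, dictionary = route_dictionary()) {
  r <- normalize_name(route_raw)
  out <- unname(dictionary[r])
  out[is.na(out) & !is.na(r) & nzchar(r) & r != "unknown"] <- "other"
  out[is.na(route_raw) | !nzchar(trimws(as.character(route_raw)))] <- NA_character_
  out
}

normalize_gender <- function(x) {
  x <- toupper(stringr::str_trim(as.character(x)))
  dplyr::case_when(
    x %in% c("M", "MALE") ~ "male",
    x %in% c("F", "FEMALE") ~ "female",
    TRUE ~ NA_character_
  )
}

# FAERS OCCP_COD / CVARD reporter types -> reporter category
normalize_reporter <- function(x) {
  x <- toupper(stringr::str_trim(as.character(x)))
  dplyr::case_when(
    x %in% c("MD", "PH", "HP", "RN", "PHYSICIAN", "PHARMACIST",
             "HEALTH PROFESSIONAL", "OTHER HEALTH PROFESSIONAL") ~
      "healthcare_professional",
    x %in% c("CN", "CONSUMER", "CONSUMER OR NON-HEALTH PROFESSIONAL") ~ "consumer",
    x %in% c("LW", "OT", "LAWYER", "OTHER") ~ "other",
    TRUE ~ NA_character_
  )
}

# ROLE_COD (FAERS) and DRUGINVOLV_ENG (CVARD) -> role enum
normalize_role <- function(x) {
  x <- toupper(stringr::str_trim(as.character(x)))
  dplyr::case_when(
    x == "PS" ~ "primary_suspect",
    x == "SS" ~ "secondary_suspect",
    x %in% c("C", "CONCOMITANT") ~ "concomitant",
    x %in% c("I", "INTERACTING") ~ "interacting",
    x == "SUSPECT" ~ "suspect",
    TRUE ~ NA_character_
  )
}
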