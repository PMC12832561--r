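# Internal helpers shared across modules: string normalization, partial-date
# handling, and round-half-up formatting.

#' Normalize a drug or event name
#'
#' Lowercases, trims, and collapses internal whitespace. All name and
#' preferred-term matching in the package happens on this normalized form.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_name(c("  DALIRESP ", "Chronic  Obstructive Pulmonary Disease"))
normalize_name <- function(x) {
  stringr::str_squish(stringr::str_to_lower(as.character(x)))
}

#' Round half away from zero
#'
#' Deterministic decimal rounding with ties going up (2.345 -> 2.35 at two
#' digits), matching the convention of published pharmacovigilance tables.
#' Base `round()` rounds half to even and is not used for report output.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# --- partial calendar dates -------------------------------------------------
# Spontaneous-report dates come as YYYY, YYYYMM, or YYYYMMDD digit strings
# (FAERS) or dash-separated ISO prefixes (CVARD). They are stored as bare
# digit strings plus a precision, and compared in zero-padded numeric form.

# Canonical digit string ("2013", "201305", "20130518") or NA.
clean_date_string <- function(x) {
  x <- stringr::str_remove_all(as.character(x), "[-/ ]")
  x[!stringr::str_detect(x, "^[0-9]{4}([0-9]{2}([0-9]{2})?)?$")] <- NA_character_
  x
}

# "year", "month", "day", or NA.
date_precision <- function(x) {
  dplyr::case_when(
    is.na(x) ~ NA_character_,
    nchar(x) == 4 ~ "year",
    nchar(x) == 6 ~ "month",
    nchar(x) == 8 ~ "day"
  )
}

# Zero-padded numeric form for ordering (20130500 for "201305").
date_num <- function(x) {
  suppressWarnings(as.numeric(stringr::str_pad(x, 8, side = "right", pad = "0")))
}

date_year <- function(x) {
  suppressWarnings(as.integer(substr(x, 1, 4)))
}

# Date object for day-precision strings; NA otherwise.
date_as_Date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & nchar(x) == 8
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out
}

# stop() with a classed condition, keeping error handling testable
stop_pv <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pvsignal_error"))
}

`%||%` <- rlang::`%||%`
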