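# Event-term hierarchy (preferred term -> system organ class) and drug-label
# dictionaries. The full MedDRA terminology is licensed and must be supplied
# by the user; the package ships a small fixture vocabulary covering the
# organ classes exercised by its examples and tests.

#' Load a PT-to-SOC vocabulary
#'
#' Reads a two-column delimited file mapping preferred terms (PT) to system
#' organ classes (SOC). Terms are normalized (lowercased, trimmed) so that
#' downstream matching is case-insensitive. Duplicate PT rows are allowed
#' only when they agree on the SOC; conflicting rows are an error.
#'
#' @param path Path to a tab- or comma-delimited file with columns `pt` and
#'   `soc` (header required).
#' @return An `event_vocabulary` object: a tibble of (`pt`, `soc`) plus the
#'   SOC set.
#' @export
load_vocabulary <- function(path) {
  df <- readr::read_delim(path, delim = guess_delim(path), trim_ws = TRUE,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("pt", "soc") %in% names(df))) {
    stop_pv(sprintf("vocabulary file '%s' needs columns pt and soc", path),
            "pv_format_error")
  }
  event_vocabulary(df$pt, df$soc)
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Build an event vocabulary from vectors
#'
#' @param pt,soc Character vectors of equal length.
#' @return An `event_vocabulary` object.
#' @export
event_vocabulary <- function(pt, soc) {
  tab <- tibble(pt = normalize_name(pt), soc = normalize_name(soc)) |>
    dplyr::distinct()
  if (nrow(tab) == 0) {
    stop_pv("empty vocabulary", "pv_format_error")
  }
  dup <- tab$pt[duplicated(tab$pt)]
  if (length(dup) > 0) {
    stop_pv(paste0("conflicting SOC assignments for PT(s): ",
                   paste(unique(dup), collapse = ", ")),
            "pv_vocab_conflict")
  }
  structure(list(table = tab, soc_set = sort(unique(tab$soc))),
            class = "event_vocabulary")
}

#' @export
print.event_vocabulary <- function(x, ...) {
  cat("<event_vocabulary> ", nrow(x$table), " preferred terms across ",
      length(x$soc_set), " system organ classes\n", sep = "")
  invisible(x)
}

#' Map preferred terms to system organ classes
#'
#' Unmapped terms return the reserved class `"unmapped"`.
#'
#' @param vocab An `event_vocabulary`.
#' @param pt Character vector of preferred terms (any case).
#' @return Character vector of SOC names.
#' @export
map_pt_to_soc <- function(vocab, pt) {
  stopifnot(inherits(vocab, "event_vocabulary"))
  idx <- match(normalize_name(pt), vocab$table$pt)
  out <- vocab$table$soc[idx]
  out[is.na(out)] <- "unmapped"
  out
}

# --- label dictionaries -----------------------------------------------------

#' Build a drug-label dictionary
#'
#' Lists the adverse-event preferred terms documented in one agency's
#' product label, with an optional synonym map sending reported variants to
#' their canonical labeled term. Synonym targets must be labeled terms.
#'
#' @param agency `"fda"` or `"canada"`.
#' @param labeled_terms Character vector of labeled preferred terms.
#' @param synonyms Optional named character vector
#'   (`c(variant = "canonical term")`).
#' @return A `label_dictionary` object.
#' @export
label_dictionary <- function(agency, labeled_terms, synonyms = character()) {
  agency <- match.arg(agency, c("fda", "canada"))
  labeled <- unique(normalize_name(labeled_terms))
  syn <- setNames(normalize_name(unname(synonyms)),
                  normalize_name(names(synonyms)))
  if (length(syn) > 0 && !all(syn %in% labeled)) {
    stop_pv("synonym targets must be members of the labeled-term set",
            "pv_label_error")
  }
  structure(list(agency = agency, labeled_terms = labeled, synonym_map = syn),
            class = "label_dictionary")
}

#' Load a label dictionary from a delimited file
#'
#' @param path File with a `term` column and optionally a `canonical` column:
#'   rows with an empty `canonical` are labeled terms, the others synonyms.
#' @param agency `"fda"` or `"canada"`.
#' @return A `label_dictionary`.
#' @export
load_label_dictionary <- function(path, agency) {
  df <- readr::read_delim(path, delim = guess_delim(path), trim_ws = TRUE,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  if (!"term" %in% names(df)) {
    stop_pv(sprintf("label file '%s' needs a term column", path),
            "pv_format_error")
  }
  if (!"canonical" %in% names(df)) df$canonical <- NA_character_
  is_syn <- !is.na(df$canonical) & nzchar(df$canonical)
  label_dictionary(agency,
                   labeled_terms = df$term[!is_syn],
                   synonyms = setNames(df$canonical[is_syn], df$term[is_syn]))
}

#' Classify preferred terms as labeled or unlabeled per agency
#'
#' A term counts as labeled when, after synonym canonicalization, it matches
#' a labeled term exactly (case-insensitive). Signals positive in
#' disproportionality analysis but unlabeled in every supplied dictionary
#' are the "unexpected" findings of a pharmacovigilance study.
#'
#' @param pt Character vector of preferred terms.
#' @param label_dicts A list of [label_dictionary()] objects.
#' @return A tibble with column `pt` plus one `labeled_<agency>` logical
#'   column per dictionary.
#' @export
classify_labeledness <- function(pt, label_dicts) {
  if (inherits(label_dicts, "label_dictionary")) label_dicts <- list(label_dicts)
  out <- tibble(pt = pt)
  key <- normalize_name(pt)
  for (dict in label_dicts) {
    canon <- key
    hit <- match(canon, names(dict$synonym_map))
    canon[!is.na(hit)] <- unname(dict$synonym_map[hit[!is.na(hit)]])
    out[[paste0("labeled_", dict$agency)]] <- canon %in% dict$labeled_terms
  }
  out
}
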