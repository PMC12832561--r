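# Within-drug subgroup comparisons: for each frequent event, a 2x2 table of
# event vs all-other-events crossed with target vs control stratum, all
# within the query drug's reports. The resulting stratified ROR ("adjusted
# ROR" in pharmacovigilance reporting) is paired with a two-sided test and
# Benjamini-Hochberg false-discovery-rate control across events.

stratum_values <- function(store, variable) {
  rep <- store$reports
  switch(variable,
    gender = rep$gender,
    age_band = age_band(rep$age_years),
    route = rep$route,
    stop_pv(sprintf("unknown stratum variable '%s'", variable),
            "pv_invalid_stratum")
  )
}

#' Stratified reporting odds ratio across subgroups
#'
#' For each event, builds the 2x2 table (target-stratum reports with the
#' event, target without, control with, control without) within the drug's
#' own reports, computes the ROR with a Woolf interval (Haldane-Anscombe
#' 0.5 correction on zero cells, flagged), a two-sided p-value (Fisher's
#' exact test when any expected cell is below `fisher_threshold`, otherwise
#' the Yates-corrected chi-squared test), and the FDR-adjusted p-value
#' across all events tested. An estimate above 1 means the event is
#' reported disproportionately often in the target stratum.
#'
#' @param store A deduplicated `report_store` already restricted to the
#'   query drug.
#' @param variable `"gender"`, `"age_band"`, or `"route"`.
#' @param target,control Stratum values compared (e.g. `"female"` vs
#'   `"male"`; `">=65"` vs `"18-64"`; `"oral"` vs `"topical"`). Reports in
#'   neither stratum (including missing) are excluded.
#' @param top_k When `events` is `NULL`, test the `top_k` most frequent
#'   preferred terms among the included reports.
#' @param events Optional explicit character vector of preferred terms.
#' @param fisher_threshold Expected-cell cutoff for the Fisher fallback.
#' @return A tibble with one row per event: cells `a`, `b`, `c`, `d`
#'   (target-with, target-without, control-with, control-without),
#'   `adj_ror`, `ror_lo`, `ror_hi`, `ror_corrected`, `p`, `p_adj`,
#'   `stratum_variable`, `target_label`, `control_label`.
#' @export
subgroup_ror <- function(store, variable, target, control,
                         top_k = 50, events = NULL, fisher_threshold = 5) {
  stopifnot(inherits(store, "report_store"))
  strata <- stratum_values(store, variable)
  in_target <- !is.na(strata) & strata == target
  in_control <- !is.na(strata) & strata == control
  n_t <- sum(in_target)
  n_c <- sum(in_control)
  if (n_t == 0 || n_c == 0) {
    stop_pv(sprintf("empty stratum: %s has %d target and %d control reports",
                    variable, n_t, n_c), "pv_empty_stratum")
  }
  keys_t <- store$reports$report_key[in_target]
  keys_c <- store$reports$report_key[in_control]

  ev <- dplyr::distinct(store$events, .data$report_key, .data$pt) |>
    dplyr::filter(.data$report_key %in% c(keys_t, keys_c))
  if (is.null(events)) {
    events <- ev |>
      dplyr::count(.data$pt, sort = TRUE) |>
      dplyr::arrange(dplyr::desc(.data$n), .data$pt) |>
      head(top_k) |>
      dplyr::pull("pt")
  } else {
    events <- normalize_name(events)
  }

  res <- purrr::map_dfr(events, function(e) {
    with_e <- ev$report_key[ev$pt == e]
    a <- sum(keys_t %in% with_e)
    c_ <- sum(keys_c %in% with_e)
    tibble(event = e, a = a, b = n_t - a, c = c_, d = n_c - c_)
  })

  or <- ror_with_ci(res$a, res$b, res$c, res$d)
  p <- purrr::pmap_dbl(res[, c("a", "b", "c", "d")], function(a, b, c, d) {
    m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected < fisher_threshold)) {
      fisher.test(m)$p.value
    } else {
      suppressWarnings(chisq.test(m, correct = TRUE)$p.value)
    }
  })

  dplyr::bind_cols(res, or) |>
    dplyr::rename(adj_ror = "ror") |>
    dplyr::mutate(
      p = p,
      p_adj = fdr_adjust(p),
      stratum_variable = variable,
      target_label = target,
      control_label = control
    )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `p_adj(i) = min_{j >= i} (m p(j) / j)` on
#' ascending-sorted p-values, capped at 1, returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_pv("p-values must lie in [0, 1]", "pv_invalid_p")
  }
  p.adjust(p, method = "BH")
}

#' Default co-medication exclusion list
#'
#' Long-acting beta-2 agonist products commonly co-administered with the
#' study drug in obstructive lung disease: formoterol alone, dual
#' corticosteroid/formoterol combinations, and triple-therapy components.
#'
#' @return Character vector of product and ingredient names.
#' @export
default_comedications <- function() {
  c("formoterol",
    "budesonide/formoterol", "mometasone/formoterol", "fluticasone/formoterol",
    "budesonide/formoterol/glycopyrrolate",
    "fluticasone/umeclidinium/vilanterol",
    "umeclidinium", "vilanterol", "glycopyrrolate")
}

#' Drop reports with co-medication exposure
#'
#' Sensitivity reanalysis support: removes any report in which any drug
#' entry, in any role, matches any of the co-medication names (same
#' case-insensitive substring rule as [select_drug_reports()], applied to
#' both product name and active ingredient).
#'
#' @param store A `report_store`.
#' @param comed_names Character vector of names; defaults to
#'   [default_comedications()].
#' @return A filtered `report_store` (a subset of the input).
#' @export
exclude_comedications <- function(store, comed_names = default_comedications()) {
  stopifnot(inherits(store, "report_store"))
  comed_names <- normalize_name(comed_names)
  comed_names <- comed_names[nzchar(comed_names)]
  if (length(comed_names) == 0) {
    stop_pv("co-medication list must be nonempty", "pv_invalid_query")
  }
  hit_keys <- unique(store$drugs$report_key[
    match_drug_names(store$drugs, comed_names)])
  keep <- setdiff(store$reports$report_key, hit_keys)
  filter_store(store, keep,
               sprintf("exclude_comedications: dropped %d of %d reports",
                       length(hit_keys), n_reports(store)))
}
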