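# 2x2 contingency tables for drug-event pairs against the all-other-drugs
# background. The counting unit is the report: a report contributes at most
# once per preferred term, and once per system organ class even when several
# of its terms share that class.
#
#                event   no event
#   target drug    a        b        a + b = target report total
#   other drugs    c        d        a + b + c + d = N, the database total

# Per-report distinct event units at the requested level.
event_units <- function(store, level, vocab) {
  ev <- store$events
  if (level == "soc") {
    if (is.null(vocab)) {
      stop_pv("SOC-level counting needs an event vocabulary", "pv_vocab_missing")
    }
    ev <- ev |>
      dplyr::mutate(event = map_pt_to_soc(vocab, .data$pt)) |>
      dplyr::distinct(.data$report_key, .data$event)
  } else {
    ev <- ev |>
      dplyr::mutate(event = normalize_name(.data$pt)) |>
      dplyr::distinct(.data$report_key, .data$event)
  }
  ev
}

#' Build contingency tables for all events
#'
#' One table per event observed in the target reports with at least
#' `min_count` target cases, sorted by the `a` cell descending and event name
#' ascending (deterministic ties).
#'
#' @param target A `report_store` of reports selected for the query drug.
#' @param background A `report_store` of all other reports from the same
#'   extract; must be disjoint from `target`.
#' @param level `"pt"` or `"soc"`.
#' @param vocab An [event_vocabulary()], required at SOC level.
#' @param min_count Minimum `a` cell to keep an event.
#' @return A tibble with columns `event`, `level`, `a`, `b`, `c`, `d`.
#' @export
contingency_tables <- function(target, background, level = c("pt", "soc"),
                               vocab = NULL, min_count = 1) {
  level <- match.arg(level)
  stopifnot(min_count >= 1)
  if (any(target$reports$report_key %in% background$reports$report_key)) {
    stop_pv("target and background report sets must be disjoint",
            "pv_overlapping_sets")
  }
  n_t <- n_reports(target)
  n_b <- n_reports(background)

  tu <- event_units(target, level, vocab)
  bu <- event_units(background, level, vocab)

  a_tab <- dplyr::count(tu, .data$event, name = "a")
  c_tab <- dplyr::count(bu, .data$event, name = "c")

  a_tab |>
    dplyr::left_join(c_tab, by = "event") |>
    dplyr::mutate(
      c = dplyr::coalesce(.data$c, 0L),
      b = n_t - .data$a,
      d = n_b - .data$c,
      level = level
    ) |>
    dplyr::filter(.data$a >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$a), .data$event) |>
    dplyr::select("event", "level", "a", "b", "c", "d")
}

#' Build the contingency table for a single event
#'
#' @inheritParams contingency_tables
#' @param event A preferred term (`level = "pt"`) or system organ class
#'   (`level = "soc"`).
#' @return A one-row tibble as in [contingency_tables()]; the event may have
#'   zero target cases.
#' @export
contingency_table <- function(target, background, event,
                              level = c("pt", "soc"), vocab = NULL) {
  level <- match.arg(level)
  event <- normalize_name(event)
  if (level == "soc") {
    if (is.null(vocab)) {
      stop_pv("SOC-level counting needs an event vocabulary", "pv_vocab_missing")
    }
    if (!event %in% c(vocab$soc_set, "unmapped")) {
      stop_pv(sprintf("'%s' is not a system organ class in the vocabulary", event),
              "pv_unknown_event")
    }
  }
  all_tabs <- contingency_tables(target, background, level, vocab, min_count = 1)
  row <- dplyr::filter(all_tabs, .data$event == .env$event)
  if (nrow(row) == 0) {
    tu <- event_units(background, level, vocab)
    c_cell <- sum(tu$event == event)
    row <- tibble(event = event, level = level, a = 0L,
                  b = n_reports(target), c = c_cell,
                  d = n_reports(background) - c_cell)
  }
  row
}
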