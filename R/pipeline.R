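# End-to-end orchestration: ingest -> select -> deduplicate -> exclude noise
# terms -> contingency -> signal statistics -> labeledness -> time-to-onset
# -> subgroups -> co-medication sensitivity, with every stage writing its
# tabular output and the run log carrying record counts for the whole flow.

#' Split a store into target-drug and background reports
#'
#' @param store A deduplicated `report_store`.
#' @param query A [drug_query()].
#' @return List with elements `target` and `background`, two disjoint
#'   stores partitioning the input.
#' @export
partition_reports <- function(store, query) {
  target <- select_drug_reports(store, query)
  background <- filter_store(
    store, setdiff(store$reports$report_key, target$reports$report_key),
    sprintf("partition_reports: %d background reports",
            n_reports(store) - n_reports(target)))
  list(target = target, background = background)
}

#' Assemble and validate a pipeline configuration
#'
#' All paths and thresholds for [run_pipeline()], validated up front so the
#' run fails before ingestion rather than mid-flow.
#'
#' @param faers_paths Named list/vector of FAERS table paths (`demo`,
#'   `drug`, `reac`, optionally `indi`, `ther`), or `NULL` when `store` is
#'   given.
#' @param store An in-memory `report_store` alternative to `faers_paths`.
#' @param query A [drug_query()].
#' @param vocabulary An [event_vocabulary()] or path to one.
#' @param label_dicts List of [label_dictionary()] objects (may be empty).
#' @param exclusion_terms Event terms to strip; see [exclude_noise_terms()].
#' @param level `"pt"` or `"soc"` for the main signal table.
#' @param min_count Minimum target case count per event.
#' @param criteria A [signal_criteria()] list.
#' @param subgroups List of lists `(variable, target, control)` to compare.
#' @param comedications Names for the sensitivity exclusion;
#'   `NULL` disables the sensitivity stage.
#' @param tto_cap_days Onset-interval cap for [extract_tto()].
#' @param out_dir Output directory.
#' @param seed Seed for the prior-fitting optimizer starts.
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(faers_paths = NULL, store = NULL, query,
                            vocabulary, label_dicts = list(),
                            exclusion_terms = default_exclusion_terms(),
                            level = c("soc", "pt"), min_count = 1,
                            criteria = signal_criteria(),
                            subgroups = list(
                              list(variable = "gender", target = "female",
                                   control = "male"),
                              list(variable = "age_band", target = ">=65",
                                   control = "18-64"),
                              list(variable = "route", target = "oral",
                                   control = "topical")),
                            comedications = default_comedications(),
                            tto_cap_days = 3650, out_dir = tempfile("pv_run_"),
                            seed = 1) {
  level <- match.arg(level)
  if (is.null(faers_paths) && is.null(store)) {
    stop_pv("pipeline_config needs faers_paths or an in-memory store",
            "pv_invalid_config")
  }
  if (!is.null(faers_paths)) {
    need <- c("demo", "drug", "reac")
    missing_tbl <- setdiff(need, names(faers_paths))
    if (length(missing_tbl) > 0) {
      stop_pv(paste0("faers_paths lacks table(s): ",
                     paste(missing_tbl, collapse = ", ")), "pv_invalid_config")
    }
    gone <- unlist(faers_paths)[!file.exists(unlist(faers_paths))]
    if (length(gone) > 0) {
      stop_pv(paste0("input file(s) not found: ", paste(gone, collapse = ", ")),
              "pv_invalid_config")
    }
  }
  if (is.character(vocabulary)) {
    if (!file.exists(vocabulary)) {
      stop_pv(paste0("vocabulary file not found: ", vocabulary),
              "pv_invalid_config")
    }
    vocabulary <- load_vocabulary(vocabulary)
  }
  stopifnot(inherits(query, "drug_query"),
            inherits(vocabulary, "event_vocabulary"),
            inherits(criteria, "signal_criteria"))
  structure(
    list(faers_paths = faers_paths, store = store, query = query,
         vocabulary = vocabulary, label_dicts = label_dicts,
         exclusion_terms = exclusion_terms, level = level,
         min_count = min_count, criteria = criteria, subgroups = subgroups,
         comedications = comedications, tto_cap_days = tto_cap_days,
         out_dir = out_dir, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full signal-detection pipeline
#'
#' Executes every stage in order, writes each stage's TSV beside a plain-text
#' run log with the record counts of the screening flow, and returns the
#' in-memory results. Any stage failure aborts with a stage-named error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the output directory, the per-stage
#'   tibbles, and the run log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", sprintf(...))
    log <<- c(log, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_pv(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "pv_stage_error")
    })
  }

  store <- stage("ingest", {
    if (!is.null(config$store)) {
      config$store
    } else {
      p <- config$faers_paths
      parse_faers_quarter(p$demo, p$drug, p$reac, p$indi %||% NULL,
                          p$ther %||% NULL)
    }
  })
  note("ingest: %d raw report versions", n_reports(store))

  selected <- stage("select", select_drug_reports(store, config$query))
  note("select: %d reports mention the query drug in an accepted role",
       n_reports(selected))

  dedup_all <- stage("deduplicate", deduplicate(store))
  dedup_sel <- stage("deduplicate", deduplicate(selected))
  note("deduplicate: %d cases total, %d for the query drug",
       n_reports(dedup_all), n_reports(dedup_sel))

  clean_sel <- stage("exclude_noise",
                     exclude_noise_terms(dedup_sel, config$exclusion_terms))
  note("exclude_noise: %d query-drug cases with informative events",
       n_reports(clean_sel))

  background <- stage("partition", filter_store(
    dedup_all, setdiff(dedup_all$reports$report_key,
                       dedup_sel$reports$report_key)))
  note("background: %d cases", n_reports(background))

  demo <- stage("demographics", summarize_demographics(clean_sel))
  write_out <- function(df, name) {
    readr::write_tsv(df, file.path(config$out_dir, name), na = "")
  }
  write_out(demo, "demographics.tsv")

  tables <- stage("contingency", contingency_tables(
    clean_sel, background, level = config$level, vocab = config$vocabulary,
    min_count = config$min_count))
  write_out(tables, "contingency.tsv")
  note("contingency: %d %s-level events", nrow(tables), config$level)

  signals <- stage("signals", {
    mgps <- if (nrow(tables) >= 50) NULL else default_mgps_priors()
    disproportionality(tables, mgps = mgps, criteria = config$criteria,
                       seed = config$seed)
  })
  signals <- stage("labeledness", {
    if (length(config$label_dicts) > 0) {
      lab <- classify_labeledness(signals$event, config$label_dicts)
      dplyr::bind_cols(signals, lab[-1])
    } else {
      signals
    }
  })
  write_out(signals, "signals.tsv")
  note("signals: %d events, %d positive on any algorithm, %d on all four",
       nrow(signals), sum(signals$positive_any), sum(signals$positive_all))

  tto <- stage("tto", extract_tto(clean_sel, config$query,
                                  cap_days = config$tto_cap_days))
  note("tto: %d usable onset records (%s excluded)", nrow(tto),
       paste(names(attr(tto, "exclusions")), attr(tto, "exclusions"),
             sep = "=", collapse = ", "))
  weib <- NULL
  if (nrow(tto) > 0) {
    ts <- stage("tto", tto_summary(tto))
    write_out(ts$bins, "tto_bins.tsv")
    write_out(tibble(n = ts$n, median_days = ts$median, q25 = ts$q25,
                     q75 = ts$q75), "tto_summary.tsv")
    write_out(tto_ecdf(tto), "tto_cumulative_incidence.tsv")
    if (length(unique(tto$tto_days)) >= 10) {
      weib <- stage("weibull", weibull_fit(tto))
      write_out(
        tibble(parameter = c("scale_alpha", "shape_beta"),
               estimate = c(weib$scale, weib$shape),
               ci_lo = c(weib$scale_ci[1], weib$shape_ci[1]),
               ci_hi = c(weib$scale_ci[2], weib$shape_ci[2]),
               n = weib$n, failure_class = weib$failure_class),
        "weibull.tsv")
      note("weibull: shape %.3f (%s failure type)", weib$shape,
           weib$failure_class)
    }
  }

  subgroup_results <- list()
  for (sg in config$subgroups) {
    res <- tryCatch(
      subgroup_ror(clean_sel, sg$variable, sg$target, sg$control),
      pvsignal_error = function(e) NULL
    )
    if (!is.null(res)) {
      nm <- sprintf("subgroup_%s.tsv", sg$variable)
      write_out(res, nm)
      subgroup_results[[sg$variable]] <- res
      note("subgroup %s (%s vs %s): %d events, %d with p_adj < 0.05",
           sg$variable, sg$target, sg$control, nrow(res),
           sum(res$p_adj < 0.05))
    } else {
      note("subgroup %s skipped: empty stratum", sg$variable)
    }
  }

  sensitivity <- NULL
  if (!is.null(config$comedications)) {
    sens_sel <- stage("sensitivity",
                      exclude_comedications(clean_sel, config$comedications))
    note("sensitivity: %d query-drug cases after co-medication exclusion",
         n_reports(sens_sel))
    if (n_reports(sens_sel) > 0) {
      sens_tabs <- stage("sensitivity", contingency_tables(
        sens_sel, background, level = config$level,
        vocab = config$vocabulary, min_count = config$min_count))
      sensitivity <- stage("sensitivity", {
        mgps <- if (nrow(sens_tabs) >= 50) NULL else default_mgps_priors()
        disproportionality(sens_tabs, mgps = mgps,
                           criteria = config$criteria, seed = config$seed) |>
          dplyr::mutate(analysis = "sensitivity")
      })
      write_out(sensitivity, "sensitivity_signals.tsv")
    }
  }

  store_dir <- file.path(config$out_dir, "normalized_store")
  write_store(clean_sel, store_dir)
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  yaml::write_yaml(resolved_config(config),
                   file.path(config$out_dir, "config.yaml"))

  invisible(list(out_dir = config$out_dir, demographics = demo,
                 contingency = tables, signals = signals, tto = tto,
                 weibull = weib, subgroups = subgroup_results,
                 sensitivity = sensitivity, log = log))
}

# serializable view of the configuration, written beside the outputs
resolved_config <- function(config) {
  list(
    query = list(names = config$query$names, roles = config$query$roles),
    level = config$level, min_count = config$min_count,
    criteria = unclass(config$criteria),
    exclusion_terms = config$exclusion_terms,
    comedications = config$comedications,
    tto_cap_days = config$tto_cap_days, seed = config$seed,
    subgroups = config$subgroups
  )
}

# Weakly-informative fallback prior for small event universes where marginal
# maximum likelihood is not identified (fewer than 50 tables).
default_mgps_priors <- function() {
  mgps_priors(shape1 = 1, rate1 = 1, shape2 = 2, rate2 = 2, mix_p = 0.5)
}

# --- publication-style rendering -------------------------------------------

fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Render a signal table in publication style
#'
#' Statistics to two decimals (half-up), intervals and companion statistics
#' in parentheses, an asterisk beside each algorithm meeting its positivity
#' criterion.
#'
#' @param signals Tibble from [disproportionality()].
#' @return Tibble with character columns `event`, `n`, `ror`, `prr`,
#'   `ebgm`, `ic`.
#' @export
render_signal_table <- function(signals) {
  star <- function(flag) ifelse(flag, "*", "")
  tibble(
    event = signals$event,
    n = signals$n,
    ror = paste0(fmt2(signals$ror), " (", fmt2(signals$ror_lo), ", ",
                 fmt2(signals$ror_hi), ")", star(signals$flag_ror)),
    prr = paste0(fmt2(signals$prr), " (", fmt2(signals$chi2), ")",
                 star(signals$flag_prr)),
    ebgm = paste0(fmt2(signals$ebgm), " (", fmt2(signals$ebgm05), ")",
                  star(signals$flag_mgps)),
    ic = paste0(fmt2(signals$ic), " (", fmt2(signals$ic025), ")",
                star(signals$flag_bcpnn))
  )
}

#' Forest-table of positive preferred terms above a case minimum
#'
#' The tabular twin of a PT-level forest plot: positive events with at
#' least `min_n` cases, most frequent first.
#'
#' @param signals Tibble from [disproportionality()] at PT level.
#' @param min_n Case minimum (30 by convention for display).
#' @return Filtered, sorted tibble.
#' @export
render_forest_table <- function(signals, min_n = 30) {
  signals |>
    dplyr::filter(.data$positive_any, .data$n >= min_n) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$event)
}

#' Render a demographic table in publication style
#'
#' @param demo Tibble from [summarize_demographics()].
#' @return Tibble with a formatted percentage column.
#' @export
render_demographics_table <- function(demo) {
  demo |>
    dplyr::mutate(pct = sprintf("%.1f%%", .data$pct))
}
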