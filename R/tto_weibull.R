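# Time-to-onset (TTO): days from initiation of the query drug to the
# adverse event, characterized by quantile summaries, an empirical
# cumulative-incidence curve, and a Weibull model whose shape parameter
# classifies the hazard pattern (early / random / wear-out failure).

#' Extract time-to-onset records
#'
#' TTO is the event date minus the earliest day-precision start date among
#' the report's drug entries matching the query. Records are excluded, with
#' logged reasons, when either date is missing or only partially known
#' (year or month precision), when the interval is non-positive, or when it
#' exceeds `cap_days` (a guard against date-entry errors).
#'
#' @param store A deduplicated `report_store`.
#' @param query A [drug_query()] identifying the target drug entries.
#' @param cap_days Maximum plausible interval, in days.
#' @return A tibble with columns `report_key`, `tto_days`; the counts of
#'   excluded reports by reason are attached as attribute `exclusions`.
#' @export
extract_tto <- function(store, query, cap_days = 3650) {
  stopifnot(inherits(store, "report_store"))
  matched <- store$drugs[match_drug_entries(store$drugs, query), ]

  starts <- matched |>
    dplyr::mutate(full = !is.na(.data$start_date) &
                    date_precision(.data$start_date) == "day") |>
    dplyr::group_by(.data$report_key) |>
    dplyr::summarise(
      start = if (any(.data$full)) min(.data$start_date[.data$full]) else NA_character_,
      has_any_start = any(!is.na(.data$start_date)),
      .groups = "drop"
    )

  df <- store$reports |>
    dplyr::inner_join(starts, by = "report_key") |>
    dplyr::mutate(
      event_full = !is.na(.data$event_date) &
        date_precision(.data$event_date) == "day",
      reason = dplyr::case_when(
        is.na(.data$start) & !.data$has_any_start ~ "missing date",
        is.na(.data$start) ~ "partial date",
        !.data$event_full & is.na(.data$event_date) ~ "missing date",
        !.data$event_full ~ "partial date",
        TRUE ~ "ok"
      )
    )
  ok <- df$reason == "ok"
  tto <- rep(NA_real_, nrow(df))
  tto[ok] <- as.numeric(date_as_Date(df$event_date[ok]) -
                          date_as_Date(df$start[ok]))
  df$reason[ok & tto <= 0] <- "non-positive"
  df$reason[ok & tto > cap_days] <- "over cap"

  keep <- df$reason == "ok"
  exclusions <- table(df$reason[!keep])
  out <- tibble(report_key = df$report_key[keep],
                tto_days = as.integer(tto[keep]))
  attr(out, "exclusions") <- exclusions
  out
}

#' Quantile with the inverse-empirical-CDF convention
#'
#' The package's single percentile rule: the smallest observed value whose
#' empirical CDF reaches `p` (base R type 1). The median under this rule is
#' the lower of the two middle values for even sample sizes, so all reported
#' quantiles are observed values.
#'
#' @param x Numeric vector.
#' @param p Probabilities.
#' @return Numeric vector of quantiles.
#' @export
tto_quantile <- function(x, p) {
  unname(quantile(x, probs = p, type = 1, names = FALSE))
}

#' Summarize time-to-onset records
#'
#' Median and interquartile range under the [tto_quantile()] convention,
#' plus counts and percentages per onset interval.
#'
#' @param tto_days Integer vector of onset times (or the tibble from
#'   [extract_tto()]).
#' @param bin_edges Upper edges of the onset bins in days; `Inf` closes the
#'   last bin.
#' @return A list of class `tto_summary`: `n`, `median`, `q25`, `q75`, and a
#'   `bins` tibble (`bin`, `n`, `pct`).
#' @export
tto_summary <- function(tto_days, bin_edges = c(30, 60, 90, 180, 360, Inf)) {
  if (is.data.frame(tto_days)) tto_days <- tto_days$tto_days
  if (length(tto_days) == 0) {
    stop_pv("no time-to-onset records to summarize", "pv_empty_input")
  }
  edges <- c(0, bin_edges)
  labels <- paste0(
    edges[-length(edges)] + 1, "-",
    ifelse(is.finite(edges[-1]), edges[-1], "")
  )
  labels <- sub("-$", "+", labels)
  idx <- findInterval(tto_days, edges + 1, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(labels))
  bins <- tibble(
    bin = labels, n = counts,
    pct = round_half_up(100 * counts / length(tto_days), 1)
  )
  structure(
    list(n = length(tto_days),
         median = tto_quantile(tto_days, 0.5),
         q25 = tto_quantile(tto_days, 0.25),
         q75 = tto_quantile(tto_days, 0.75),
         bins = bins),
    class = "tto_summary"
  )
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf("<tto_summary> n = %d, median %s days (IQR %s-%s)\n",
              x$n, format(x$median), format(x$q25), format(x$q75)))
  print(x$bins)
  invisible(x)
}

#' Empirical cumulative incidence of onset
#'
#' The fraction of onset records occurring by each observed day — the
#' tabular form of a cumulative-incidence (Kaplan-Meier-style) onset curve.
#' With every record carrying an observed event there is no censoring, so
#' this is the empirical CDF.
#'
#' @inheritParams tto_summary
#' @return Tibble with columns `day`, `cum_frac`.
#' @export
tto_ecdf <- function(tto_days) {
  if (is.data.frame(tto_days)) tto_days <- tto_days$tto_days
  days <- sort(unique(tto_days))
  tibble(day = days,
         cum_frac = vapply(days, function(d) mean(tto_days <= d), numeric(1)))
}

#' Fit a Weibull model to onset times
#'
#' Maximum-likelihood estimates of the scale (alpha, days) and shape (beta)
#' parameters with 95% confidence intervals from the normal approximation on
#' the log-parameter scale (delta method on the observed information). A
#' shape below 1 means a decreasing hazard: most events early in treatment.
#'
#' @param tto_days Integer vector of onset times in days (or the tibble
#'   from [extract_tto()]); needs at least 10 distinct values.
#' @return A `weibull_fit` object: `scale`, `shape`, `scale_ci`, `shape_ci`,
#'   `n`, `failure_class`, `loglik`.
#' @export
weibull_fit <- function(tto_days) {
  if (is.data.frame(tto_days)) tto_days <- tto_days$tto_days
  x <- as.numeric(tto_days)
  if (length(unique(x)) < 10) {
    stop_pv("Weibull fitting needs at least 10 distinct onset values",
            "pv_too_few_values")
  }
  fit <- fitdistrplus::fitdist(x, "weibull")
  est <- fit$estimate
  se <- fit$sd
  ci <- function(par) {
    # normal interval on log(par), back-transformed
    exp(log(est[par]) + c(-1, 1) * 1.96 * se[par] / est[par])
  }
  shape_ci <- unname(ci("shape"))
  out <- structure(
    list(scale = unname(est["scale"]), shape = unname(est["shape"]),
         scale_ci = unname(ci("scale")), shape_ci = shape_ci,
         n = length(x), loglik = fit$loglik),
    class = "weibull_fit"
  )
  out$failure_class <- classify_failure_type(out)
  out
}

#' Classify the hazard pattern from a Weibull shape estimate
#'
#' Early failure: shape below 1 with the whole interval below 1 (hazard
#' decreasing over treatment). Wear-out: shape above 1 with the whole
#' interval above 1. Random: the interval contains 1 (roughly constant
#' hazard). Anything else is indeterminate.
#'
#' @param fit A `weibull_fit`, or a shape estimate (with `ci`).
#' @param ci Length-2 interval when `fit` is numeric.
#' @return One of `"early"`, `"random"`, `"wear_out"`, `"indeterminate"`.
#' @export
classify_failure_type <- function(fit, ci = NULL) {
  if (inherits(fit, "weibull_fit")) {
    shape <- fit$shape
    ci <- fit$shape_ci
  } else {
    shape <- fit
  }
  if (shape < 1 && ci[2] < 1) {
    "early"
  } else if (shape > 1 && ci[1] > 1) {
    "wear_out"
  } else if (ci[1] <= 1 && ci[2] >= 1) {
    "random"
  } else {
    "indeterminate"
  }
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> n = %d\n  scale alpha = %.2f days (95%% CI %.2f-%.2f)\n  shape beta  = %.3f (95%% CI %.3f-%.3f)\n  pattern: %s failure type\n",
    x$n, x$scale, x$scale_ci[1], x$scale_ci[2],
    x$shape, x$shape_ci[1], x$shape_ci[2], x$failure_class))
  invisible(x)
}

#' @rdname weibull_fit
#' @param x A `weibull_fit` object.
#' @param ... Unused.
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble(
    term = c("scale", "shape"),
    estimate = c(x$scale, x$shape),
    conf.low = c(x$scale_ci[1], x$shape_ci[1]),
    conf.high = c(x$scale_ci[2], x$shape_ci[2])
  )
}

#' @rdname weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble(n = x$n, logLik = x$loglik, failure_class = x$failure_class)
}
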