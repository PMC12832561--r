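# Disproportionality statistics on 2x2 contingency tables. All four
# estimators operate on the same cells (a, b, c, d) with N = a + b + c + d:
#
#   ROR   (a*d)/(b*c) with a Woolf log-scale confidence interval
#   PRR   [a/(a+b)] / [c/(c+d)] with a Yates-corrected chi-squared statistic
#   IC    Bayesian shrinkage estimate of log2(observed/expected) co-reporting
#         with closed-form posterior mean and variance (BCPNN)
#   EBGM  empirical-Bayes geometric mean of the posterior reporting-rate
#         ratio under a two-component gamma mixture prior (gamma-Poisson
#         shrinker), with EBGM05 its 5th posterior percentile

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d)/(b c)`; the interval is
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero
#' the Haldane-Anscombe correction adds 0.5 to all four cells first and the
#' `ror_corrected` flag is set.
#'
#' @param a,b,c,d Integer vectors: target-with-event, target-without,
#'   background-with, background-without.
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @return Tibble with columns `ror`, `ror_lo`, `ror_hi`, `ror_corrected`.
#' @export
#' @examples
#' ror_with_ci(10, 90, 100, 9900)
ror_with_ci <- function(a, b, c, d, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(a == 0 & b == 0)) {
    stop_pv("no target reports (a = 0 and b = 0): ROR undefined",
            "pv_undefined_result")
  }
  corrected <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  a2 <- a + 0.5 * corrected
  b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected
  d2 <- d + 0.5 * corrected
  est <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  tibble(
    ror = est,
    ror_lo = exp(log(est) - z * se),
    ror_hi = exp(log(est) + z * se),
    ror_corrected = corrected
  )
}

#' Proportional reporting ratio with Yates-corrected chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`. The chi-squared statistic is the
#' Yates-corrected `N(|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`, floored
#' at zero when `|ad - bc| <= N/2`. A zero `c` cell yields an infinite PRR,
#' reported as `Inf` with the `prr_infinite` flag rather than an error.
#'
#' @inheritParams ror_with_ci
#' @return Tibble with columns `prr`, `chi2`, `prr_infinite`.
#' @export
prr_with_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(a + b == 0) || any(c + d == 0)) {
    stop_pv("PRR needs a + b > 0 and c + d > 0", "pv_undefined_result")
  }
  n <- a + b + c + d
  prr <- (a / (a + b)) / (c / (c + d))
  dev <- abs(a * d - b * c)
  chi2 <- ifelse(
    dev <= n / 2,
    0,
    n * (dev - n / 2)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  )
  tibble(prr = prr, chi2 = chi2, prr_infinite = is.infinite(prr))
}

#' BCPNN prior pseudo-counts
#'
#' Defaults give the standard closed-form information-component posterior:
#' row/column pseudo-counts of 1, total pseudo-counts of 2, joint
#' pseudo-count of 1.
#'
#' @param alpha1,beta1 Row and column pseudo-counts.
#' @param alpha,beta Total pseudo-counts.
#' @param gamma11 Joint pseudo-count.
#' @return A `bcpnn_priors` object.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                         gamma11 = 1) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
            gamma11 = gamma11)
  if (any(vals <= 0)) stop_pv("BCPNN priors must be positive", "pv_invalid_priors")
  structure(as.list(vals), class = "bcpnn_priors")
}

#' Information component with lower credibility bound (BCPNN)
#'
#' Closed-form posterior expectation and variance of the information
#' component IC = log2 of the shrunk observed-to-expected co-reporting
#' ratio; `ic025 = E(IC) - 2 sqrt(V(IC))`.
#'
#' @inheritParams ror_with_ci
#' @param priors A [bcpnn_priors()] object.
#' @return Tibble with columns `ic`, `ic025`.
#' @export
bcpnn_ic <- function(a, b, c, d, priors = bcpnn_priors()) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (any(n <= 0)) stop_pv("empty table: N must be positive", "pv_undefined_result")
  p <- priors
  row_ <- a + b + p$alpha1   # drug margin plus pseudo-count
  col_ <- a + c + p$beta1    # event margin plus pseudo-count
  gam <- p$gamma11 * (n + p$alpha) * (n + p$beta) / (row_ * col_)
  ic <- log2((a + p$gamma11) * (n + p$alpha) * (n + p$beta) /
               ((n + gam) * row_ * col_))
  vic <- (1 / log(2)^2) * (
    (n - a + gam - p$gamma11) / ((a + p$gamma11) * (1 + n + gam)) +
      (n - a - b + p$alpha - p$alpha1) / (row_ * (1 + n + p$alpha)) +
      (n - a - c + p$beta - p$beta1) / (col_ * (1 + n + p$beta))
  )
  tibble(ic = ic, ic025 = ic - 2 * sqrt(vic))
}

# --- gamma-Poisson shrinker -------------------------------------------------

#' Gamma-mixture hyperparameters for the gamma-Poisson shrinker
#'
#' @param shape1,rate1 First gamma component.
#' @param shape2,rate2 Second gamma component.
#' @param mix_p Weight of the first component, in `[0, 1]`.
#' @return An `mgps_priors` object.
#' @export
mgps_priors <- function(shape1, rate1, shape2, rate2, mix_p) {
  if (any(c(shape1, rate1, shape2, rate2) <= 0)) {
    stop_pv("gamma shapes and rates must be positive", "pv_invalid_priors")
  }
  if (mix_p < 0 || mix_p > 1) {
    stop_pv("mix_p must lie in [0, 1]", "pv_invalid_priors")
  }
  structure(list(shape1 = shape1, rate1 = rate1, shape2 = shape2,
                 rate2 = rate2, mix_p = mix_p),
            class = "mgps_priors")
}

#' @export
print.mgps_priors <- function(x, ...) {
  cat(sprintf(
    "<mgps_priors> p = %.3f * Gamma(%.3f, %.3f) + %.3f * Gamma(%.3f, %.3f)\n",
    x$mix_p, x$shape1, x$rate1, 1 - x$mix_p, x$shape2, x$rate2))
  invisible(x)
}

#' Expected count under row/column independence
#'
#' `E = (a + b)(a + c) / N`, the baseline co-reporting count the
#' gamma-Poisson shrinker compares observations against.
#'
#' @inheritParams ror_with_ci
#' @return Numeric vector of expected counts.
#' @export
expected_count <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  (a + b) * (a + c) / n
}

# marginal log-likelihood of observed counts under the mixture prior:
# a_i ~ NB(size = shape_j, prob = rate_j / (rate_j + E_i)) within component j
mgps_negloglik <- function(par, a, E) {
  s1 <- exp(par[1]); r1 <- exp(par[2])
  s2 <- exp(par[3]); r2 <- exp(par[4])
  p <- stats::plogis(par[5])
  l1 <- dnbinom(a, size = s1, prob = r1 / (r1 + E), log = TRUE)
  l2 <- dnbinom(a, size = s2, prob = r2 / (r2 + E), log = TRUE)
  m <- pmax(l1, l2)
  ll <- m + log(p * exp(l1 - m) + (1 - p) * exp(l2 - m))
  -sum(ll)
}

#' Fit gamma-Poisson shrinker priors by marginal maximum likelihood
#'
#' Maximizes the two-component negative-binomial mixture likelihood of the
#' observed `a` cells given their expected counts `E = (a+b)(a+c)/N`,
#' using bounded quasi-Newton optimization from several start points
#' (deterministic given `seed`). The event universe should cover the whole
#' database, not only the target drug's events.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (at least 50 rows),
#'   or columns `a` and `expected` when the expected counts are supplied
#'   directly.
#' @param n_starts Number of optimizer start points.
#' @param seed Seed controlling the jittered start points.
#' @return An `mgps_priors` object with attributes `loglik` and `converged`.
#' @export
fit_mgps_priors <- function(tables, n_starts = 8, seed = 1) {
  if (nrow(tables) < 50) {
    stop_pv("prior fitting needs at least 50 drug-event tables",
            "pv_too_few_tables")
  }
  a <- tables$a
  E <- if ("expected" %in% names(tables)) {
    tables$expected
  } else {
    expected_count(tables$a, tables$b, tables$c, tables$d)
  }
  keep <- E > 0
  a <- a[keep]; E <- E[keep]

  # DuMouchel's classic start plus seeded jitter
  base <- c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3))
  starts <- list(base,
                 c(log(1), log(1), log(1), log(1), 0),
                 c(log(0.5), log(0.5), log(5), log(1), stats::qlogis(0.1)))
  set.seed(seed %% .Machine$integer.max)
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1]] <- base + stats::rnorm(5, sd = 1)
  }

  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      optim(st, mgps_negloglik, a = a, E = E, method = "L-BFGS-B",
            lower = rep(-10, 5), upper = rep(10, 5),
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop_pv("gamma-mixture optimization failed from every start point",
            "pv_fit_failure")
  }
  par <- best$par
  out <- mgps_priors(exp(par[1]), exp(par[2]), exp(par[3]), exp(par[4]),
                     stats::plogis(par[5]))
  attr(out, "loglik") <- -best$value
  attr(out, "converged") <- any_conv
  if (!any_conv) {
    warn_cond <- simpleCondition("gamma-mixture fit did not formally converge; best parameters returned")
    class(warn_cond) <- c("pv_fit_warning", "warning", "condition")
    warning(warn_cond)
  }
  out
}

# posterior mixture for one (a, E): updated shapes/rates and weights
mgps_posterior <- function(a, E, priors) {
  l1 <- dnbinom(a, size = priors$shape1,
                prob = priors$rate1 / (priors$rate1 + E), log = TRUE)
  l2 <- dnbinom(a, size = priors$shape2,
                prob = priors$rate2 / (priors$rate2 + E), log = TRUE)
  w1 <- priors$mix_p * exp(l1 - max(l1, l2))
  w2 <- (1 - priors$mix_p) * exp(l2 - max(l1, l2))
  list(
    w = c(w1, w2) / (w1 + w2),
    shape = c(priors$shape1 + a, priors$shape2 + a),
    rate = c(priors$rate1 + E, priors$rate2 + E)
  )
}

#' Empirical-Bayes geometric mean and fifth percentile (EBGM, EBGM05)
#'
#' The posterior of the reporting-rate ratio is a two-component gamma
#' mixture with updated shapes and rates. `EBGM = 2^{E[log2 lambda]}` (the
#' posterior geometric mean); `EBGM05` is the 5th percentile of the mixture,
#' found by bisection on the mixture distribution function.
#'
#' @param a Observed counts (vector).
#' @param E Expected counts under independence (vector, same length).
#' @param priors An [mgps_priors()] object, typically from
#'   [fit_mgps_priors()].
#' @return Tibble with columns `ebgm`, `ebgm05`.
#' @export
ebgm <- function(a, E, priors) {
  stopifnot(inherits(priors, "mgps_priors"), length(a) == length(E))
  out_e <- numeric(length(a))
  out_q <- numeric(length(a))
  for (i in seq_along(a)) {
    post <- mgps_posterior(a[i], E[i], priors)
    elog <- sum(post$w * (digamma(post$shape) - log(post$rate))) / log(2)
    out_e[i] <- 2^elog
    out_q[i] <- mixture_gamma_quantile(0.05, post$w, post$shape, post$rate)
  }
  tibble(ebgm = out_e, ebgm05 = out_q)
}

# quantile of a gamma mixture by bisection on its CDF
mixture_gamma_quantile <- function(p, w, shape, rate, tol = 1e-8) {
  cdf <- function(x) sum(w * pgamma(x, shape = shape, rate = rate))
  lo <- 0
  hi <- max(qgamma(p, shape = shape, rate = rate)) + 1
  while (cdf(hi) < p) hi <- hi * 2
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# --- classification ---------------------------------------------------------

#' Signal-positivity criteria
#'
#' The standard threshold set used with the four algorithms: ROR positive
#' when `a >= 3` and the CI lower bound exceeds 1; PRR positive when
#' `a >= 3`, `PRR >= 2` and `chi2 >= 4`; BCPNN positive when `IC025 > 0`;
#' gamma-Poisson shrinker positive when `a >= 3` and `EBGM05 > 2`.
#'
#' @param ror_min_n,ror_lo_gt ROR case minimum and CI lower-bound threshold.
#' @param prr_min_n,prr_ge,chi2_ge PRR case minimum, PRR and chi2 thresholds.
#' @param ic025_gt BCPNN IC025 threshold.
#' @param mgps_min_n,ebgm05_gt Shrinker case minimum and EBGM05 threshold.
#' @return A `signal_criteria` list.
#' @export
signal_criteria <- function(ror_min_n = 3, ror_lo_gt = 1,
                            prr_min_n = 3, prr_ge = 2, chi2_ge = 4,
                            ic025_gt = 0,
                            mgps_min_n = 3, ebgm05_gt = 2) {
  structure(list(ror_min_n = ror_min_n, ror_lo_gt = ror_lo_gt,
                 prr_min_n = prr_min_n, prr_ge = prr_ge, chi2_ge = chi2_ge,
                 ic025_gt = ic025_gt,
                 mgps_min_n = mgps_min_n, ebgm05_gt = ebgm05_gt),
            class = "signal_criteria")
}

#' Flag per-algorithm and overall signal positivity
#'
#' Takes a tibble of computed statistics (columns `n`, `ror_lo`, `prr`,
#' `chi2`, `ic025`, `ebgm05`; extra columns pass through) and appends the
#' four per-algorithm flags plus `positive_any` (at least one algorithm) and
#' `positive_all` (all four). Missing statistics yield `FALSE` flags.
#'
#' @param stats Tibble of statistics; `n` is the target-with-event cell.
#' @param criteria A [signal_criteria()] list.
#' @return The input tibble with columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps`, `positive_any`, `positive_all` appended.
#' @export
classify_signals <- function(stats, criteria = signal_criteria()) {
  cr <- criteria
  flag <- function(x) !is.na(x) & x
  stats |>
    dplyr::mutate(
      flag_ror = flag(.data$n >= cr$ror_min_n & .data$ror_lo > cr$ror_lo_gt),
      flag_prr = flag(.data$n >= cr$prr_min_n & .data$prr >= cr$prr_ge &
                        .data$chi2 >= cr$chi2_ge),
      flag_bcpnn = flag(.data$ic025 > cr$ic025_gt),
      flag_mgps = flag(.data$n >= cr$mgps_min_n & .data$ebgm05 > cr$ebgm05_gt),
      positive_any = .data$flag_ror | .data$flag_prr | .data$flag_bcpnn |
        .data$flag_mgps,
      positive_all = .data$flag_ror & .data$flag_prr & .data$flag_bcpnn &
        .data$flag_mgps
    )
}

#' Compute all four disproportionality statistics and classify signals
#'
#' The one-stop wrapper: given contingency tables (from
#' [contingency_tables()]), computes ROR with its interval, PRR with the
#' Yates chi-squared, the information component with IC025, and EBGM with
#' EBGM05, then applies the positivity criteria.
#'
#' @param tables Tibble with columns `event`, `a`, `b`, `c`, `d` (a `level`
#'   column passes through).
#' @param mgps Either an [mgps_priors()] object or `NULL` to fit the priors
#'   from `tables` (which then needs at least 50 rows).
#' @param bcpnn A [bcpnn_priors()] object.
#' @param criteria A [signal_criteria()] list.
#' @param seed Seed passed to [fit_mgps_priors()] when `mgps` is `NULL`.
#' @return A tibble, one row per event: the cells, statistics, and flags.
#' @export
disproportionality <- function(tables, mgps = NULL, bcpnn = bcpnn_priors(),
                               criteria = signal_criteria(), seed = 1) {
  if (is.null(mgps)) mgps <- fit_mgps_priors(tables, seed = seed)
  E <- expected_count(tables$a, tables$b, tables$c, tables$d)
  res <- dplyr::bind_cols(
    tables,
    ror_with_ci(tables$a, tables$b, tables$c, tables$d),
    prr_with_chi2(tables$a, tables$b, tables$c, tables$d),
    bcpnn_ic(tables$a, tables$b, tables$c, tables$d, bcpnn),
    ebgm(tables$a, E, mgps)
  )
  res$expected <- E
  res$n <- res$a
  classify_signals(res, criteria)
}
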