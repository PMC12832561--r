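# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: explicit loops and direct formula transcription, so
# agreement is evidence rather than tautology.

oracle_cells <- function(target_events, background_events, event,
                         n_target, n_background) {
  a <- 0L
  for (ev_list in target_events) if (event %in% ev_list) a <- a + 1L
  cc <- 0L
  for (ev_list in background_events) if (event %in% ev_list) cc <- cc + 1L
  c(a = a, b = n_target - a, c = cc, d = n_background - cc)
}

oracle_ror <- function(a, b, c, d) (a * d) / (b * c)

oracle_prr <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))

oracle_yates_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (dev <= n / 2) return(0)
  n * (dev - n / 2)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# quadratic-time Benjamini-Hochberg straight from the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) {
      cand <- m * p[ord[j]] / j
      if (cand < best) best <- cand
    }
    adj[ord[i]] <- min(1, best)
  }
  adj
}

# posterior mean of log2(lambda) under the two-gamma mixture, by numerical
# integration of the posterior density (marginal weights via the negative
# binomial, density integrated on a wide grid)
oracle_ebgm_integration <- function(a, E, priors) {
  marg <- function(shape, rate) {
    stats::dnbinom(a, size = shape, prob = rate / (rate + E))
  }
  w1 <- priors$mix_p * marg(priors$shape1, priors$rate1)
  w2 <- (1 - priors$mix_p) * marg(priors$shape2, priors$rate2)
  dens <- function(x) {
    (w1 * stats::dgamma(x, priors$shape1 + a, rate = priors$rate1 + E) +
       w2 * stats::dgamma(x, priors$shape2 + a, rate = priors$rate2 + E)) /
      (w1 + w2)
  }
  num <- stats::integrate(function(x) log2(x) * dens(x), 0, Inf,
                          rel.tol = 1e-10, subdivisions = 2000L)$value
  2^num
}

oracle_quantile_sorted <- function(x, p) {
  # inverse empirical CDF on the sorted sample, by linear scan
  xs <- sort(x)
  n <- length(xs)
  for (i in seq_len(n)) {
    if (i / n >= p) return(xs[i])
  }
  xs[n]
}
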