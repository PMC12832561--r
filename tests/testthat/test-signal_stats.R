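# The four disproportionality estimators against oracles and frozen values.

test_that("ROR and its Woolf interval match the direct formulas", {
  r <- ror_with_ci(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  expect_equal(r$ror_lo, 5.556, tolerance = 1e-3)
  expect_equal(r$ror_hi, 21.775, tolerance = 1e-3)
  expect_false(r$ror_corrected)

  # symmetric table
  expect_equal(ror_with_ci(5, 5, 5, 5)$ror, 1)
  expect_true(ror_with_ci(5, 5, 5, 5)$ror_lo < 1)
  expect_true(ror_with_ci(5, 5, 5, 5)$ror_hi > 1)

  # zero-cell continuity correction, flagged
  rz <- ror_with_ci(2, 8, 0, 90)
  expect_true(rz$ror_corrected)
  expect_equal(rz$ror, (2.5 * 90.5) / (8.5 * 0.5))

  expect_error(ror_with_ci(0, 0, 5, 5), class = "pv_undefined_result")
})

test_that("PRR and the Yates chi-squared match hand evaluation", {
  p <- prr_with_chi2(10, 90, 100, 9900)
  expect_equal(p$prr, 10)
  expect_equal(p$chi2, oracle_yates_chi2(10, 90, 100, 9900))
  expect_equal(p$chi2, 66.33, tolerance = 1e-3)

  # equal reporting proportions
  expect_equal(prr_with_chi2(5, 45, 20, 180)$prr, 1)
  # floor at zero when |ad-bc| <= N/2
  expect_equal(prr_with_chi2(1, 1, 1, 1)$chi2, 0)
  # infinite PRR is flagged, not thrown
  pinf <- prr_with_chi2(3, 7, 0, 90)
  expect_true(is.infinite(pinf$prr))
  expect_true(pinf$prr_infinite)
})

test_that("ROR/PRR/chi2 agree with brute-force loops on small fixtures", {
  set.seed(11)
  for (rep in 1:20) {
    a <- sample(1:8, 1); b <- sample(1:8, 1)
    c_ <- sample(1:8, 1); d <- sample(1:8, 1)
    expect_equal(ror_with_ci(a, b, c_, d)$ror, oracle_ror(a, b, c_, d))
    pp <- prr_with_chi2(a, b, c_, d)
    expect_equal(pp$prr, oracle_prr(a, b, c_, d))
    expect_equal(pp$chi2, oracle_yates_chi2(a, b, c_, d))
  }
})

test_that("information component matches the closed form and its limits", {
  ic <- bcpnn_ic(10, 90, 100, 9900)
  expect_equal(ic$ic, 2.38, tolerance = 0.005)
  expect_true(ic$ic025 < ic$ic)

  # no observed co-reports cannot give positive IC
  expect_lt(bcpnn_ic(0, 100, 100, 9800)$ic, 0)

  # independence at large N: IC ~ 0 within 0.05
  n <- 1e6; row_ <- 1000; col_ <- 1000
  a <- row_ * col_ / n
  ici <- bcpnn_ic(a, row_ - a, col_ - a, n - row_ - col_ + a)
  expect_lt(abs(ici$ic), 0.05)
})

test_that("EBGM matches numerical posterior integration to 3 decimals", {
  priors <- mgps_priors(shape1 = 0.3, rate1 = 0.2, shape2 = 2, rate2 = 4,
                        mix_p = 0.1)
  grid <- expand.grid(a = c(1, 3, 10, 50, 100), E = c(0.5, 2, 10, 60))
  res <- ebgm(grid$a, grid$E, priors)
  for (i in seq_len(nrow(grid))) {
    expect_equal(res$ebgm[i],
                 oracle_ebgm_integration(grid$a[i], grid$E[i], priors),
                 tolerance = 5e-4)
  }
  # EBGM05 really is the 5th posterior percentile, and sits below EBGM
  expect_true(all(res$ebgm05 < res$ebgm))
  post_cdf <- function(a, E, x) {
    marg1 <- stats::dnbinom(a, size = priors$shape1,
                            prob = priors$rate1 / (priors$rate1 + E))
    marg2 <- stats::dnbinom(a, size = priors$shape2,
                            prob = priors$rate2 / (priors$rate2 + E))
    w1 <- priors$mix_p * marg1; w2 <- (1 - priors$mix_p) * marg2
    (w1 * stats::pgamma(x, priors$shape1 + a, rate = priors$rate1 + E) +
       w2 * stats::pgamma(x, priors$shape2 + a, rate = priors$rate2 + E)) /
      (w1 + w2)
  }
  for (i in c(1, 7, 20)) {
    expect_equal(post_cdf(grid$a[i], grid$E[i], res$ebgm05[i]), 0.05,
                 tolerance = 1e-6)
  }
})

test_that("EBGM shrinks toward the prior and calibrates at the null", {
  diffuse <- mgps_priors(0.1, 0.1, 0.2, 0.1, 0.5)
  e1 <- ebgm(100, 10, diffuse)
  expect_gt(e1$ebgm, 8)
  expect_lt(e1$ebgm, 10)  # pulled below the raw ratio

  informative <- mgps_priors(50, 50, 60, 60, 0.5)  # tight around 1
  e2 <- ebgm(20, 20, informative)
  expect_equal(e2$ebgm, 1, tolerance = 0.1)
})

test_that("prior fitting recovers simple generative regimes", {
  # all-null data (lambda = 1 everywhere): posterior EBGM of every pair
  # stays in [0.5, 2]
  set.seed(21)
  E <- runif(500, 5, 80)
  a <- rpois(500, E)
  pri <- fit_mgps_priors(tibble::tibble(a = a, expected = E), seed = 5)
  post <- ebgm(a, E, pri)
  expect_true(all(post$ebgm > 0.5 & post$ebgm < 2))

  # two-component truth p = 0.1, component means 1 and 10: recovered
  # component means within 25% of the truth
  set.seed(22)
  n_pairs <- 2000
  comp <- runif(n_pairs) < 0.1
  lam <- ifelse(comp, stats::rgamma(n_pairs, 20, rate = 2),
                stats::rgamma(n_pairs, 5, rate = 5))
  E2 <- runif(n_pairs, 2, 50)
  a2 <- rpois(n_pairs, lam * E2)
  pri2 <- fit_mgps_priors(tibble::tibble(a = a2, expected = E2), seed = 5)
  means <- sort(c(pri2$shape1 / pri2$rate1, pri2$shape2 / pri2$rate2))
  expect_equal(means[1], 1, tolerance = 0.25)
  expect_equal(means[2], 10, tolerance = 0.25)

  expect_error(fit_mgps_priors(tibble::tibble(a = 1:10, b = 1, c = 1, d = 1)),
               class = "pv_too_few_tables")
})

test_that("classification reproduces per-algorithm thresholds", {
  # published psychiatric-disorders style row: three of four positive
  stats <- tibble::tibble(
    event = c("psychiatric disorders", "respiratory disorders", "tiny"),
    n = c(983, 898, 2),
    ror_lo = c(2.02, 2.19, 40),
    prr = c(2.03, 2.2, 50), chi2 = c(541.95, 617.68, 30),
    ebgm05 = c(1.92, 2.08, 30), ic025 = c(0.92, 1.04, 3)
  )
  out <- classify_signals(stats)
  expect_equal(out$flag_ror, c(TRUE, TRUE, FALSE))     # n=2 fails case minimum
  expect_equal(out$flag_prr, c(TRUE, TRUE, FALSE))
  expect_equal(out$flag_mgps, c(FALSE, TRUE, FALSE))   # 1.92 <= 2
  expect_equal(out$flag_bcpnn, c(TRUE, TRUE, TRUE))    # ic025 has no case minimum
  expect_equal(out$positive_all, c(FALSE, TRUE, FALSE))
  expect_equal(out$positive_any, c(TRUE, TRUE, TRUE))
})

test_that("all four statistics increase with a at fixed margins", {
  # margins fixed: a + b = 100, a + c = 120, N = 10100
  N <- 10100; row_ <- 100; col_ <- 120
  a_vals <- c(2, 5, 10, 20, 50)
  priors <- mgps_priors(0.5, 0.5, 2, 2, 0.3)
  stats <- lapply(a_vals, function(a) {
    b <- row_ - a; c_ <- col_ - a; d <- N - a - b - c_
    list(ror = ror_with_ci(a, b, c_, d)$ror,
         prr = prr_with_chi2(a, b, c_, d)$prr,
         ic = bcpnn_ic(a, b, c_, d)$ic,
         ebgm = ebgm(a, expected_count(a, b, c_, d), priors)$ebgm)
  })
  for (m in c("ror", "prr", "ic", "ebgm")) {
    vals <- vapply(stats, `[[`, numeric(1), m)
    expect_true(all(diff(vals) > 0), info = m)
  }
})
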