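# Stratified within-drug comparisons, FDR control, co-medication exclusion.

subgroup_fixture <- function() {
  # 100 female reports (30 with headache), 100 male (15 with headache)
  n <- 200
  keys <- as.character(seq_len(n))
  events <- c(rep("headache", 30), rep("nausea", 70),
              rep("headache", 15), rep("nausea", 85))
  store <- tiny_store(as.list(events), keys = keys)
  store$reports$gender <- rep(c("female", "male"), each = 100)
  store
}

test_that("stratified ROR matches the direct Woolf computation", {
  store <- subgroup_fixture()
  res <- subgroup_ror(store, "gender", target = "female", control = "male",
                      events = "headache")
  expect_equal(unlist(res[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(30, 70, 15, 85))
  expect_equal(res$adj_ror, (30 * 85) / (70 * 15), tolerance = 1e-12)
  expect_equal(res$ror_lo, 2.4286 * exp(-1.96 * 0.3550), tolerance = 1e-3)
  expect_equal(res$ror_hi, 2.4286 * exp(1.96 * 0.3550), tolerance = 1e-3)
  expect_true(res$p < 0.05)

  # identical proportions give an odds ratio of 1
  store2 <- subgroup_fixture()
  store2$events$pt <- rep(c(rep("headache", 30), rep("nausea", 70)), 2)
  res2 <- subgroup_ror(store2, "gender", "female", "male", events = "headache")
  expect_equal(res2$adj_ror, 1)

  # female-only event: continuity-corrected with the flag set
  store3 <- subgroup_fixture()
  res3 <- subgroup_ror(store3, "gender", "male", "female", events = "headache")
  expect_equal(unlist(res3[1, c("a", "c")], use.names = FALSE), c(15, 30))
  store3$events$pt[101:115] <- "nausea"  # no male headaches left
  res4 <- subgroup_ror(store3, "gender", "female", "male", events = "headache")
  expect_true(res4$ror_corrected)
  expect_true(is.finite(res4$adj_ror))

  expect_error(subgroup_ror(store, "gender", "female", "nonbinary_absent"),
               class = "pv_empty_stratum")
  expect_error(subgroup_ror(store, "bogus_variable", "x", "y"),
               class = "pv_invalid_stratum")
})

test_that("cells conserve stratum totals and direction is target-over-control", {
  store <- subgroup_fixture()
  res <- subgroup_ror(store, "gender", "female", "male", top_k = 10)
  expect_true(all(res$a + res$b == 100))
  expect_true(all(res$c + res$d == 100))
  # headache enriched among females -> estimate above 1
  expect_gt(res$adj_ror[res$event == "headache"], 1)
  # and the reverse orientation inverts it
  rev <- subgroup_ror(store, "gender", "male", "female", events = "headache")
  expect_lt(rev$adj_ror, 1)
})

test_that("BH adjustment matches its step-up definition", {
  expect_equal(fdr_adjust(c(0.005, 0.01, 0.03, 0.05)),
               c(0.02, 0.02, 0.04, 0.05))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.02, 5)), rep(0.02, 5))

  set.seed(51)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-12))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(fdr_adjust(p[perm]), adj[perm])
    # monotone nondecreasing in sorted-p order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "pv_invalid_p")
  expect_error(fdr_adjust(c(0.5, -0.1)), class = "pv_invalid_p")
})

test_that("co-medication exclusion drops matching reports in any role", {
  store <- tiny_store(list(c("dyspnoea"), c("nausea"), c("rash")))
  store$drugs <- dplyr::bind_rows(
    store$drugs,
    tibble::tibble(report_key = "1", name_raw = "BUDESONIDE/FORMOTEROL",
                   name_normalized = "budesonide/formoterol",
                   ai_normalized = "budesonide\\formoterol fumarate",
                   role = "concomitant", route_raw = NA_character_,
                   start_date = NA_character_)
  )
  out <- exclude_comedications(store)
  expect_equal(sort(out$reports$report_key), c("2", "3"))
  # monotone: output is a subset of input
  expect_true(all(out$reports$report_key %in% store$reports$report_key))
  # no matches leaves the store unchanged
  out2 <- exclude_comedications(store, "tiotropium")
  expect_equal(n_reports(out2), 3)
  expect_error(exclude_comedications(store, character()),
               class = "pv_invalid_query")
})
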