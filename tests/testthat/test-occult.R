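test_that("occult probability has the right boundaries and monotonicity", {
  expect_equal(occult_probability(0, 2.5, 6.21, 0.389), 0.389)
  occ <- occult_probability(0:60, 2.5, 6.21, 0.389)
  expect_true(all(diff(occ) < 0))
  expect_true(all(occ <= 0.389 & occ >= 0))
  expect_lt(occult_probability(500, 2.5, 6.21, 0.389), 1e-4)
  expect_error(occult_probability(3, 2.5, 6.21, 1.2), "prevalence")
})

test_that("minimum adequate yield matches a brute-force scan", {
  expect_equal(min_nodes_for_confidence(2.5, 6.21, 0.389, 0.10), 7)
  expect_message(
    expect_equal(min_nodes_for_confidence(2.5, 6.21, 0.389, 0.5), 0L),
    "m = 0")
  set.seed(77)
  for (i in 1:20) {
    a <- runif(1, 0.3, 8); b <- runif(1, 0.5, 15)
    prev <- runif(1, 0.1, 0.7); thr <- runif(1, 0.02, prev * 0.9)
    scan <- which(occult_probability(1:100, a, b, prev) <= thr)[1]
    if (is.na(scan)) {
      # a heavy-tailed law can stay above the threshold for every m <= 100
      expect_error(min_nodes_for_confidence(a, b, prev, thr, m_max = 100),
                   "does not reach")
    } else {
      expect_equal(min_nodes_for_confidence(a, b, prev, thr, m_max = 100),
                   scan)
    }
  }
})

test_that("false-negative counts follow the odds form of the miss probability", {
  # m = 1 stratum with 10 observed positives: fn = P0 * 10 / (1 - P0)
  coh <- make_cohort(rep(1, 30), c(rep(1, 10), rep(0, 20)))
  prof <- occult_risk_profile(coh, 2.50, 6.21, prevalence = 0.389, m_max = 5)
  p0 <- 6.21 / 8.71
  expect_equal(prof$fn_count[1], p0 * 10 / (1 - p0), tolerance = 1e-12)
  expect_equal(round(prof$fn_count[1], 2), 24.84)
  # strata with no observed positives contribute nothing
  expect_equal(prof$fn_count[2:5], rep(0, 4))
  # fixed #TP, increasing m: fewer implied false negatives
  fn <- bb_prob_all_negative(1:20, 2.5, 6.21) * 10 /
    (1 - bb_prob_all_negative(1:20, 2.5, 6.21))
  expect_true(all(diff(fn) < 0))
})

test_that("risk profile is internally consistent", {
  coh <- simulate_nodal_cohort(3000, 0.389, 2.5, 6.21, seed = 12)
  fit <- fit_bb_mle(coh, truncated = TRUE)
  prof <- occult_risk_profile(coh, fit, m_max = 30)
  expect_equal(nrow(prof), 30)
  expect_equal(prof$detection_prob, 1 - prof$p_all_negative)
  expect_true(all(diff(prof$p_all_negative) < 0))
  expect_true(all(diff(prof$occult_prob) < 0))
  expect_lte(max(prof$occult_prob), attr(prof, "prevalence"))
})

test_that("corrected prevalence recovers the generative truth", {
  coh <- simulate_nodal_cohort(100000, prevalence = 0.389, alpha = 2.5,
                               beta = 6.21, seed = 31)
  est <- corrected_prevalence(coh, 2.5, 6.21)
  expect_lt(abs(est$corrected_prevalence - 0.389), 0.01)
  # observed prevalence is materially lower than the corrected one
  expect_lt(est$observed_prevalence, est$corrected_prevalence - 0.05)
  expect_equal(est$observed_prevalence,
               mean(coh$nodes_positive >= 1), tolerance = 1e-12)
})

test_that("corrected prevalence degenerates correctly", {
  all_pos <- make_cohort(rep(6, 40), rep(2, 40))
  est <- suppressWarnings(corrected_prevalence(all_pos, 2.5, 6.21))
  expect_equal(est$observed_prevalence, 1)
  expect_equal(est$corrected_prevalence, 1)  # capped
  # observed prevalence is the simple count ratio
  coh <- make_cohort(rep(8, 5399), c(rep(1, 1664), rep(0, 5399 - 1664)))
  est2 <- corrected_prevalence(coh, 2.5, 6.21)
  expect_equal(est2$observed_prevalence, 1664 / 5399, tolerance = 1e-12)
  expect_equal(round(est2$observed_prevalence, 3), 0.308)
  expect_gte(est2$corrected_prevalence, est2$observed_prevalence)
  expect_error(corrected_prevalence(make_cohort(integer(), integer()),
                                    2.5, 6.21), "empty")
})
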