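test_that("nodal simulation is deterministic given config and seed", {
  a <- simulate_nodal_cohort(500, 0.4, 2.5, 6.21, seed = 17)
  b <- simulate_nodal_cohort(500, 0.4, 2.5, 6.21, seed = 17)
  expect_identical(a, b)
  c <- simulate_nodal_cohort(500, 0.4, 2.5, 6.21, seed = 18)
  expect_false(identical(a, c))
  expect_error(simulate_nodal_cohort(10, 0.4, 2.5, 6.21), "seed")
})

test_that("degenerate prevalence behaves as specified", {
  none <- simulate_nodal_cohort(200, 0, 2.5, 6.21, seed = 1)
  expect_true(all(none$nodes_positive == 0))
  expect_true(all(!none$.true_positive))
  # prevalence 1, single node: observed positive fraction ~ alpha/(alpha+beta)
  one <- simulate_nodal_cohort(40000, 1, 2.5, 6.21,
                               yield = yield_uniform(1, 1), seed = 2)
  expect_equal(mean(one$nodes_positive >= 1), 2.5 / 8.71, tolerance = 0.02)
})

test_that("observed positive fraction converges to pi * E[detection]", {
  coh <- simulate_nodal_cohort(100000, 0.389, 2.5, 6.21,
                               yield = yield_uniform(2, 15), seed = 4)
  expected <- 0.389 * mean(bb_detection_prob(2:15, 2.5, 6.21))
  expect_equal(mean(coh$nodes_positive >= 1), expected, tolerance = 0.015)
  # and is materially lower than the true prevalence
  expect_lt(mean(coh$nodes_positive >= 1), 0.389)
})

test_that("default yield law reproduces the target median and IQR", {
  law <- yield_nbinom()
  set.seed(9)
  m <- law$sample(200000)
  expect_equal(unname(quantile(m, c(0.25, 0.5, 0.75))), c(4, 7, 11))
  expect_true(all(m >= 1))
  emp <- yield_empirical(c(3, 3, 7))
  set.seed(1)
  expect_true(all(emp$sample(50) %in% c(3, 7)))
  expect_error(yield_uniform(0, 5))
})

test_that("uncensored covariate-free survival follows the exponential law", {
  lam <- 0.01
  coh <- simulate_survival_cohort(20000, baseline_hazard = lam,
                                  effects = list(), horizon_months = 1e6,
                                  entry_spread_months = 0, seed = 6)
  expect_true(all(coh$vital_status == "dead"))
  km <- km_estimate(coh)
  for (t in c(30, 60, 120)) {
    expect_equal(km_survival_at(km, t), exp(-lam * t), tolerance = 0.02)
  }
})

test_that("a log(2) covariate effect is recovered by a Cox fit", {
  coh <- simulate_survival_cohort(15000, baseline_hazard = 0.002,
                                  effects = list(rai = log(2)), seed = 44)
  fit <- survival::coxph(
    survival::Surv(follow_up_months, vital_status == "dead") ~ rai,
    data = coh)
  expect_equal(unname(exp(coef(fit))), 2, tolerance = 0.15)
})

test_that("a zero horizon censors everyone at time zero", {
  coh <- simulate_survival_cohort(50, horizon_months = 0,
                                  entry_spread_months = 0, seed = 3)
  expect_true(all(coh$follow_up_months == 0))
  expect_true(all(coh$vital_status == "alive"))
})

test_that("survival simulation is deterministic and validates effects", {
  a <- simulate_survival_cohort(100, seed = 5)
  b <- simulate_survival_cohort(100, seed = 5)
  expect_identical(a, b)
  expect_error(simulate_survival_cohort(10, effects = list(bogus = 1),
                                        seed = 1), "unknown covariate")
})
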