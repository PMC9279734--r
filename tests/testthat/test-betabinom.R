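test_that("pmf matches closed forms and normalizes", {
  # x = 0, m = 1 reduces to beta / (alpha + beta)
  expect_equal(bb_pmf(0, 1, 2.50, 6.21), 6.21 / 8.71, tolerance = 1e-12)
  # empty examination is certain to find nothing
  expect_equal(bb_pmf(0, 0, 2.50, 6.21), 1)
  # normalization over the support, across a parameter sweep
  for (ab in list(c(0.1, 0.1), c(2.5, 6.21), c(50, 0.3), c(17, 42))) {
    for (m in c(1, 5, 10, 50)) {
      expect_equal(sum(bb_pmf(0:m, m, ab[1], ab[2])), 1, tolerance = 1e-10)
    }
  }
})

test_that("pmf rejects invalid inputs", {
  expect_error(bb_pmf(3, 2, 2.5, 6.21), "0 <= x <= m")
  expect_error(bb_pmf(0, 1, -1, 6.21), "positive")
  expect_error(bb_pmf(0, 1, 2.5, 0), "positive")
  expect_error(bb_pmf(0, -1, 2.5, 6.21), "non-negative")
})

test_that("all-negative probability equals the telescoping product", {
  expect_equal(bb_prob_all_negative(1, 2.50, 6.21), 6.21 / 8.71,
               tolerance = 1e-12)
  expect_equal(bb_prob_all_negative(0, 2.50, 6.21), 1)
  # frozen from the product form evaluated term by term
  expect_equal(bb_prob_all_negative(7, 2.50, 6.21), p0_product(7, 2.50, 6.21),
               tolerance = 1e-12)
  expect_equal(round(bb_prob_all_negative(7, 2.50, 6.21), 4), 0.1740)
  for (ab in list(c(0.5, 3), c(2.5, 6.21), c(10, 1))) {
    expect_equal(bb_prob_all_negative(0:20, ab[1], ab[2]),
                 p0_product(0:20, ab[1], ab[2]), tolerance = 1e-12)
  }
})

test_that("all-negative probability decreases and detection increases in m", {
  p0 <- bb_prob_all_negative(0:50, 2.5, 6.21)
  expect_true(all(diff(p0) < 0))
  det <- bb_detection_prob(0:50, 2.5, 6.21)
  expect_equal(det[1], 0)
  expect_equal(det[2], 2.5 / 8.71, tolerance = 1e-12)
  expect_true(all(diff(det) > 0))
})

test_that("log-likelihood matches direct sums, plain and truncated", {
  one <- make_cohort(1, 0)
  expect_equal(bb_loglik(one, 2.5, 6.21), log(6.21 / 8.71), tolerance = 1e-12)
  # only one outcome is possible for a truncated (x=1, m=1) record
  expect_equal(bb_loglik(make_cohort(1, 1), 2.5, 6.21, truncated = TRUE), 0,
               tolerance = 1e-12)
  # aggregated cells agree with the per-record sum
  set.seed(4)
  coh <- make_cohort(sample(2:9, 60, TRUE), 0)
  coh$nodes_positive <- as.integer(pmin(rpois(60, 1), coh$nodes_examined))
  direct <- sum(log(bb_pmf(coh$nodes_positive, coh$nodes_examined, 1.7, 4.2)))
  expect_equal(bb_loglik(coh, 1.7, 4.2), direct, tolerance = 1e-10)
  expect_true(is.finite(bb_loglik(coh, 0.01, 90)))
  expect_error(bb_loglik(coh, 2.5, 6.21, truncated = TRUE), "nodes_positive")
})

test_that("cohort validation enforces the count constraints", {
  expect_error(validate_nodal_cohort(data.frame(nodes_examined = 1)),
               "nodes_positive")
  expect_error(validate_nodal_cohort(make_cohort(2, 3)), "0 <= nodes_positive")
  expect_error(validate_nodal_cohort(make_cohort(0, 0)), ">= 1")
  expect_s3_class(validate_nodal_cohort(make_cohort(3, 1)), "tbl_df")
})
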