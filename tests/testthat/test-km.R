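test_that("three-patient product-limit fixture matches hand values", {
  # deaths at 2 and 5, censoring at 4:
  # S(2) = 2/3; censoring leaves 1 at risk; S(5) = 2/3 * 0 = 0
  rec <- make_survival_records(3, follow_up = c(2, 4, 5),
                               status = c("dead", "alive", "dead"))
  km <- km_estimate(rec)
  expect_equal(km_survival_at(km, 2), 2 / 3, tolerance = 1e-12)
  expect_equal(km_survival_at(km, 4.5), 2 / 3, tolerance = 1e-12)
  expect_equal(km_survival_at(km, 5), 0, tolerance = 1e-12)
  expect_equal(km_survival_at(km, 1), 1)
})

test_that("without censoring the curve is the empirical survival function", {
  set.seed(10)
  t_obs <- round(rexp(300, 0.02), 2)
  rec <- make_survival_records(300, follow_up = t_obs,
                               status = rep("dead", 300))
  km <- km_estimate(rec)
  for (t in c(10, 25, 60, 100)) {
    expect_equal(km_survival_at(km, t), mean(t_obs > t), tolerance = 1e-12)
  }
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
})

test_that("survival accessors handle short follow-up explicitly", {
  rec <- make_survival_records(10, follow_up = runif(10, 5, 50),
                               status = rep("dead", 10))
  km <- km_estimate(rec)
  expect_warning(r <- os_rates(km), "unavailable")
  expect_true(is.na(r$os_5yr) && is.na(r$os_10yr))
  expect_error(km_estimate(make_survival_records(2, c(0, 0),
                                                 c("alive", "alive"))),
               "zero")
})

test_that("log-rank is zero on identical groups and matches a hand table", {
  base <- make_survival_records(20, follow_up = seq(2, 40, 2),
                                status = rep(c("dead", "alive"), 10))
  both <- dplyr::bind_rows(dplyr::mutate(base, g = "A"),
                           dplyr::mutate(base, g = "B"))
  res <- log_rank_test(both, group = "g")
  expect_equal(res$chi_square, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1)

  # small two-group fixture: independent O-E / hypergeometric-variance sums
  recA <- make_survival_records(4, c(1, 3, 5, 7), rep("dead", 4))
  recB <- make_survival_records(4, c(2, 4, 5, 9),
                                c("dead", "dead", "alive", "dead"))
  both2 <- dplyr::bind_rows(dplyr::mutate(recA, g = "A"),
                            dplyr::mutate(recB, g = "B"))
  d <- data.frame(time = both2$follow_up_months,
                  event = both2$vital_status == "dead",
                  a = both2$g == "A")
  times <- sort(unique(d$time[d$event]))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- d$time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & d$a)
    dd <- sum(d$time == t & d$event)
    d_a <- sum(d$time == t & d$event & d$a)
    o_minus_e <- o_minus_e + d_a - dd * n_a / n
    if (n > 1) v <- v + dd * (n_a / n) * (1 - n_a / n) * (n - dd) / (n - 1)
  }
  expected_chi <- o_minus_e^2 / v
  res2 <- log_rank_test(both2, group = "g")
  expect_equal(res2$chi_square, expected_chi, tolerance = 1e-10)
  # invariant to swapping the group labels
  both3 <- dplyr::mutate(both2, g = ifelse(g == "A", "B", "A"))
  expect_equal(log_rank_test(both3, group = "g")$chi_square,
               res2$chi_square, tolerance = 1e-12)
})

test_that("log-rank type-I error is near nominal under the null", {
  n_rep <- 300
  p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(6000 + i)
    rec <- make_survival_records(100, follow_up = rexp(100, 0.02),
                                 status = ifelse(runif(100) < 0.7, "dead",
                                                 "alive"))
    rec$g <- rep(c("A", "B"), 50)
    p[i] <- log_rank_test(rec, group = "g")$p_value
  }
  expect_lt(mean(p < 0.05), 0.10)
  expect_gt(mean(p < 0.05), 0.005)
})

test_that("log-rank needs exactly two non-empty groups", {
  rec <- make_survival_records(5, 1:5, rep("dead", 5))
  rec$g <- "A"
  expect_error(log_rank_test(rec, group = "g"), "2 non-empty groups")
})
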