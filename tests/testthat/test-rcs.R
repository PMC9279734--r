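test_that("spline columns are linear beyond the boundary knots", {
  kn <- c(1, 2, 9)
  x <- sort(c(seq(-5, 20, 0.25), kn))
  B <- rcs_basis(x, kn)
  expect_equal(ncol(B), 2)  # k - 1 columns for k = 3
  for (j in 2:ncol(B)) {
    for (side in list(x < kn[1], x > kn[3])) {
      xi <- x[side]; yi <- B[side, j]
      if (length(xi) > 2) {
        second_diff <- diff(diff(yi) / diff(xi))
        expect_lt(max(abs(second_diff)), 1e-8)
      }
    }
  }
  expect_error(rcs_basis(x, c(1, 1, 9)), "distinct")
  expect_error(rcs_basis(x, c(1, 9)), "3 knots")
})

test_that("basis matches an independently coded truncated-power form", {
  kn <- c(1, 2, 9)
  x <- seq(0, 15, 0.5)
  B <- rcs_basis(x, kn)
  # independent oracle: literal truncated-power expression
  tp <- function(u) ifelse(u > 0, u^3, 0)
  j <- 1
  oracle <- (tp(x - kn[j]) -
               tp(x - kn[2]) * (kn[3] - kn[j]) / (kn[3] - kn[2]) +
               tp(x - kn[3]) * (kn[2] - kn[j]) / (kn[3] - kn[2])) /
    (kn[3] - kn[1])^2
  expect_equal(unname(B[, 2]), oracle, tolerance = 1e-12)
  expect_equal(unname(B[, 1]), x)
  # 5 knots: k - 1 = 4 columns, same oracle for each nonlinear column
  kn5 <- c(1, 3, 5, 8, 12)
  B5 <- rcs_basis(x, kn5)
  expect_equal(ncol(B5), 4)
  for (j in 1:3) {
    o5 <- (tp(x - kn5[j]) -
             tp(x - kn5[4]) * (kn5[5] - kn5[j]) / (kn5[5] - kn5[4]) +
             tp(x - kn5[5]) * (kn5[4] - kn5[j]) / (kn5[5] - kn5[4])) /
      (kn5[5] - kn5[1])^2
    expect_equal(unname(B5[, j + 1]), o5, tolerance = 1e-12)
  }
})

test_that("percentile placement follows the fixed tables", {
  x <- 0:100
  expect_equal(rcs_knots(x, 3), c(10, 50, 90))
  expect_equal(rcs_knots(x, 4), c(5, 35, 65, 95))
  expect_equal(rcs_knots(x, 5), c(5, 27.5, 50, 72.5, 95))
  expect_error(rcs_knots(rep(1, 50), 3), "not distinct")
  expect_error(rcs_knots(x, 6), "3, 4 or 5")
})

simulate_rcs_cohort <- function(n, seed, beta_m = 0) {
  simulate_survival_cohort(
    n, baseline_hazard = 0.004,
    effects = if (beta_m == 0) list() else list(nodes_examined = beta_m),
    nodal = list(yield = yield_uniform(1, 15)), seed = seed)
}

test_that("AIC identity holds and a linear truth selects 3 knots", {
  coh <- simulate_rcs_cohort(6000, seed = 123, beta_m = 0.05)
  sel <- select_knots_by_aic(coh, spline_vars = "nodes_examined",
                             covariates = "sex")
  for (i in seq_len(nrow(sel$aic_table))) {
    k <- sel$aic_table$n_knots[i]
    # AIC = -2 logPL + 2 * (#spline terms + #covariate terms)
    expect_equal(sel$aic_table$AIC[i],
                 -2 * sel$aic_table$logLik[i] + 2 * ((k - 1) + 1),
                 tolerance = 1e-10)
  }
  expect_equal(sel$n_knots, 3)
  expect_equal(sel$fit$AIC, min(sel$aic_table$AIC))
})

test_that("degenerate main variable drops every candidate", {
  coh <- simulate_rcs_cohort(300, seed = 9)
  coh$nodes_examined <- rep(c(1L, 2L), 150)
  expect_error(
    suppressWarnings(select_knots_by_aic(coh, spline_vars = "nodes_examined",
                                         covariates = "sex")),
    "no candidate")
})

test_that("hazard-ratio curve is anchored at the reference and recovers effects", {
  coh <- simulate_rcs_cohort(8000, seed = 321, beta_m = log(1.10))
  fit <- fit_cox_rcs(coh, spline_vars = "nodes_examined",
                     covariates = c("sex", "age_years"), ref = 7)
  hr <- hr_curve(fit, at = c(7, 2, 12))
  expect_equal(hr$hr[1], 1)
  expect_equal(hr$conf_low[1], 1)
  # true log-linear effect: HR(12 vs 7) = 1.1^5, HR(2 vs 7) = 1.1^-5
  expect_equal(hr$hr[3], 1.1^5, tolerance = 0.25)
  expect_equal(hr$hr[2], 1.1^-5, tolerance = 0.25)
  # spline CI covers the linear-truth curve
  expect_true(hr$conf_low[3] < 1.1^5 && hr$conf_high[3] > 1.1^5 * 0.8)
})

test_that("a binary covariate with true HR 2 is recovered in the full model", {
  coh <- simulate_survival_cohort(12000, baseline_hazard = 0.003,
                                  effects = list(rai = log(2)), seed = 61)
  fit <- fit_cox_rcs(coh)
  td <- generics::tidy(fit)
  est <- exp(td$estimate[td$term == "raiTRUE"])
  expect_equal(est, 2, tolerance = 0.15)
  # the null main variable shows no association
  expect_gt(fit$overall$p_value, 0.01)
  gl <- generics::glance(fit)
  expect_equal(gl$AIC, -2 * gl$logLik + 2 * gl$n_parameters,
               tolerance = 1e-10)
})

test_that("incomplete cases are dropped with a count", {
  coh <- simulate_rcs_cohort(500, seed = 8)
  coh$age_years[1:25] <- NA
  expect_message(fit <- fit_cox_rcs(coh, covariates = c("sex", "age_years"),
                                    spline_vars = "nodes_examined"),
                 "25")
  expect_equal(fit$n_dropped, 25)
  expect_equal(fit$n, 475)
})

test_that("likelihood-ratio variant of the overall test is available", {
  coh <- simulate_rcs_cohort(3000, seed = 14)
  fw <- fit_cox_rcs(coh, spline_vars = "nodes_examined", covariates = "sex")
  fl <- fit_cox_rcs(coh, spline_vars = "nodes_examined", covariates = "sex",
                    overall_test = "lr")
  expect_match(fl$overall$method, "likelihood ratio")
  expect_equal(fw$overall$df, fl$overall$df)
  expect_lt(abs(fw$overall$statistic - fl$overall$statistic), 3)
})
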