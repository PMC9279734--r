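#' Fit the beta-binomial positivity law by maximum likelihood
#'
#' Estimates the latent Beta(alpha, beta) law of per-node positivity from
#' per-patient counts of examined and positive nodes. The default fitting
#' subset is node-positive patients with at least two nodes examined, the
#' substrate on which the observed fraction of positive nodes is informative
#' about the latent law; a zero-truncated likelihood (conditioning on at
#' least one observed positive node) is available via `truncated`.
#'
#' Optimization is unconstrained quasi-Newton (L-BFGS-B) on
#' (log alpha, log beta) from (0, 0), with the parameters capped at
#' `max_param` to detect a divergent likelihood (which arises when the
#' observed positive fractions are consistent with a point mass, so the Beta
#' law degenerates). Standard errors come from the numerically differentiated
#' Hessian on the log scale, delta-transformed back.
#'
#' @param cohort Data frame with `nodes_examined`, `nodes_positive`.
#' @param truncated Logical; use the zero-truncated likelihood?
#' @param min_examined Minimum node yield for a record to enter the fit
#'   (default 2).
#' @param positive_only Keep only records with at least one positive node
#'   (default `TRUE`).
#' @param start Numeric length-2 starting value for (alpha, beta).
#' @param max_param Cap on either shape parameter; reaching it triggers a
#'   bounded-parameter warning.
#'
#' @return An object of class `bb_fit`: a list with elements `alpha`, `beta`,
#'   `logLik`, `n`, `truncated`, `convergence`, `se_alpha`, `se_beta`,
#'   `vcov_log` (covariance of the log-scale estimates) and `cells`.
#' @seealso [bb_bootstrap()] for percentile confidence intervals,
#'   [bb_gof()] for goodness of fit.
#' @examples
#' set.seed(1)
#' coh <- simulate_nodal_cohort(2000, prevalence = 1, alpha = 2.5, beta = 6.21,
#'                              yield = yield_uniform(2, 15), seed = 1)
#' fit_bb_mle(coh, truncated = TRUE)
#' @export
fit_bb_mle <- function(cohort, truncated = FALSE, min_examined = 2,
                       positive_only = TRUE, start = c(1, 1),
                       max_param = 1e6) {
  cohort <- validate_nodal_cohort(cohort)
  sub <- dplyr::filter(cohort, .data$nodes_examined >= min_examined)
  if (positive_only) sub <- dplyr::filter(sub, .data$nodes_positive >= 1)
  if (nrow(sub) == 0L) {
    stop("fitting subset is empty (min_examined = ", min_examined,
         ", positive_only = ", positive_only, ")", call. = FALSE)
  }
  if (truncated && any(sub$nodes_positive == 0)) {
    stop("truncated fit requires nodes_positive >= 1 in the fitting subset",
         call. = FALSE)
  }
  cells <- nodal_cells(sub)

  negll <- function(theta) {
    -bb_loglik_cells(cells, exp(theta[1]), exp(theta[2]), truncated = truncated)
  }
  lbfgsb <- function(par0) {
    stats::optim(par0, negll, method = "L-BFGS-B",
                 lower = log(1e-8), upper = log(max_param),
                 control = list(maxit = 500, factr = 1e7))
  }
  opt <- lbfgsb(log(start))
  if (opt$convergence != 0) {
    # flat ridges can abort the line search; restart via a simplex pass
    nm <- stats::optim(log(start), negll, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    opt <- lbfgsb(pmin(pmax(nm$par, log(1e-8)), log(max_param)))
    if (opt$convergence != 0) {
      stop("beta-binomial fit did not converge (code ", opt$convergence,
           "): ", opt$message, call. = FALSE)
    }
  }
  opt$hessian <- tryCatch(stats::optimHess(opt$par, negll),
                          error = function(e) matrix(NA_real_, 2, 2))
  at_bound <- any(opt$par > log(max_param) - 1e-6)
  if (at_bound) {
    warning("parameter bound (", format(max_param), ") reached; the likelihood ",
            "appears unbounded (degenerate positive-fraction distribution)",
            call. = FALSE)
  }

  vcov_log <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  est <- exp(opt$par)
  se <- sqrt(pmax(diag(vcov_log), 0)) * est  # delta method: Var(exp(t)) ~ exp(t)^2 Var(t)

  structure(
    list(alpha = est[1], beta = est[2],
         se_alpha = se[1], se_beta = se[2],
         vcov_log = vcov_log,
         logLik = -opt$value, n = nrow(sub),
         truncated = truncated, min_examined = min_examined,
         positive_only = positive_only,
         convergence = opt$convergence, at_bound = at_bound,
         cells = cells),
    class = "bb_fit"
  )
}

#' @export
print.bb_fit <- function(x, digits = 4, ...) {
  cat("Beta-binomial nodal positivity fit",
      if (x$truncated) "(zero-truncated)" else "", "\n")
  cat(sprintf("  alpha = %.*g (SE %.*g)\n", digits, x$alpha, digits, x$se_alpha))
  cat(sprintf("  beta  = %.*g (SE %.*g)\n", digits, x$beta, digits, x$se_beta))
  cat(sprintf("  log-likelihood = %.*g on %d patients\n", digits, x$logLik, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a beta-binomial fit
#'
#' @param x A `bb_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per shape parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.bb_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = c(x$se_alpha, x$se_beta)
  )
}

#' One-row summary of a beta-binomial fit
#'
#' @param x A `bb_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `beta`, `logLik`, `AIC`, `nobs`,
#'   `truncated`, `converged`.
#' @export
glance.bb_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, beta = x$beta,
    logLik = x$logLik, AIC = -2 * x$logLik + 2 * 2,
    nobs = x$n, truncated = x$truncated,
    converged = x$convergence == 0 && !x$at_bound
  )
}

#' Pearson chi-square goodness of fit of the beta-binomial law
#'
#' Compares observed counts of positive nodes with their fitted expectation
#' within each node-yield stratum. Cells are (m, x) pairs; within each `m`
#' stratum adjacent x-cells are pooled until the expected count reaches
#' `min_expected`, and any still-small cells are pooled across strata into
#' one remainder cell. Degrees of freedom are cells - 1 - 2 (two estimated
#' shape parameters).
#'
#' @param cohort Data frame with `nodes_examined`, `nodes_positive`; should be
#'   the same subset the parameters were fitted on.
#' @param alpha,beta Fitted shape parameters (or a `bb_fit` as `alpha`).
#' @param truncated Logical; expected frequencies conditioned on x >= 1
#'   (use when the fit was zero-truncated / restricted to node-positive
#'   patients).
#' @param min_expected Minimum expected count per pooled cell (default 5).
#'
#' @return A `bb_gof` object (also `htest`-like list) with `statistic`, `df`,
#'   `p.value` and the pooled `table` of observed vs expected counts.
#' @export
bb_gof <- function(cohort, alpha, beta = NULL, truncated = TRUE,
                   min_expected = 5) {
  if (inherits(alpha, "bb_fit")) {
    fit <- alpha
    beta <- fit$beta
    alpha <- fit$alpha
  }
  cohort <- validate_nodal_cohort(cohort)
  if (truncated && any(cohort$nodes_positive == 0)) {
    stop("truncated expected frequencies require nodes_positive >= 1; ",
         "filter the cohort or set truncated = FALSE", call. = FALSE)
  }

  tab <- cohort |>
    dplyr::group_by(m = .data$nodes_examined) |>
    dplyr::summarise(obs = list(tabulate(.data$nodes_positive + 1L, nbins = .data$m[1] + 1L)),
                     n = dplyr::n(), .groups = "drop")

  cells <- purrr::pmap_dfr(tab, function(m, obs, n) {
    x <- 0:m
    p <- bb_pmf(x, m, alpha, beta)
    if (truncated) {
      keep <- x >= 1
      x <- x[keep]; obs <- obs[keep]; p <- p[keep] / sum(p[keep])
    }
    tibble::tibble(m = m, x = x, observed = obs, expected = n * p)
  })

  pooled <- pool_gof_cells(cells, min_expected)
  k <- nrow(pooled)
  if (k < 3) stop("fewer than 3 cells after pooling; goodness-of-fit test ",
                  "is not defined", call. = FALSE)
  df <- k - 1 - 2
  if (df < 1) stop("too few pooled cells (", k, ") for a chi-square test ",
                   "with 2 estimated parameters", call. = FALSE)
  stat <- sum((pooled$observed - pooled$expected)^2 / pooled$expected)
  structure(
    list(statistic = c("X-squared" = stat), parameter = c(df = df),
         p.value = stats::pchisq(stat, df, lower.tail = FALSE),
         method = "Pearson chi-square goodness of fit (beta-binomial)",
         table = pooled),
    class = c("bb_gof", "htest")
  )
}

# greedy within-stratum pooling; residual small cells pooled across strata
pool_gof_cells <- function(cells, min_expected) {
  pooled <- cells |>
    dplyr::group_by(.data$m) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$x)
      grp <- integer(nrow(d)); g <- 1L; acc <- 0
      for (i in seq_len(nrow(d))) {
        grp[i] <- g
        acc <- acc + d$expected[i]
        if (acc >= min_expected && i < nrow(d)) { g <- g + 1L; acc <- 0 }
      }
      # a trailing underweight group merges backwards
      if (acc < min_expected && g > 1L) grp[grp == g] <- g - 1L
      d$cell <- grp
      d |>
        dplyr::group_by(.data$cell) |>
        dplyr::summarise(observed = sum(.data$observed),
                         expected = sum(.data$expected),
                         x_lo = min(.data$x), x_hi = max(.data$x),
                         .groups = "drop")
    }) |>
    dplyr::ungroup()

  small <- pooled$expected < min_expected
  if (sum(small) > 1) {
    rest <- pooled[!small, ]
    merged <- tibble::tibble(m = NA_integer_, cell = 0L,
                             observed = sum(pooled$observed[small]),
                             expected = sum(pooled$expected[small]),
                             x_lo = NA_integer_, x_hi = NA_integer_)
    pooled <- dplyr::bind_rows(rest, merged)
  }
  pooled
}
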