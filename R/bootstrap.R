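#' Percentile bootstrap over patients
#'
#' Resamples the cohort's patients with replacement, recomputes a statistic
#' per replicate (refitting the beta-binomial parameters when the statistic
#' depends on them), and returns the 2.5 / 97.5 percentile confidence
#' interval. Replicates whose fit fails are dropped and counted; more than
#' `max_fail_frac` failures aborts as an unstable fit.
#'
#' @param cohort Data frame with `nodes_examined`, `nodes_positive`.
#' @param statistic Either one of `"alpha"`, `"beta"`,
#'   `"corrected_prevalence"`, `"occult_probability"`, or a function
#'   `cohort -> single number`.
#' @param n_replicates Number of bootstrap resamples (default 2000).
#' @param seed Integer seed (required; recorded in the result).
#' @param m Node yield at which `"occult_probability"` is evaluated.
#' @param conf_level Confidence level for the percentile interval
#'   (default 0.95).
#' @param max_fail_frac Maximum tolerated fraction of failed replicates
#'   (default 0.1).
#' @param ... Passed to [fit_bb_mle()] for the named parameter statistics
#'   (e.g. `truncated = TRUE`).
#'
#' @return A `bb_boot` object: list with `point_estimate`, `ci_lower`,
#'   `ci_upper`, `replicate_values`, `n_replicates`, `n_failed`, `seed`,
#'   `statistic`.
#' @examples
#' coh <- simulate_nodal_cohort(400, 1, 2.5, 6.21,
#'                              yield = yield_uniform(2, 15), seed = 3)
#' coh <- coh[coh$nodes_positive >= 1, ]
#' bb_bootstrap(coh, "alpha", n_replicates = 50, seed = 9, truncated = TRUE)
#' @export
bb_bootstrap <- function(cohort, statistic, n_replicates = 2000, seed,
                         m = NULL, conf_level = 0.95, max_fail_frac = 0.1,
                         ...) {
  cohort <- validate_nodal_cohort(cohort)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_replicates >= 1)

  stat_fun <- resolve_statistic(statistic, m, ...)
  label <- if (is.character(statistic)) statistic else "custom"
  point <- stat_fun(cohort)

  n <- nrow(cohort)
  reps <- with_preserved_rng(seed, {
    purrr::map_dbl(seq_len(n_replicates), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(stat_fun(cohort[idx, , drop = FALSE]),
               error = function(e) NA_real_,
               warning = function(w) NA_real_)
    })
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > max_fail_frac * n_replicates) {
    stop(n_failed, "/", n_replicates, " bootstrap replicates failed; ",
         "the fit is unstable on this cohort", call. = FALSE)
  }
  ok <- reps[!is.na(reps)]
  a <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(ok, c(a, 1 - a), type = 7))
  structure(
    list(point_estimate = point, ci_lower = ci[1], ci_upper = ci[2],
         replicate_values = ok, n_replicates = n_replicates,
         n_failed = n_failed, seed = seed, conf_level = conf_level,
         statistic = label),
    class = "bb_boot"
  )
}

resolve_statistic <- function(statistic, m, ...) {
  if (is.function(statistic)) return(statistic)
  if (!is.character(statistic) || length(statistic) != 1) {
    stop("`statistic` must be a function or a single name", call. = FALSE)
  }
  fit_args <- list(...)
  refit <- function(coh) do.call(fit_bb_mle, c(list(coh), fit_args))
  switch(statistic,
    alpha = function(coh) refit(coh)$alpha,
    beta = function(coh) refit(coh)$beta,
    corrected_prevalence = function(coh) {
      f <- refit(coh)
      corrected_prevalence(coh, f$alpha, f$beta)$corrected_prevalence
    },
    occult_probability = {
      if (is.null(m)) stop("`m` is required for statistic = \"occult_probability\"",
                           call. = FALSE)
      function(coh) {
        f <- refit(coh)
        prev <- corrected_prevalence(coh, f$alpha, f$beta)$corrected_prevalence
        occult_probability(m, f$alpha, f$beta, prev)
      }
    },
    stop("unknown statistic: ", statistic, call. = FALSE)
  )
}

#' @export
print.bb_boot <- function(x, digits = 4, ...) {
  cat(sprintf("Percentile bootstrap (%d replicates, %d failed, seed %d)\n",
              x$n_replicates, x$n_failed, x$seed))
  cat(sprintf("  %s = %.*g [%.*g, %.*g] (%g%% CI)\n", x$statistic,
              digits, x$point_estimate, digits, x$ci_lower,
              digits, x$ci_upper, 100 * x$conf_level))
  invisible(x)
}

#' Tidy a bootstrap result
#'
#' @param x A `bb_boot` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `estimate`, `conf.low`, `conf.high`,
#'   `n_replicates`, `n_failed`.
#' @export
tidy.bb_boot <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, estimate = x$point_estimate,
    conf.low = x$ci_lower, conf.high = x$ci_upper,
    n_replicates = x$n_replicates, n_failed = x$n_failed
  )
}
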