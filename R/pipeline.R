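#' Derive a per-stage random seed from a global seed
#'
#' Stages of the pipeline draw their own substreams so each can be re-run
#' independently and still be reproducible from the manifest alone. The
#' derivation hashes the stage label into the global seed and stays inside
#' the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulate and write the pipeline's input cohorts
#'
#' Writes `nodal_cohort.csv`, `survival_cohort.csv` and `manifest.json`
#' (the echoed configuration plus seed, sufficient to regenerate both files)
#' into `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed (required).
#' @param n_nodal,n_survival Cohort sizes.
#' @param nodal Arguments for [simulate_nodal_cohort()] other than size/seed.
#' @param survival Arguments for [simulate_survival_cohort()] other than
#'   size/seed.
#' @return Invisibly, a list with the two cohorts and the manifest.
#' @export
run_simulate <- function(out_dir, seed, n_nodal = 5399, n_survival = 15340,
                         nodal = list(prevalence = 0.389, alpha = 2.5,
                                      beta = 6.21),
                         survival = list()) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nodal_seed <- derive_seed(seed, "nodal")
  surv_seed <- derive_seed(seed, "survival")
  coh <- do.call(simulate_nodal_cohort,
                 c(list(n_patients = n_nodal, seed = nodal_seed), nodal))
  surv <- do.call(simulate_survival_cohort,
                  c(list(n_patients = n_survival, seed = surv_seed),
                    survival))
  write_nodal_cohort(coh, file.path(out_dir, "nodal_cohort.csv"))
  write_survival_cohort(surv, file.path(out_dir, "survival_cohort.csv"))
  manifest <- list(seed = seed, nodal_seed = nodal_seed,
                   survival_seed = surv_seed, n_nodal = n_nodal,
                   n_survival = n_survival, nodal = nodal,
                   survival = survival)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(nodal = coh, survival = surv, manifest = manifest))
}

#' Fit stage: maximum likelihood, bootstrap intervals and goodness of fit
#'
#' Runs [fit_bb_mle()] on the cohort, percentile-bootstraps both shape
#' parameters and the corrected prevalence, and attaches the chi-square
#' goodness of fit. When `out_dir` is given, writes `fit_report.json` and a
#' rendered `fit_report.txt`.
#'
#' @param cohort Nodal cohort (data frame) or a path to a cohort CSV.
#' @param seed Global integer seed (required; bootstrap substream derived
#'   from it).
#' @param truncated Zero-truncated likelihood? (default `TRUE`: the fitting
#'   subset is node-positive patients).
#' @param n_replicates Bootstrap replicates (default 2000).
#' @param out_dir Optional output directory.
#' @return A list report: `fit` (the `bb_fit`), `alpha`, `beta`, CI bounds,
#'   `prevalence` (one-row tibble), `prevalence_ci`, `gof`, `seed`.
#' @export
run_fit <- function(cohort, seed, truncated = TRUE, n_replicates = 2000,
                    out_dir = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.character(cohort)) cohort <- read_nodal_cohort(cohort)
  fit <- fit_bb_mle(cohort, truncated = truncated)
  boot_seed <- derive_seed(seed, "fit-bootstrap")
  fit_sub <- dplyr::filter(cohort, .data$nodes_examined >= fit$min_examined,
                           .data$nodes_positive >= 1)
  ba <- bb_bootstrap(fit_sub, "alpha", n_replicates = n_replicates,
                     seed = boot_seed, truncated = truncated)
  bb <- bb_bootstrap(fit_sub, "beta", n_replicates = n_replicates,
                     seed = derive_seed(seed, "fit-bootstrap-beta"),
                     truncated = truncated)
  prev <- corrected_prevalence(cohort, fit$alpha, fit$beta)
  gof <- bb_gof(fit_sub, fit, truncated = TRUE)
  report <- list(
    fit = fit,
    alpha = fit$alpha, alpha_ci = c(ba$ci_lower, ba$ci_upper),
    beta = fit$beta, beta_ci = c(bb$ci_lower, bb$ci_upper),
    logLik = fit$logLik, converged = fit$convergence == 0 && !fit$at_bound,
    n_fit = fit$n, truncated = truncated,
    prevalence = prev,
    gof = list(statistic = unname(gof$statistic), df = unname(gof$parameter),
               p_value = gof$p.value),
    seed = seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    json <- report[setdiff(names(report), "fit")]
    json$prevalence <- as.list(prev)
    jsonlite::write_json(json, file.path(out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- c(
      "Beta-binomial occult nodal disease fit",
      sprintf("  alpha = %.3f (95%% CI %.3f-%.3f)", fit$alpha,
              ba$ci_lower, ba$ci_upper),
      sprintf("  beta  = %.3f (95%% CI %.3f-%.3f)", fit$beta,
              bb$ci_lower, bb$ci_upper),
      sprintf("  log-likelihood %.2f on %d patients%s", fit$logLik, fit$n,
              if (truncated) " (zero-truncated)" else ""),
      sprintf("  observed prevalence %.3f, corrected %.3f (%.1f estimated FN)",
              prev$observed_prevalence, prev$corrected_prevalence,
              prev$total_fn),
      sprintf("  goodness of fit: chi-square %.2f on %d df, p = %.3f",
              report$gof$statistic, report$gof$df, report$gof$p_value))
    writeLines(txt, file.path(out_dir, "fit_report.txt"))
  }
  report
}

#' Risk-table stage: occult-risk profile with bootstrap bands
#'
#' Builds the per-yield [occult_risk_profile()] and attaches percentile
#' bootstrap intervals for the occult-disease probability at every yield
#' (one resampling pass; the shape parameters and prevalence are refitted
#' per replicate and the whole curve recomputed). Reports the minimum
#' adequate yield at `risk_threshold`.
#'
#' @param cohort Nodal cohort (data frame) or CSV path.
#' @param seed Global integer seed (required).
#' @param m_max Largest yield tabulated (default 30).
#' @param risk_threshold Acceptable occult-disease probability (default 0.10).
#' @param n_replicates Bootstrap replicates (default 2000).
#' @param truncated Zero-truncated refits? (default `TRUE`).
#' @param out_dir Optional output directory for `risk_table.csv`.
#' @return A list: `profile` (tibble with `occult_lo`/`occult_hi` columns),
#'   `min_adequate_yield`, `alpha`, `beta`, `prevalence`.
#' @export
run_risk_table <- function(cohort, seed, m_max = 30, risk_threshold = 0.10,
                           n_replicates = 2000, truncated = TRUE,
                           out_dir = NULL) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.character(cohort)) cohort <- read_nodal_cohort(cohort)
  fit <- fit_bb_mle(cohort, truncated = truncated)
  prev <- corrected_prevalence(cohort, fit$alpha, fit$beta)$corrected_prevalence
  profile <- occult_risk_profile(cohort, fit, prevalence = prev, m_max = m_max)

  boot_seed <- derive_seed(seed, "risk-table")
  n <- nrow(cohort)
  curves <- with_preserved_rng(boot_seed, {
    purrr::map(seq_len(n_replicates), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch({
        coh_i <- cohort[idx, , drop = FALSE]
        f <- fit_bb_mle(coh_i, truncated = truncated)
        p <- corrected_prevalence(coh_i, f$alpha, f$beta)$corrected_prevalence
        occult_probability(seq_len(m_max), f$alpha, f$beta, p)
      }, error = function(e) NULL, warning = function(w) NULL)
    })
  })
  curves <- curves[!vapply(curves, is.null, logical(1))]
  if (length(curves) < 0.9 * n_replicates) {
    stop("more than 10% of bootstrap replicates failed in the risk table",
         call. = FALSE)
  }
  mat <- do.call(rbind, curves)
  profile$occult_lo <- apply(mat, 2, stats::quantile, probs = 0.025)
  profile$occult_hi <- apply(mat, 2, stats::quantile, probs = 0.975)

  myield <- min_nodes_for_confidence(fit$alpha, fit$beta, prev, risk_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(dplyr::as_tibble(profile),
                     file.path(out_dir, "risk_table.csv"))
  }
  list(profile = profile, min_adequate_yield = myield,
       alpha = fit$alpha, beta = fit$beta, prevalence = prev,
       risk_threshold = risk_threshold, seed = seed)
}

#' Survival stage: eligibility, cutoff comparison and spline Cox model
#'
#' Runs the verification pipeline end to end: [eligibility_filter()],
#' [stratify_by_yield()], Kaplan-Meier with 5-/10-year rates per group,
#' log-rank comparison overall and in the elderly subgroup,
#' [select_knots_by_aic()] and [fit_cox_rcs()]. When `out_dir` is given,
#' writes a consolidated `survival_report.json`, per-group KM curves as CSV
#' and (optionally) the two figures.
#'
#' @param records Survival cohort (data frame) or CSV path.
#' @param cutoff Adequate-yield cutoff (default 7).
#' @param age_min Elderly-subgroup age bound (default 55).
#' @param candidate_counts Knot counts tried for the spline (default 3:5).
#' @param rules Eligibility rules (default [eligibility_rules()]).
#' @param out_dir Optional output directory.
#' @param plots Write figure files? (default `FALSE`; requires `out_dir`).
#' @return A list report: `tally`, `n_analyzed`, `km` (per-group OS rates),
#'   `log_rank`, `log_rank_elderly`, `knot_selection`, `cox` (`cox_rcs`),
#'   `hr_curve`.
#' @export
run_survival <- function(records, cutoff = 7, age_min = 55,
                         candidate_counts = 3:5,
                         rules = eligibility_rules(), out_dir = NULL,
                         plots = FALSE) {
  if (is.character(records)) records <- read_survival_cohort(records)
  n_input <- nrow(records)
  flt <- eligibility_filter(records, rules)
  kept <- stratify_by_yield(flt$records, cutoff = cutoff)

  km_groups <- kept |>
    dplyr::group_by(.data$yield_group) |>
    dplyr::group_modify(function(d, key) {
      os_rates(suppressWarnings(km_estimate(d)))
    }) |>
    dplyr::ungroup()

  lr_all <- log_rank_test(kept)
  elderly <- subgroup_elderly(kept, age_min = age_min)
  lr_eld <- if (nrow(elderly) > 0 &&
                dplyr::n_distinct(elderly$yield_group) == 2) {
    log_rank_test(elderly)
  } else NULL

  sel <- select_knots_by_aic(kept, variable = "nodes_examined",
                             candidate_counts = candidate_counts)
  hr <- hr_curve(sel$fit)

  report <- list(
    n_input = n_input, tally = flt$tally, n_analyzed = nrow(kept),
    cutoff = cutoff, km = km_groups,
    log_rank = lr_all, log_rank_elderly = lr_eld,
    knot_selection = sel$aic_table, n_knots = sel$n_knots,
    knots = sel$knots, cox = sel$fit,
    p_overall = sel$fit$overall$p_value, hr_curve = hr
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    json <- list(
      n_input = n_input, n_analyzed = nrow(kept), cutoff = cutoff,
      exclusions = as.list(stats::setNames(flt$tally$excluded,
                                           flt$tally$rule)),
      km = km_groups, log_rank = lr_all, log_rank_elderly = lr_eld,
      knot_selection = sel$aic_table, chosen_knots = sel$knots,
      cox = list(AIC = sel$fit$AIC, logLik = sel$fit$logLik,
                 n = sel$fit$n, n_events = sel$fit$n_events,
                 overall = sel$fit$overall))
    jsonlite::write_json(json, file.path(out_dir, "survival_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (g in levels(kept$yield_group)) {
      d <- kept[kept$yield_group == g, ]
      readr::write_csv(dplyr::as_tibble(km_estimate(d)),
                       file.path(out_dir, paste0("km_", g, ".csv")))
    }
    readr::write_csv(hr, file.path(out_dir, "hr_curve.csv"))
    if (plots) {
      ggplot2::ggsave(file.path(out_dir, "km_by_yield.pdf"),
                      plot_km_by_group(kept), width = 6, height = 4)
      ggplot2::ggsave(file.path(out_dir, "hr_curve.pdf"),
                      autoplot(sel$fit), width = 6, height = 4)
    }
  }
  report
}
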