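#' Node-yield sampling laws
#'
#' Small constructors describing how many nodes are examined per patient.
#' The default for simulated cohorts, `yield_nbinom()`, is a shifted negative
#' binomial `1 + NB(size, mu)` tuned so the yield has median 7 and
#' interquartile range 4-11, the pattern typical of central-compartment
#' dissection series; `yield_uniform()` gives a clean uniform support for
#' oracle tests, and `yield_empirical()` resamples a supplied table.
#'
#' @param lo,hi Integer bounds of the uniform law (inclusive).
#' @param size,mu Negative-binomial parameters of the shifted law.
#' @param counts Either an integer vector of observed yields to resample, or
#'   a data frame with columns `m` and `weight`.
#' @return A `yield_law` object: a list with a `sample(n)` function.
#' @export
yield_uniform <- function(lo = 2, hi = 15) {
  stopifnot(lo >= 1, hi >= lo)
  new_yield_law(function(n) sample(lo:hi, n, replace = TRUE),
                sprintf("uniform{%d..%d}", lo, hi))
}

#' @rdname yield_uniform
#' @export
yield_nbinom <- function(size = 2.5, mu = 7) {
  stopifnot(size > 0, mu > 0)
  new_yield_law(function(n) 1L + stats::rnbinom(n, size = size, mu = mu),
                sprintf("1 + NB(size = %g, mu = %g)", size, mu))
}

#' @rdname yield_uniform
#' @export
yield_empirical <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("m", "weight") %in% names(counts)), all(counts$m >= 1))
    m <- counts$m; w <- counts$weight
  } else {
    stopifnot(is.numeric(counts), all(counts >= 1))
    m <- as.integer(counts); w <- NULL
  }
  new_yield_law(function(n) sample(m, n, replace = TRUE, prob = w),
                "empirical")
}

new_yield_law <- function(sample, label) {
  structure(list(sample = sample, label = label), class = "yield_law")
}

#' @export
print.yield_law <- function(x, ...) {
  cat("<yield_law>", x$label, "\n")
  invisible(x)
}

#' Simulate a nodal-pathology cohort
#'
#' Generates per-patient examined/positive node counts under the model the
#' occult-disease analysis assumes: a patient truly harbors nodal disease
#' with probability `prevalence`; a diseased patient's per-node positivity
#' probability is drawn from Beta(alpha, beta); the node yield `m` follows
#' `yield`; and the positive count is Binomial(m, p) for diseased patients
#' and 0 otherwise. The latent truth is kept in a `.true_positive` column so
#' recovery oracles can see it; it is excluded from CSV output unless
#' requested.
#'
#' @param n_patients Number of patients.
#' @param prevalence True prevalence of nodal disease in \[0, 1\].
#' @param alpha,beta Shape parameters of the latent positivity law.
#' @param yield A `yield_law` (default `yield_nbinom()`).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration and seed.
#' @return A tibble with `patient_id`, `nodes_examined`, `nodes_positive`,
#'   `.true_positive`.
#' @examples
#' simulate_nodal_cohort(5, prevalence = 0.4, alpha = 2.5, beta = 6.21, seed = 1)
#' @export
simulate_nodal_cohort <- function(n_patients, prevalence, alpha, beta,
                                  yield = yield_nbinom(), seed) {
  check_bb_params(alpha, beta)
  stopifnot(n_patients >= 0, prevalence >= 0, prevalence <= 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!inherits(yield, "yield_law")) stop("`yield` must be a yield_law", call. = FALSE)
  with_preserved_rng(seed, {
    truly_pos <- stats::runif(n_patients) < prevalence
    m <- yield$sample(n_patients)
    x <- integer(n_patients)
    if (any(truly_pos)) {
      p <- stats::rbeta(sum(truly_pos), alpha, beta)
      x[truly_pos] <- stats::rbinom(sum(truly_pos), m[truly_pos], p)
    }
    tibble::tibble(
      patient_id = seq_len(n_patients),
      nodes_examined = as.integer(m),
      nodes_positive = as.integer(x),
      .true_positive = truly_pos
    )
  })
}

#' Simulate a registry-style survival cohort
#'
#' Generates per-patient records with the fields a SEER-like extract carries
#' (demographics, histology, staging, treatment, nodal counts, follow-up and
#' vital status) under a proportional-hazards structure: event times are
#' exponential with hazard `baseline_hazard * exp(linear predictor)`, where
#' the linear predictor sums `effects[[v]] * value(v)` over named covariates.
#' Censoring combines staggered study entry (administrative horizon minus a
#' uniform entry offset) with optional random exponential censoring.
#'
#' Covariate names usable in `effects`: `age_years`, `sex_female`,
#' `race_black`, `race_other`, `extrathyroidal_extension`, `multifocality`,
#' `surgery_total`, `rai`, `nodes_examined`, `nodes_positive` (indicators for
#' the categorical ones, raw values for the counts and age).
#'
#' @param n_patients Number of patients.
#' @param baseline_hazard Events per month for a patient with zero linear
#'   predictor (default 2.5e-4, giving ~98.5% 5-year survival).
#' @param effects Named list/vector of log hazard ratios (default: modest
#'   age and sex effects, no effect of node yield).
#' @param horizon_months Administrative follow-up horizon (default 126).
#' @param entry_spread_months Uniform spread of study entry before the
#'   horizon; `horizon_months` spread gives uniform censoring times and a
#'   median follow-up near half the horizon (default `horizon_months`).
#' @param censor_rate Additional random censoring hazard per month (default 0).
#' @param nodal A list of arguments passed to [simulate_nodal_cohort()]
#'   (fields `prevalence`, `alpha`, `beta`, `yield`); the nodal counts feed
#'   the `n_stage` field.
#' @param age_mean Mean of the age law, normal with SD 12 truncated to
#'   \[18, 90\] (default 47, which puts about a quarter of patients at 55+).
#' @param inject_ineligible Optional named integer vector adding records that
#'   violate eligibility, with names among `n1b`, `m1`, `oversize`,
#'   `histology`, `prior_malignancy`; used to exercise the eligibility filter.
#' @param seed Integer seed.
#' @return A tibble of survival records (one row per patient).
#' @export
simulate_survival_cohort <- function(n_patients,
                                     baseline_hazard = 2.5e-4,
                                     effects = list(age_years = log(1.08),
                                                    sex_female = log(0.7)),
                                     horizon_months = 126,
                                     entry_spread_months = horizon_months,
                                     censor_rate = 0,
                                     nodal = list(prevalence = 0.389,
                                                  alpha = 2.5, beta = 6.21),
                                     age_mean = 47,
                                     inject_ineligible = NULL,
                                     seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(baseline_hazard > 0, horizon_months >= 0, censor_rate >= 0)
  with_preserved_rng(seed, {
    nodal_args <- utils::modifyList(
      list(prevalence = 0.389, alpha = 2.5, beta = 6.21,
           yield = yield_nbinom()),
      as.list(nodal))
    truly_pos <- stats::runif(n_patients) < nodal_args$prevalence
    m <- nodal_args$yield$sample(n_patients)
    x <- integer(n_patients)
    if (any(truly_pos)) {
      p <- stats::rbeta(sum(truly_pos), nodal_args$alpha, nodal_args$beta)
      x[truly_pos] <- stats::rbinom(sum(truly_pos), m[truly_pos], p)
    }

    age <- pmin(pmax(stats::rnorm(n_patients, age_mean, 12), 18), 90)
    sex <- ifelse(stats::runif(n_patients) < 0.80, "female", "male")
    race <- sample(c("white", "black", "other"), n_patients, replace = TRUE,
                   prob = c(0.78, 0.08, 0.14))
    ete <- stats::runif(n_patients) < 0.04
    multi <- stats::runif(n_patients) < 0.30
    surgery <- ifelse(stats::runif(n_patients) < 0.60, "total", "lobectomy")
    rai <- stats::runif(n_patients) < 0.40
    histology <- sample(c("8050/3", "8260/3", "8340/3", "8341/3", "8342/3",
                          "8343/3"), n_patients, replace = TRUE,
                        prob = c(0.02, 0.55, 0.35, 0.04, 0.02, 0.02))
    size <- round(stats::runif(n_patients, 2, 10), 1)

    design <- list(
      age_years = age - 47,  # centered: baseline hazard refers to a 47-year-old
      sex_female = as.numeric(sex == "female"),
      race_black = as.numeric(race == "black"),
      race_other = as.numeric(race == "other"),
      extrathyroidal_extension = as.numeric(ete),
      multifocality = as.numeric(multi),
      surgery_total = as.numeric(surgery == "total"),
      rai = as.numeric(rai),
      nodes_examined = as.numeric(m),
      nodes_positive = as.numeric(x)
    )
    lp <- rep(0, n_patients)
    for (v in names(effects)) {
      if (!v %in% names(design)) {
        stop("unknown covariate in `effects`: ", v, call. = FALSE)
      }
      lp <- lp + effects[[v]] * design[[v]]
    }

    event_time <- stats::rexp(n_patients, rate = baseline_hazard * exp(lp))
    admin <- horizon_months - stats::runif(n_patients, 0, entry_spread_months)
    censor_time <- if (censor_rate > 0) {
      pmin(admin, stats::rexp(n_patients, censor_rate))
    } else admin
    censor_time <- pmax(censor_time, 0)
    fu <- pmin(event_time, censor_time)
    status <- ifelse(event_time <= censor_time, "dead", "alive")

    out <- tibble::tibble(
      patient_id = seq_len(n_patients),
      histology_code = histology,
      tumor_size_mm = size,
      n_stage = ifelse(x >= 1, "N1a", "N0"),
      m_stage = "M0",
      prior_malignancy = FALSE,
      age_years = age,
      sex = sex,
      race = race,
      extrathyroidal_extension = ete,
      multifocality = multi,
      surgery_extent = surgery,
      rai = rai,
      nodes_examined = as.integer(m),
      nodes_positive = as.integer(x),
      follow_up_months = fu,
      vital_status = status,
      .true_positive = truly_pos
    )
    if (!is.null(inject_ineligible)) {
      out <- dplyr::bind_rows(out, ineligible_records(inject_ineligible, nrow(out)))
    }
    out
  })
}

# records violating one eligibility rule each, for filter audits
ineligible_records <- function(counts, id_offset) {
  known <- c("n1b", "m1", "oversize", "histology", "prior_malignancy")
  bad <- setdiff(names(counts), known)
  if (length(bad)) stop("unknown ineligibility type(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  template <- tibble::tibble(
    histology_code = "8260/3", tumor_size_mm = 6, n_stage = "N0",
    m_stage = "M0", prior_malignancy = FALSE, age_years = 50,
    sex = "female", race = "white", extrathyroidal_extension = FALSE,
    multifocality = FALSE, surgery_extent = "total", rai = FALSE,
    nodes_examined = 5L, nodes_positive = 0L,
    follow_up_months = 60, vital_status = "alive", .true_positive = FALSE
  )
  rows <- purrr::imap_dfr(as.list(counts), function(k, type) {
    if (k == 0) return(NULL)
    r <- template[rep(1, k), ]
    switch(type,
           n1b = { r$n_stage <- "N1b"; r$nodes_positive <- 1L },
           m1 = { r$m_stage <- "M1" },
           oversize = { r$tumor_size_mm <- 14 },
           histology = { r$histology_code <- "8020/3" },
           prior_malignancy = { r$prior_malignancy <- TRUE })
    r
  })
  rows$patient_id <- id_offset + seq_len(nrow(rows))
  rows
}

# run expr under a local, seeded RNG without disturbing the caller's stream
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
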