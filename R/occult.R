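#' Probability of occult nodal disease given an all-negative examination
#'
#' For a patient whose `m` examined nodes are all negative, the posterior
#' probability that nodal disease is nonetheless present is
#' `prevalence * P0(m) / (prevalence * P0(m) + 1 - prevalence)`, where
#' `P0(m) = B(alpha, beta + m) / B(alpha, beta)` is the false-negative
#' probability of the beta-binomial law. At `m = 0` no information has been
#' gathered and the value is the prevalence itself; it decreases strictly to
#' 0 as `m` grows.
#'
#' @inheritParams bb_pmf
#' @param prevalence True (corrected) prevalence of nodal disease in \[0, 1\].
#' @return Numeric vector in \[0, prevalence\].
#' @examples
#' occult_probability(1:7, 2.50, 6.21, prevalence = 0.389)
#' @export
occult_probability <- function(m, alpha, beta, prevalence) {
  if (any(prevalence < 0) || any(prevalence > 1)) {
    stop("`prevalence` must lie in [0, 1]", call. = FALSE)
  }
  p0 <- bb_prob_all_negative(m, alpha, beta)
  prevalence * p0 / (prevalence * p0 + 1 - prevalence)
}

#' Minimum node yield ruling out occult disease at a given confidence
#'
#' Smallest number of examined nodes `m` at which the occult-disease
#' probability [occult_probability()] falls to `risk_threshold` or below;
#' examining that many nodes rules out residual nodal disease with confidence
#' `1 - risk_threshold`.
#'
#' @inheritParams occult_probability
#' @param risk_threshold Acceptable residual-disease probability (e.g. 0.10
#'   for 90% confidence).
#' @param m_max Search cap; exceeding it is an error.
#' @return Integer count (0 when the threshold is already met with no nodes
#'   examined, i.e. `risk_threshold >= prevalence`).
#' @examples
#' min_nodes_for_confidence(2.50, 6.21, prevalence = 0.389, risk_threshold = 0.10)
#' @export
min_nodes_for_confidence <- function(alpha, beta, prevalence, risk_threshold,
                                     m_max = 1000) {
  if (risk_threshold <= 0 || risk_threshold > 1) {
    stop("`risk_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (risk_threshold >= prevalence) {
    message("risk threshold ", risk_threshold, " already met at m = 0 ",
            "(prevalence ", prevalence, ")")
    return(0L)
  }
  for (m in seq_len(m_max)) {
    if (occult_probability(m, alpha, beta, prevalence) <= risk_threshold) {
      return(m)
    }
  }
  stop("occult probability does not reach ", risk_threshold,
       " within m_max = ", m_max, " examined nodes", call. = FALSE)
}

#' Per-yield occult risk profile with false-negative counts
#'
#' Tabulates, for every node yield `m` from 1 to `m_max`, the probability
#' that a truly node-positive patient shows no positive node (`p_all_negative`),
#' its complement (`detection_prob`), the occult-disease probability for an
#' observed node-negative patient (`occult_prob`), the number of observed
#' node-positive patients at that yield (`n_tp`) and the implied number of
#' false-negative patients `fn_count = P0(m) * n_tp / (1 - P0(m))`.
#'
#' @param cohort Data frame with `nodes_examined`, `nodes_positive`.
#' @param alpha,beta Shape parameters (or a `bb_fit` as `alpha`).
#' @param prevalence Prevalence used for `occult_prob`; default the cohort's
#'   corrected prevalence under (alpha, beta).
#' @param m_max Largest yield tabulated (default 30).
#' @return A tibble with columns `m`, `p_all_negative`, `detection_prob`,
#'   `occult_prob`, `n_tp`, `fn_count`, carrying the inputs as attributes.
#' @export
occult_risk_profile <- function(cohort, alpha, beta = NULL, prevalence = NULL,
                                m_max = 30) {
  if (inherits(alpha, "bb_fit")) {
    beta <- alpha$beta
    alpha <- alpha$alpha
  }
  cohort <- validate_nodal_cohort(cohort)
  if (is.null(prevalence)) {
    prevalence <- corrected_prevalence(cohort, alpha, beta)$corrected_prevalence
  }
  m <- seq_len(m_max)
  p0 <- bb_prob_all_negative(m, alpha, beta)
  tp <- cohort |>
    dplyr::filter(.data$nodes_positive >= 1) |>
    dplyr::count(m = .data$nodes_examined, name = "n_tp")
  out <- tibble::tibble(
    m = m,
    p_all_negative = p0,
    detection_prob = 1 - p0,
    occult_prob = occult_probability(m, alpha, beta, prevalence)
  ) |>
    dplyr::left_join(tp, by = "m") |>
    dplyr::mutate(n_tp = dplyr::coalesce(.data$n_tp, 0L),
                  fn_count = .data$p_all_negative * .data$n_tp /
                    (1 - .data$p_all_negative))
  attr(out, "alpha") <- alpha
  attr(out, "beta") <- beta
  attr(out, "prevalence") <- prevalence
  class(out) <- c("occult_risk_profile", class(out))
  out
}

#' Observed and false-negative-corrected nodal prevalence
#'
#' The observed prevalence is the fraction of patients with at least one
#' positive node. Each yield stratum's observed node-positive count is
#' inflated by the estimated false negatives
#' `fn_m = P0(m) * tp_m / (1 - P0(m))`, and the corrected prevalence is the
#' inflated positive total over the fixed total patient count, capped at 1.
#'
#' @param cohort Data frame with `nodes_examined`, `nodes_positive`.
#' @param alpha,beta Shape parameters (or a `bb_fit` as `alpha`).
#' @return A one-row tibble: `observed_prevalence`, `corrected_prevalence`,
#'   `total_fn`, `n_patients`.
#' @examples
#' coh <- simulate_nodal_cohort(5000, prevalence = 0.389, alpha = 2.5,
#'                              beta = 6.21, seed = 7)
#' corrected_prevalence(coh, 2.5, 6.21)
#' @export
corrected_prevalence <- function(cohort, alpha, beta = NULL) {
  if (inherits(alpha, "bb_fit")) {
    beta <- alpha$beta
    alpha <- alpha$alpha
  }
  cohort <- validate_nodal_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  n <- nrow(cohort)
  strata <- cohort |>
    dplyr::group_by(m = .data$nodes_examined) |>
    dplyr::summarise(n_tp = sum(.data$nodes_positive >= 1), .groups = "drop") |>
    dplyr::mutate(p0 = bb_prob_all_negative(.data$m, alpha, beta),
                  fn = .data$p0 * .data$n_tp / (1 - .data$p0))
  total_fn <- sum(strata$fn)
  corrected <- (sum(strata$n_tp) + total_fn) / n
  if (corrected > 1) {
    warning("false-negative correction exceeds the cohort size; ",
            "corrected prevalence capped at 1", call. = FALSE)
    corrected <- 1
  }
  tibble::tibble(
    observed_prevalence = sum(strata$n_tp) / n,
    corrected_prevalence = corrected,
    total_fn = total_fn,
    n_patients = n
  )
}
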