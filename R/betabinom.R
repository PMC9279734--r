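#' Beta-binomial probability mass function
#'
#' Probability of observing `x` positive nodes among `m` examined when the
#' per-node positivity probability varies across patients as Beta(alpha, beta)
#' and nodes within a patient are conditionally independent. All Beta-function
#' ratios are evaluated as log-gamma differences.
#'
#' @param x Integer vector, number of positive nodes (0 <= x <= m).
#' @param m Integer vector, number of nodes examined (m >= 0).
#' @param alpha,beta Positive shape parameters of the latent Beta law.
#' @param log Logical; return log probabilities?
#'
#' @return Numeric vector of probabilities (recycled over `x`, `m`).
#' @examples
#' bb_pmf(0, 1, 2.50, 6.21)            # beta / (alpha + beta)
#' sum(bb_pmf(0:10, 10, 2.50, 6.21))   # 1
#' @export
bb_pmf <- function(x, m, alpha, beta, log = FALSE) {
  check_bb_params(alpha, beta)
  if (any(m < 0)) stop("`m` must be non-negative", call. = FALSE)
  if (any(x < 0) || any(x > m)) {
    stop("`x` must satisfy 0 <= x <= m", call. = FALSE)
  }
  ll <- lchoose(m, x) + lbeta(alpha + x, beta + m - x) - lbeta(alpha, beta)
  if (log) ll else exp(ll)
}

#' Probability that all examined nodes are negative
#'
#' For a truly node-positive patient with `m` nodes examined, the chance that
#' every examined node is negative is B(alpha, beta + m) / B(alpha, beta),
#' equivalently the telescoping product of (beta + k) / (alpha + beta + k)
#' for k = 0, ..., m - 1. This is the false-negative staging probability at
#' yield `m`.
#'
#' @inheritParams bb_pmf
#' @return Numeric vector in \[0, 1\]; strictly decreasing in `m`.
#' @examples
#' bb_prob_all_negative(7, 2.50, 6.21)
#' @export
bb_prob_all_negative <- function(m, alpha, beta) {
  check_bb_params(alpha, beta)
  if (any(m < 0)) stop("`m` must be non-negative", call. = FALSE)
  exp(lbeta(alpha, beta + m) - lbeta(alpha, beta))
}

#' Probability that nodal disease is detected
#'
#' Complement of [bb_prob_all_negative()]: the chance that a truly
#' node-positive patient shows at least one positive node among `m` examined.
#'
#' @inheritParams bb_pmf
#' @return Numeric vector in \[0, 1\]; increasing in `m`, 0 at `m = 0`.
#' @export
bb_detection_prob <- function(m, alpha, beta) {
  1 - bb_prob_all_negative(m, alpha, beta)
}

#' Beta-binomial log-likelihood of a nodal cohort
#'
#' Sum of log beta-binomial masses over patients; with `truncated = TRUE` the
#' zero-truncated likelihood conditioning on at least one observed positive
#' node (every record must then have `nodes_positive >= 1`). Internally the
#' cohort is collapsed to (m, x) count cells, so large cohorts cost no more
#' than their number of distinct cells.
#'
#' @param cohort Data frame with integer columns `nodes_examined` and
#'   `nodes_positive`, one row per patient.
#' @param alpha,beta Positive shape parameters.
#' @param truncated Logical; condition on `nodes_positive >= 1`?
#'
#' @return A single finite number for positive finite parameters.
#' @export
bb_loglik <- function(cohort, alpha, beta, truncated = FALSE) {
  cohort <- validate_nodal_cohort(cohort)
  cells <- nodal_cells(cohort)
  bb_loglik_cells(cells, alpha, beta, truncated = truncated)
}

# (m, x, n) sufficient-statistic cells for likelihood work
nodal_cells <- function(cohort) {
  dplyr::count(cohort, .data$nodes_examined, .data$nodes_positive, name = "n_patients")
}

bb_loglik_cells <- function(cells, alpha, beta, truncated = FALSE) {
  if (truncated && any(cells$nodes_positive == 0)) {
    stop("truncated likelihood requires every record to have nodes_positive >= 1",
         call. = FALSE)
  }
  ll <- bb_pmf(cells$nodes_positive, cells$nodes_examined, alpha, beta, log = TRUE)
  if (truncated) {
    p0 <- bb_prob_all_negative(cells$nodes_examined, alpha, beta)
    ll <- ll - log1p(-p0)
  }
  sum(cells$n_patients * ll)
}

check_bb_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(alpha <= 0) || any(beta <= 0)) {
    stop("`alpha` and `beta` must be finite and positive", call. = FALSE)
  }
  invisible(NULL)
}

#' Validate a nodal pathology cohort
#'
#' Checks the two required integer columns and the per-row constraint
#' 0 <= nodes_positive <= nodes_examined; returns the cohort as a tibble.
#'
#' @param cohort Data frame with `nodes_examined`, `nodes_positive`.
#' @return The validated cohort as a tibble.
#' @export
validate_nodal_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("`cohort` must be a data frame", call. = FALSE)
  need <- c("nodes_examined", "nodes_positive")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0L) return(tibble::as_tibble(cohort))
  m <- cohort$nodes_examined
  x <- cohort$nodes_positive
  if (any(is.na(m)) || any(is.na(x))) {
    stop("`nodes_examined` and `nodes_positive` must not contain NA", call. = FALSE)
  }
  if (any(m < 1)) stop("`nodes_examined` must be >= 1 for every patient", call. = FALSE)
  if (any(x < 0) || any(x > m)) {
    stop("each row must satisfy 0 <= nodes_positive <= nodes_examined", call. = FALSE)
  }
  tibble::as_tibble(cohort)
}
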