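#' Kaplan-Meier overall-survival curve
#'
#' Product-limit estimate of overall survival from `follow_up_months` and
#' `vital_status` (`"dead"` = event, anything else censored). The numerical
#' core is `survival::survfit()`; the curve is returned as a tidy step
#' function queryable at arbitrary times.
#'
#' @param records Data frame with `follow_up_months` and `vital_status`.
#' @return A `km_curve` object: a tibble with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `std_err`, `conf_low`, `conf_high`,
#'   carrying the `survfit` object as an attribute.
#' @export
km_estimate <- function(records) {
  records <- check_survival_fields(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  if (all(records$follow_up_months == 0)) {
    stop("all follow-up times are zero; no survival curve can be estimated",
         call. = FALSE)
  }
  sf <- survival::survfit(
    survival::Surv(follow_up_months, status) ~ 1,
    data = records, conf.type = "log-log")
  out <- tibble::tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, survival = sf$surv, std_err = sf$std.err,
    conf_low = sf$lower, conf_high = sf$upper)
  attr(out, "survfit") <- sf
  attr(out, "n") <- nrow(records)
  class(out) <- c("km_curve", class(out))
  out
}

check_survival_fields <- function(records) {
  need <- c("follow_up_months", "vital_status")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records are missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(records$follow_up_months < 0)) {
    stop("`follow_up_months` must be non-negative", call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  records$status <- as.integer(records$vital_status == "dead")
  records
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step evaluation; times before the first event return 1.
#'
#' @param curve A `km_curve`.
#' @param times Numeric vector of times (months).
#' @return Numeric vector of survival probabilities; `NA` (with a warning)
#'   beyond the last follow-up time.
#' @export
km_survival_at <- function(curve, times) {
  sf <- attr(curve, "survfit")
  max_t <- max(sf$time)
  out <- summary(sf, times = pmin(times, max_t), extend = TRUE)$surv
  beyond <- times > max_t
  if (any(beyond)) {
    warning("follow-up never reaches ", paste(times[beyond], collapse = ", "),
            " months; survival there is unavailable", call. = FALSE)
    out[beyond] <- NA_real_
  }
  out
}

#' Five- and ten-year overall-survival rates
#'
#' @param curve A `km_curve`.
#' @return One-row tibble `os_5yr`, `os_10yr` (survival at 60 and 120
#'   months; `NA` with a warning when follow-up does not reach the horizon).
#' @export
os_rates <- function(curve) {
  s <- km_survival_at(curve, c(60, 120))
  tibble::tibble(os_5yr = s[1], os_10yr = s[2])
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison (hypergeometric variance summed over the
#' pooled distinct event times, df = 1) via `survival::survdiff()`.
#'
#' @param records Data frame with `follow_up_months`, `vital_status` and the
#'   grouping column.
#' @param group Name of a two-level grouping column (default `yield_group`,
#'   as added by [stratify_by_yield()]).
#' @return One-row tibble: `chi_square`, `df`, `p_value`, `n_<level>` group
#'   sizes.
#' @export
log_rank_test <- function(records, group = "yield_group") {
  records <- check_survival_fields(records)
  if (!group %in% names(records)) {
    stop("grouping column `", group, "` not found", call. = FALSE)
  }
  g <- factor(records[[group]])
  g <- droplevels(g)
  if (nlevels(g) != 2) {
    stop("log-rank comparison needs exactly 2 non-empty groups, got ",
         nlevels(g), call. = FALSE)
  }
  records$.group <- g
  sd <- survival::survdiff(
    survival::Surv(follow_up_months, status) ~ .group, data = records)
  df <- length(sd$n) - 1
  sizes <- as.list(as.integer(sd$n))
  names(sizes) <- paste0("n_", levels(g))
  dplyr::bind_cols(
    tibble::tibble(chi_square = sd$chisq, df = df,
                   p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
    tibble::as_tibble(sizes))
}
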