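#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an occult-risk profile
#'
#' Occult-disease probability against the number of nodes examined, with the
#' false-negative staging probability as a companion line.
#'
#' @param object An `occult_risk_profile` tibble.
#' @param risk_threshold Optional horizontal reference line (e.g. 0.10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occult_risk_profile <- function(object, risk_threshold = NULL, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[c("m", "occult_prob", "p_all_negative")],
    -"m", names_to = "quantity", values_to = "probability")
  long$quantity <- factor(long$quantity,
                          levels = c("occult_prob", "p_all_negative"),
                          labels = c("occult disease (observed negative)",
                                     "all examined nodes negative (truly positive)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$probability,
                                          colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "nodes examined", y = "probability", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
  if (!is.null(risk_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = risk_threshold,
                                 linetype = "dashed")
  }
  p
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve`.
#' @param conf_int Shade the pointwise confidence band?
#' @param ... Unused.
#' @return A ggplot object (step curve).
#' @export
autoplot.km_curve <- function(object, conf_int = TRUE, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1, conf_low = 1, conf_high = 1),
    dplyr::as_tibble(object)[c("time", "survival", "conf_low", "conf_high")])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "overall survival") +
    ggplot2::theme_minimal()
  if (conf_int) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$conf_low),
                                linetype = "dotted", na.rm = TRUE) +
      ggplot2::geom_step(ggplot2::aes(y = .data$conf_high),
                         linetype = "dotted", na.rm = TRUE)
  }
  p
}

#' Compare Kaplan-Meier curves across yield groups
#'
#' @param records Data frame with `follow_up_months`, `vital_status` and a
#'   grouping column (see [stratify_by_yield()]).
#' @param group Grouping column name (default `"yield_group"`).
#' @return A ggplot object with one step curve per group.
#' @export
plot_km_by_group <- function(records, group = "yield_group") {
  curves <- records |>
    dplyr::group_by(.data[[group]]) |>
    dplyr::group_modify(function(d, key) {
      dplyr::as_tibble(km_estimate(d))[c("time", "survival")]
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data[[group]])) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "overall survival", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot the hazard-ratio curve of a spline Cox fit
#'
#' @param object A `cox_rcs` fit.
#' @param at Grid of main-variable values (default as in [hr_curve()]).
#' @param ... Unused.
#' @return A ggplot object: HR versus the main variable with the pointwise
#'   confidence band, knot rug and HR = 1 reference.
#' @export
autoplot.cox_rcs <- function(object, at = NULL, ...) {
  d <- hr_curve(object, at = at)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$hr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_rug(data = tibble::tibble(x = object$knots[[object$main]]),
                      ggplot2::aes(x = .data$x), inherit.aes = FALSE,
                      sides = "b") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$main, y = "hazard ratio") +
    ggplot2::theme_minimal()
}
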