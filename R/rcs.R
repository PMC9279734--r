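#' Restricted cubic spline basis (Harrell parameterization)
#'
#' For k knots t1 < ... < tk the basis has k - 1 columns: the identity, and
#' for j = 1, ..., k - 2 the truncated-cube combination
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2,}
#' which is linear beyond the boundary knots by construction. The division by
#' the squared knot range keeps the nonlinear columns on the scale of `x`.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing numeric vector of at least 3 knots.
#' @return A numeric matrix with `length(knots) - 1` columns and a `knots`
#'   attribute.
#' @examples
#' rcs_basis(0:12, knots = c(1, 2, 9))
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(as.numeric(knots))
  k <- length(knots)
  if (k < 3) stop("at least 3 knots are required", call. = FALSE)
  if (any(diff(knots) <= 0)) stop("knots must be distinct", call. = FALSE)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (pos3(x - tj) -
       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- paste0("s", seq_len(k - 1))
  attr(out, "knots") <- knots
  out
}

#' Percentile knot placement
#'
#' Fixed-percentile locations: 3 knots at the 10/50/90th percentiles,
#' 4 at 5/35/65/95, 5 at 5/27.5/50/72.5/95.
#'
#' @param x Numeric vector of observed values.
#' @param k Number of knots (3, 4 or 5).
#' @return Numeric vector of knot locations; error if they are not distinct.
#' @export
rcs_knots <- function(x, k) {
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop("`k` must be 3, 4 or 5", call. = FALSE))
  kn <- unname(stats::quantile(x, probs, type = 7, na.rm = TRUE))
  if (any(diff(kn) <= 0)) {
    stop("percentile knots are not distinct for k = ", k,
         " (values: ", paste(signif(kn, 4), collapse = ", "), ")",
         call. = FALSE)
  }
  kn
}

#' Multivariable Cox model with restricted cubic splines
#'
#' Fits overall survival on a main continuous variable and adjustment
#' covariates, modeling the main variable (and any other continuous
#' covariates named in `spline_vars`) with a restricted cubic spline.
#' The partial-likelihood fit delegates to `survival::coxph()` with the
#' Efron tie correction; the spline basis, knot placement, the overall
#' association test on the main variable's spline block, the AIC and the
#' hazard-ratio curve are computed here.
#'
#' Only complete cases over the model fields are used; the number of dropped
#' rows is recorded in the result.
#'
#' @param records Data frame of survival records.
#' @param main Name of the main continuous variable (default
#'   `"nodes_examined"`).
#' @param spline_vars Continuous variables modeled with a spline (must
#'   include `main`).
#' @param covariates Adjustment covariates entered linearly (factors for
#'   character columns).
#' @param n_knots Knot count for every spline variable (3-5), or a named
#'   list per variable.
#' @param knots Optional named list of explicit knot vectors, overriding the
#'   percentile placement.
#' @param ref Reference value of `main` for the hazard-ratio curve (default
#'   its median in the analysis data).
#' @param overall_test `"wald"` (default) for the joint Wald chi-square on
#'   the main spline block, or `"lr"` for the likelihood-ratio variant.
#' @return A `cox_rcs` object: list with elements `model` (the `coxph` fit),
#'   `knots`, `main`, `ref`, `logLik`, `AIC`, `n`, `n_events`, `n_dropped`,
#'   `overall` (tibble: statistic, df, p_value, method).
#' @export
fit_cox_rcs <- function(records,
                        main = "nodes_examined",
                        spline_vars = c("nodes_examined", "age_years",
                                        "nodes_positive"),
                        covariates = c("sex", "race",
                                       "extrathyroidal_extension",
                                       "multifocality", "surgery_extent",
                                       "rai"),
                        n_knots = 3, knots = NULL, ref = NULL,
                        overall_test = c("wald", "lr")) {
  overall_test <- match.arg(overall_test)
  if (!main %in% spline_vars) spline_vars <- c(main, spline_vars)
  records <- check_survival_fields(records)
  fields <- unique(c("follow_up_months", "status", spline_vars, covariates))
  miss <- setdiff(fields, names(records))
  if (length(miss)) {
    stop("records are missing model field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cc <- stats::complete.cases(records[fields])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped as incomplete cases")
  }
  dat <- records[cc, fields, drop = FALSE]

  knot_count <- function(v) {
    if (is.list(n_knots)) n_knots[[v]] %||% 3 else n_knots
  }
  knot_list <- list()
  design <- dat[c("follow_up_months", "status")]
  terms <- character(0)
  for (v in spline_vars) {
    kn <- if (!is.null(knots) && !is.null(knots[[v]])) {
      sort(as.numeric(knots[[v]]))
    } else {
      tryCatch(rcs_knots(dat[[v]], knot_count(v)), error = function(e) {
        if (v == main) stop(e)
        # a tied covariate (e.g. mostly-zero positive-node counts) enters
        # linearly rather than aborting the adjusted model
        message("covariate `", v, "` has tied percentile knots; ",
                "entered linearly")
        NULL
      })
    }
    if (is.null(kn)) {
      cn <- paste0(v, "_rcs1")
      design[[cn]] <- dat[[v]]
      terms <- c(terms, cn)
      next
    }
    knot_list[[v]] <- kn
    B <- rcs_basis(dat[[v]], kn)
    cn <- paste0(v, "_rcs", seq_len(ncol(B)))
    colnames(B) <- cn
    design <- dplyr::bind_cols(design, tibble::as_tibble(B))
    terms <- c(terms, cn)
  }
  for (v in covariates) {
    col <- dat[[v]]
    design[[v]] <- if (is.character(col)) factor(col) else col
    terms <- c(terms, v)
  }

  fml <- stats::as.formula(paste(
    "survival::Surv(follow_up_months, status) ~",
    paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = design, ties = "efron")
  if (any(is.na(stats::coef(fit)))) {
    stop("Cox fit produced undefined coefficients (collinear or separated ",
         "design)", call. = FALSE)
  }

  p <- length(stats::coef(fit))
  ll <- fit$loglik[2]
  aic <- -2 * ll + 2 * p

  block <- grep(paste0("^", main, "_rcs"), names(stats::coef(fit)))
  overall <- if (overall_test == "wald") {
    b <- stats::coef(fit)[block]
    V <- stats::vcov(fit)[block, block, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    tibble::tibble(statistic = stat, df = length(block),
                   p_value = stats::pchisq(stat, length(block),
                                           lower.tail = FALSE),
                   method = "Wald (spline block)")
  } else {
    keep <- setdiff(terms, paste0(main, "_rcs",
                                  seq_along(knot_list[[main]])))
    fml0 <- stats::as.formula(paste(
      "survival::Surv(follow_up_months, status) ~",
      if (length(keep)) paste(keep, collapse = " + ") else "1"))
    fit0 <- survival::coxph(fml0, data = design, ties = "efron")
    stat <- 2 * (fit$loglik[2] - fit0$loglik[2])
    tibble::tibble(statistic = stat, df = length(block),
                   p_value = stats::pchisq(stat, length(block),
                                           lower.tail = FALSE),
                   method = "likelihood ratio (spline block)")
  }

  if (is.null(ref)) ref <- stats::median(dat[[main]])
  structure(
    list(model = fit, knots = knot_list, main = main, ref = ref,
         logLik = ll, AIC = aic, n = nrow(dat),
         n_events = sum(dat$status), n_dropped = n_dropped,
         overall = overall, terms = terms),
    class = "cox_rcs"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cox_rcs <- function(x, digits = 4, ...) {
  cat("Cox proportional-hazards model with restricted cubic splines\n")
  cat(sprintf("  n = %d (%d events, %d dropped incomplete)\n",
              x$n, x$n_events, x$n_dropped))
  cat(sprintf("  main variable: %s, knots at %s (reference %g)\n", x$main,
              paste(signif(x$knots[[x$main]], 4), collapse = ", "), x$ref))
  cat(sprintf("  logPL = %.*g, AIC = %.*g\n", digits, x$logLik, digits, x$AIC))
  cat(sprintf("  overall association (%s): chi-square = %.*g, df = %d, p = %.3g\n",
              x$overall$method, digits, x$overall$statistic, x$overall$df,
              x$overall$p_value))
  invisible(x)
}

#' Tidy a spline Cox fit
#'
#' @param x A `cox_rcs` object.
#' @param ... Unused.
#' @return Tibble of coefficients: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.cox_rcs <- function(x, ...) {
  b <- stats::coef(x$model)
  se <- sqrt(diag(stats::vcov(x$model)))
  z <- b / se
  tibble::tibble(term = names(b), estimate = unname(b),
                 std.error = unname(se), statistic = unname(z),
                 p.value = 2 * stats::pnorm(-abs(z)))
}

#' One-row summary of a spline Cox fit
#'
#' @param x A `cox_rcs` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_events`, `logLik`, `AIC`, `n_parameters`,
#'   `p_overall`.
#' @export
glance.cox_rcs <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, logLik = x$logLik,
                 AIC = x$AIC, n_parameters = length(stats::coef(x$model)),
                 p_overall = x$overall$p_value)
}

#' Hazard-ratio curve of the main spline variable
#'
#' Hazard ratio of `main = x` versus the reference value, holding all other
#' covariates fixed: `exp(B(x) b - B(ref) b)` over the main variable's spline
#' block, with pointwise delta-method confidence intervals on the log scale.
#' The HR at the reference value is exactly 1.
#'
#' @param fit A `cox_rcs` object.
#' @param at Numeric vector of main-variable values (default an even grid
#'   over the analysis range).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble: `x`, `hr`, `conf_low`, `conf_high`.
#' @export
hr_curve <- function(fit, at = NULL, conf_level = 0.95) {
  kn <- fit$knots[[fit$main]]
  if (is.null(at)) at <- seq(min(kn) - 1, max(kn) + 3, length.out = 50)
  block <- grep(paste0("^", fit$main, "_rcs"), names(stats::coef(fit$model)))
  b <- stats::coef(fit$model)[block]
  V <- stats::vcov(fit$model)[block, block, drop = FALSE]
  D <- rcs_basis(at, kn) - matrix(rcs_basis(fit$ref, kn), nrow = length(at),
                                  ncol = length(b), byrow = TRUE)
  eta <- drop(D %*% b)
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(x = at, hr = exp(eta),
                 conf_low = exp(eta - z * se), conf_high = exp(eta + z * se))
}

#' Choose the spline knot count by AIC
#'
#' Fits the full Cox model of [fit_cox_rcs()] once per candidate knot count
#' for the main variable (knots at the fixed percentiles of [rcs_knots()]),
#' and returns the candidate minimizing the AIC; ties go to fewer knots.
#' Candidates whose percentile knots are not distinct are dropped with a
#' warning.
#'
#' @param records Data frame of survival records.
#' @param variable Main spline variable (default `"nodes_examined"`).
#' @param candidate_counts Integer knot counts to try (default 3:5).
#' @param ... Further arguments to [fit_cox_rcs()].
#' @return A list: `n_knots` (chosen count), `knots`, `fit` (the chosen
#'   `cox_rcs`), `aic_table` (tibble of candidate AICs).
#' @export
select_knots_by_aic <- function(records, variable = "nodes_examined",
                                candidate_counts = 3:5, ...) {
  fits <- list()
  rows <- list()
  for (k in candidate_counts) {
    # the candidate count applies to the main variable; other splined
    # covariates keep the default 3 knots
    nk <- stats::setNames(list(k), variable)
    fit_k <- tryCatch(
      fit_cox_rcs(records, main = variable, n_knots = nk, ...),
      error = function(e) {
        warning("knot count ", k, " dropped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fit_k)) next
    fits[[as.character(k)]] <- fit_k
    rows[[as.character(k)]] <- tibble::tibble(n_knots = k, AIC = fit_k$AIC,
                                              logLik = fit_k$logLik)
  }
  if (length(fits) == 0) {
    stop("no candidate knot count could be fitted for `", variable, "`",
         call. = FALSE)
  }
  aic_table <- dplyr::bind_rows(rows)
  best <- aic_table$n_knots[which.min(aic_table$AIC)]  # which.min takes first = fewest on ties
  fit <- fits[[as.character(best)]]
  list(n_knots = best, knots = fit$knots[[variable]], fit = fit,
       aic_table = aic_table)
}
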