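#' Read and write nodal-pathology cohorts as CSV
#'
#' Comma-separated, UTF-8, header row mandatory. Required columns:
#' `nodes_examined`, `nodes_positive`; any further columns (clinical
#' covariates) are carried through. Rows violating
#' `0 <= nodes_positive <= nodes_examined` raise an error naming the
#' offending data line(s).
#'
#' @param path File path.
#' @param cohort Data frame to write.
#' @param include_truth Also write the `.true_positive` column if present
#'   (default `FALSE`; the column is simulation-only ground truth).
#' @return `read_nodal_cohort()` returns a validated tibble;
#'   `write_nodal_cohort()` returns `path` invisibly.
#' @export
read_nodal_cohort <- function(path) {
  df <- read_checked_csv(path, required = c("nodes_examined", "nodes_positive"))
  bad <- which(df$nodes_positive > df$nodes_examined | df$nodes_positive < 0 |
                 df$nodes_examined < 1)
  if (length(bad)) {
    stop("invalid node counts on data line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         " of ", path, " (need 0 <= nodes_positive <= nodes_examined, ",
         "nodes_examined >= 1)", call. = FALSE)
  }
  validate_nodal_cohort(df)
}

#' @rdname read_nodal_cohort
#' @export
write_nodal_cohort <- function(cohort, path, include_truth = FALSE) {
  cohort <- validate_nodal_cohort(cohort)
  if (!include_truth) {
    cohort <- dplyr::select(cohort, -dplyr::any_of(".true_positive"))
  }
  readr::write_csv(cohort, path)
  invisible(path)
}

survival_required_cols <- c(
  "histology_code", "tumor_size_mm", "n_stage", "m_stage",
  "prior_malignancy", "age_years", "sex", "race",
  "extrathyroidal_extension", "multifocality", "surgery_extent", "rai",
  "nodes_examined", "nodes_positive", "follow_up_months", "vital_status"
)

#' Read and write registry-style survival cohorts as CSV
#'
#' One row per patient with the fields the survival pipeline consumes
#' (histology code, staging, demographics, treatment, nodal counts,
#' follow-up months and vital status). Missing optional columns are
#' tolerated; missing required columns are an error naming them.
#'
#' @param path File path.
#' @param records Data frame of survival records.
#' @param include_truth Keep the simulation-only `.true_positive` column?
#' @return `read_survival_cohort()` returns a tibble;
#'   `write_survival_cohort()` returns `path` invisibly.
#' @export
read_survival_cohort <- function(path) {
  df <- read_checked_csv(path, required = survival_required_cols)
  bad <- which(df$nodes_positive > df$nodes_examined | df$nodes_positive < 0)
  if (length(bad)) {
    stop("invalid node counts on data line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  if (any(df$follow_up_months < 0)) {
    stop("negative follow_up_months in ", path, call. = FALSE)
  }
  df
}

#' @rdname read_survival_cohort
#' @export
write_survival_cohort <- function(records, path, include_truth = FALSE) {
  miss <- setdiff(survival_required_cols, names(records))
  if (length(miss)) {
    stop("survival records are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!include_truth) {
    records <- dplyr::select(records, -dplyr::any_of(".true_positive"))
  }
  readr::write_csv(records, path)
  invisible(path)
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop("parse error in ", path, " at line ", probs$row[1], ", column ",
         probs$col[1], ": ", probs$expected[1], " expected, got ",
         probs$actual[1], call. = FALSE)
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}
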