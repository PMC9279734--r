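#' Eligibility rules for the survival cohort
#'
#' Defaults mirror a registry extract of classical papillary thyroid
#' microcarcinoma: papillary ICD-O-3 histologies, tumor at most 10 mm, no
#' distant metastasis, no prior malignancy, no lateral-compartment (N1b)
#' nodal stage, and at least one node examined.
#'
#' @param allowed_histology_codes Character set of ICD-O-3 codes kept.
#' @param max_tumor_size_mm Maximum tumor size in millimetres.
#' @param excluded_n_stages,excluded_m_stages Stage labels excluded.
#' @param exclude_prior_malignancy Drop patients with a prior malignancy?
#' @param min_nodes_examined Minimum node yield.
#' @return An `eligibility_rules` list.
#' @export
eligibility_rules <- function(allowed_histology_codes = c("8050/3", "8260/3",
                                                          "8340/3", "8341/3",
                                                          "8342/3", "8343/3"),
                              max_tumor_size_mm = 10,
                              excluded_n_stages = "N1b",
                              excluded_m_stages = "M1",
                              exclude_prior_malignancy = TRUE,
                              min_nodes_examined = 1) {
  if (length(allowed_histology_codes) == 0) {
    stop("`allowed_histology_codes` must be non-empty", call. = FALSE)
  }
  structure(list(allowed_histology_codes = allowed_histology_codes,
                 max_tumor_size_mm = max_tumor_size_mm,
                 excluded_n_stages = excluded_n_stages,
                 excluded_m_stages = excluded_m_stages,
                 exclude_prior_malignancy = exclude_prior_malignancy,
                 min_nodes_examined = min_nodes_examined),
            class = "eligibility_rules")
}

#' Apply eligibility rules to survival records
#'
#' Rules are applied in a fixed order (histology, tumor size, distant
#' metastasis, prior malignancy, N stage, node yield); each exclusion is
#' attributed to the first rule it violates, so the tally sums to
#' input size minus kept size.
#'
#' @param records Data frame of survival records.
#' @param rules An [eligibility_rules()] object.
#' @return A list with `records` (kept rows, tibble) and `tally` (tibble of
#'   per-rule exclusion counts, in application order).
#' @export
eligibility_filter <- function(records, rules = eligibility_rules()) {
  need <- c("histology_code", "tumor_size_mm", "m_stage", "prior_malignancy",
            "n_stage", "nodes_examined")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records are missing required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  checks <- list(
    histology = records$histology_code %in% rules$allowed_histology_codes,
    tumor_size = records$tumor_size_mm <= rules$max_tumor_size_mm,
    distant_metastasis = !records$m_stage %in% rules$excluded_m_stages,
    prior_malignancy = if (rules$exclude_prior_malignancy) {
      !records$prior_malignancy
    } else rep(TRUE, nrow(records)),
    n_stage = !records$n_stage %in% rules$excluded_n_stages,
    nodes_examined = records$nodes_examined >= rules$min_nodes_examined
  )
  excluded_by <- rep(NA_character_, nrow(records))
  for (rule in names(checks)) {
    excluded_by[is.na(excluded_by) & !checks[[rule]]] <- rule
  }
  tally <- tibble::tibble(rule = names(checks)) |>
    dplyr::left_join(
      tibble::tibble(rule = excluded_by) |>
        dplyr::filter(!is.na(.data$rule)) |>
        dplyr::count(.data$rule, name = "excluded"),
      by = "rule") |>
    dplyr::mutate(excluded = dplyr::coalesce(.data$excluded, 0L))
  list(records = records[is.na(excluded_by), , drop = FALSE], tally = tally)
}

#' Split a cohort into adequate and inadequate node-yield groups
#'
#' Adds a `yield_group` factor: `"adequate"` when `nodes_examined >= cutoff`,
#' `"inadequate"` for 1 to cutoff - 1 nodes. Records with zero nodes examined
#' must have been excluded upstream.
#'
#' @param records Data frame with `nodes_examined`.
#' @param cutoff Minimum adequate yield (default 7, i.e. >= 7 vs 1-6).
#' @return The records tibble with a `yield_group` column.
#' @export
stratify_by_yield <- function(records, cutoff = 7) {
  if (cutoff < 2) stop("`cutoff` must be >= 2", call. = FALSE)
  if (any(records$nodes_examined < 1)) {
    stop("records with zero nodes examined must be excluded before ",
         "stratification", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(records),
                yield_group = factor(
                  ifelse(.data$nodes_examined >= cutoff, "adequate",
                         "inadequate"),
                  levels = c("inadequate", "adequate")))
}

#' Restrict to the elderly subgroup
#'
#' @param records Data frame with `age_years`.
#' @param age_min Inclusive lower age bound (default 55).
#' @return Tibble of records with `age_years >= age_min` (possibly empty).
#' @export
subgroup_elderly <- function(records, age_min = 55) {
  dplyr::filter(tibble::as_tibble(records), .data$age_years >= age_min)
}
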