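# quick cohort constructor from parallel count vectors
make_cohort <- function(m, x, ...) {
  tibble::tibble(nodes_examined = as.integer(m),
                 nodes_positive = as.integer(x), ...)
}

# independent reference for P0(m): telescoping product of (beta+k)/(alpha+beta+k)
p0_product <- function(m, alpha, beta) {
  vapply(m, function(mm) {
    if (mm == 0) return(1)
    prod((beta + 0:(mm - 1)) / (alpha + beta + 0:(mm - 1)))
  }, numeric(1))
}

# direct zero-truncated log-likelihood over a (log alpha, log beta) grid;
# plain vector math so dense oracle grids stay cheap
grid_loglik <- function(cohort, la_grid, lb_grid) {
  agg <- stats::aggregate(list(n = cohort$nodes_examined),
                          by = list(m = cohort$nodes_examined,
                                    x = cohort$nodes_positive), length)
  m <- agg$m; x <- agg$x; n <- agg$n
  grid <- expand.grid(la = la_grid, lb = lb_grid)
  grid$ll <- vapply(seq_len(nrow(grid)), function(i) {
    a <- exp(grid$la[i]); b <- exp(grid$lb[i])
    lab <- lbeta(a, b)
    ll <- lchoose(m, x) + lbeta(a + x, b + m - x) - lab
    ll <- ll - log1p(-exp(lbeta(a, b + m) - lab))
    sum(n * ll)
  }, numeric(1))
  grid
}

# minimal survival record set with all pipeline fields
make_survival_records <- function(n, follow_up, status,
                                  nodes_examined = rep(5L, n),
                                  age_years = rep(50, n), ...) {
  tibble::tibble(
    patient_id = seq_len(n),
    histology_code = "8260/3", tumor_size_mm = 6, n_stage = "N0",
    m_stage = "M0", prior_malignancy = FALSE,
    age_years = age_years, sex = "female", race = "white",
    extrathyroidal_extension = FALSE, multifocality = FALSE,
    surgery_extent = "total", rai = FALSE,
    nodes_examined = as.integer(nodes_examined),
    nodes_positive = 0L,
    follow_up_months = follow_up,
    vital_status = status, ...
  )
}
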