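# nodalyield

Beta-binomial modeling of occult (residual) lymph-node metastasis in
papillary thyroid microcarcinoma (PTMC), and the survival analyses used to
judge whether that residual disease matters.

## The problem

Most PTMC patients who undergo central lymph node dissection have only a
handful of nodes examined. A patient whose examined nodes are all negative
may still harbor nodal micrometastasis — the staging is a false negative.
`nodalyield` quantifies that risk as a function of the number of nodes
examined, corrects the observed prevalence of nodal metastasis for these
false negatives, and determines how many nodes must be examined to call a
patient node-negative with a given confidence. A companion survival toolkit
(eligibility filtering, Kaplan–Meier/log-rank comparison at a yield cutoff,
restricted-cubic-spline Cox models) checks whether an inadequate node yield
— and hence possibly retained occult disease — is associated with overall
survival in registry-style cohorts.

It is intended for biostatisticians and clinical researchers working on
lymphadenectomy adequacy; everything runs on plain per-patient tables, and
seeded generators produce cohorts with the assumed structure so the whole
pipeline is testable without registry access.

## The model

For a patient with true nodal disease, each of `m` examined nodes is
positive with a patient-specific probability `p ~ Beta(α, β)`, so the
positive count is beta-binomial. The probability that all `m` examined
nodes are negative despite true disease is

    P0(m) = B(α, β + m) / B(α, β) = Π_{k=0}^{m-1} (β + k) / (α + β + k)

(α, β) are estimated by maximum likelihood from node-positive patients —
optionally with the zero-truncated likelihood conditioning on at least one
observed positive node. With disease prevalence π, the posterior
probability that an observed node-negative patient with `m` nodes examined
harbors occult disease is

    P(occult | all m negative) = π·P0(m) / (π·P0(m) + 1 − π)

Each yield stratum's observed positives `#TP_m` imply
`#FN_m = P0(m)·#TP_m / (1 − P0(m))` false-negative patients, and the
corrected prevalence is `Σ_m (#TP_m + #FN_m) / N`. Percentile bootstrap
(resampling patients, refitting per replicate) gives confidence intervals;
a Pearson chi-square with expected-count pooling assesses fit.

## Worked example

```r
library(nodalyield)

coh <- simulate_nodal_cohort(5399, prevalence = 0.389,
                             alpha = 2.5, beta = 6.21, seed = 2024)
fit <- fit_bb_mle(coh, truncated = TRUE)
fit
#> Beta-binomial nodal positivity fit (zero-truncated)
#>   alpha = 2.226 (SE 0.2455)
#>   beta  = 5.477 (SE 0.5159)
#>   log-likelihood = -2678 on 1581 patients

corrected_prevalence(coh, fit)
#> # A tibble: 1 × 4
#>   observed_prevalence corrected_prevalence total_fn n_patients
#> 1               0.297                0.385     476.       5399

occult_risk_profile(coh, fit, m_max = 7)
#> # A tibble: 7 × 6
#>       m p_all_negative detection_prob occult_prob  n_tp fn_count
#> 1     1          0.711          0.289       0.308    24     59.1
#> 2     2          0.529          0.471       0.249    60     67.4
#> ...
#> 7     7          0.181          0.819       0.102   138     30.4
```

Only 29.7% of the simulated patients show a positive node, but after
inflating each stratum by its implied false negatives the corrected
prevalence is 38.5% — recovering the generative 38.9% within sampling
error. The occult-disease probability for an observed node-negative patient
falls from 30.8% with one node examined to 10.2% with seven. At the
published point estimates (α = 2.50, β = 6.21, π = 0.389),
`min_nodes_for_confidence(2.5, 6.21, 0.389, 0.10)` returns 7: seven
examined nodes rule out occult disease with 90% confidence.

The survival side chains the same way:

```r
surv <- simulate_survival_cohort(15340, seed = 1)
rep <- run_survival(surv, cutoff = 7)
rep$log_rank$p_value      # adequate (>= 7) vs inadequate (1-6) yield
rep$p_overall             # spline Cox overall association of yield with OS
autoplot(rep$cox)         # adjusted hazard-ratio curve vs nodes examined
```

`autoplot()` methods exist for risk profiles, Kaplan–Meier curves and
spline Cox fits; `tidy()`/`glance()` for every fitted object. A thin
command-line front end with `simulate` / `fit` / `risk-table` / `survival`
subcommands lives at `inst/cli/nodalyield-cli.R` (flags `--config`,
`--seed`, `--out-dir`, `--log-level`; the config file is flat
`key: value` YAML whose keys are the argument names of the corresponding
`run_*()` function).

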