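---
title: "Modeling occult nodal disease and lymph node yield adequacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling occult nodal disease and lymph node yield adequacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodalyield)
```

## The model and its assumptions

Nodal staging after central lymph node dissection is a sampling problem:
a patient with true nodal metastasis can still show `m` negative nodes when
`m` is small. `nodalyield` models the positive-node count of a truly
diseased patient as beta-binomial — each node positive with a
patient-specific probability `p ~ Beta(α, β)`, nodes conditionally
independent given `p`. The probability that a diseased patient shows no
positive node among `m` examined is then

$$P_0(m) = \frac{B(\alpha, \beta + m)}{B(\alpha, \beta)}
        = \prod_{k=0}^{m-1} \frac{\beta + k}{\alpha + \beta + k},$$

strictly decreasing in `m`. Two assumptions are load-bearing and worth
stating plainly: all nodes within a patient are exchangeable (equal
involvement probability — biologically a simplification, but node yield
rather than node location dominates whether a positive node is missed),
and patients share a common Beta law for `p`. Lateral-compartment (N1b)
disease is outside the model entirely.

Given a disease prevalence $\pi$, Bayes' rule converts $P_0$ into the
quantity a clinician wants: the probability that an observed node-negative
patient nonetheless harbors disease,

$$P(\text{occult} \mid m \text{ negative nodes}) =
  \frac{\pi P_0(m)}{\pi P_0(m) + 1 - \pi}.$$

This conditional form is what `occult_probability()` implements. Its
unconditional complement $1 - P_0(m)$ — the chance that disease, when
present, is detected — is kept separately as `bb_detection_prob()`; the
two answer different questions and the package deliberately exposes both.
At the published point estimates (α = 2.50, β = 6.21, π = 0.389) the
conditional form yields 31.2%, 25.2%, 20.5%, 16.9%, 14.0%, 11.8% and 10.0%
at one through seven nodes examined, and `min_nodes_for_confidence()`
returns 7 at a 10% residual-risk threshold.

### False-negative correction

Within each yield stratum, the observed node-positive count `#TP_m`
underestimates the truly positive count by the odds factor of the miss
probability: `#FN_m = P0(m) · #TP_m / (1 − P0(m))`. Summing the inflated
positives over strata and dividing by the *fixed* total patient count gives
the corrected prevalence (`corrected_prevalence()`); it is capped at 1 with
a warning, since a noisy fit on a small stratum can overflow. Note the
correction does not depend on $\pi$, so a single pass suffices:
`occult_risk_profile()` defaults its prevalence to the cohort's own
corrected value, with no iteration.

## Fitting

`fit_bb_mle()` maximizes the likelihood over $(\log\alpha, \log\beta)$ —
the parameters are positive, and the log scale makes the optimization
unconstrained and well-scaled — with L-BFGS-B from $(0, 0)$, falling back
to a Nelder-Mead restart when a flat ridge aborts the line search. The
likelihood is computed on `(m, x)` aggregate counts (they are sufficient),
so a 200,000-patient fit costs the same as its ~100 distinct cells and
runs in milliseconds. Parameters are capped at $10^6$: a cohort whose
positive fractions are consistent with a point mass drives
$\alpha, \beta \to \infty$ at a fixed ratio, and hitting the cap raises an
explicit bounded-parameter warning rather than a silent pseudo-estimate.

Two likelihood variants are provided. The plain likelihood is the default;
the zero-truncated one conditions each record on $x \ge 1$ and is the
consistent choice for the default fitting subset — node-positive patients
with at least two nodes examined. That subset deserves a note: the
observed-negative majority mixes truly negative patients with
false-negative ones, so it cannot inform the Beta law directly without a
mixture treatment; restricting to patients with observed disease and
letting the truncated likelihood undo the selection is the cleanest
estimator of (α, β), and is what the package's recovery tests exercise.
A fit on node-positive patients with the *untruncated* likelihood is kept
available (flag `truncated = FALSE`) because the source tradition of this
estimator used it; for data simulated from the model it is mildly biased,
and the tests use the truncated form.

Uncertainty comes from `bb_bootstrap()`: patients resampled with
replacement, the full pipeline (fit, and where relevant prevalence
correction) recomputed per replicate, percentile 2.5/97.5 interval —
2,000 replicates by default. Replicates that fail to converge are dropped
and counted; more than 10% failures aborts. Goodness of fit (`bb_gof()`)
is a Pearson chi-square over `(m, x)` cells, pooling adjacent x-cells
within each yield stratum until the expected count reaches 5 (a trailing
underweight group merges backwards; still-small cells pool across strata),
with degrees of freedom `cells − 1 − 2` for the two estimated shapes.

## What the generators emulate

`simulate_nodal_cohort()` is the generative mirror of the model: disease
with probability π, `p ~ Beta(α, β)`, yield `m` from a configurable law,
`x ~ Binomial(m, p)` for diseased patients and 0 otherwise, with the latent
truth kept in a `.true_positive` column for oracle tests. The default
yield law is a shifted negative binomial `1 + NB(size = 2.5, μ = 7)`,
chosen because its quartiles are exactly 4/7/11 — the median (IQR) node
yield of 7 (4–11) typical of central dissection by high-volume surgeons;
a uniform law is available for clean closed-form checks.

`simulate_survival_cohort()` adds registry-style fields (ICD-O-3 histology,
tumor size, stage, demographics, surgery, RAI) and exponential event times
under proportional hazards, `hazard = λ₀ · exp(Σ effectᵥ · v)` with age
centered at 47 so λ₀ refers to a typical patient. Defaults define the
emulated study conditions: λ₀ = 2.5·10⁻⁴ per month (≈98.5% 5-year OS, the
magnitude seen for PTMC), a modest age effect (HR 1.08/year) and female
advantage (HR 0.7), *no* effect of node yield (matching the null finding
the survival stage is designed to probe), and staggered entry over a
126-month horizon, giving uniform censoring times and a median follow-up
near 63 months with IQR ≈ 32–95. Event times are exponential rather than
Weibull because every oracle then has a closed form; covariate joint
distributions are simple product laws and make no attempt to mimic a real
registry — so passing tests certify the estimators and the pipeline's
wiring, not any claim about real SEER covariate structure, non-proportional
hazards, or informative censoring.

## Survival verification pipeline

`eligibility_filter()` applies, in a fixed order, the registry inclusion
rules (papillary histology codes, ≤10 mm, M0, no prior malignancy, no N1b,
≥1 node examined), attributing each exclusion to the first violated rule so
the audit tally always sums. `stratify_by_yield()` splits at ≥7 vs 1–6
nodes; `km_estimate()`/`log_rank_test()` wrap the `survival` package's
product-limit and log-rank machinery (the hand-verifiable parts are tested
against hand-computed tables); `subgroup_elderly()` keeps patients aged
≥55, boundary inclusive, since nodal disease plausibly matters most there.

The adjusted analysis is a Cox model with the node yield — and other
continuous covariates — entered as restricted cubic splines in Harrell's
parameterization (linear tails, `k − 1` basis columns, nonlinear columns
normalized by the squared knot range). The basis, the fixed-percentile
knot tables (10/50/90 for three knots; 5/35/65/95; 5/27.5/50/72.5/95),
the AIC-based choice among 3–5 knots (ties to fewer), the joint Wald test
on the main spline block (likelihood-ratio variant behind a flag) and the
delta-method hazard-ratio curve anchored at `HR(ref) = 1` are all
implemented and tested in-repo against independently coded truncated-power
oracles; only the partial-likelihood maximization itself delegates to
`survival::coxph()` with the Efron tie correction — the accepted default
for registry data recorded in whole months. Mostly-zero covariates (the
positive-node count in a largely node-negative cohort) have tied
percentile knots; rather than abort the adjusted model, such covariates
fall back to a linear term with a message. Complete cases only; the
dropped count is recorded on the fit.

## Numerical choices and degenerate inputs

* Every Beta-function ratio is a log-gamma difference; nothing evaluates
  `beta()` directly, so large `m` and extreme shapes stay finite.
* `bb_pmf(0, 0, ·) = 1` (empty product) and
  `occult_probability(0, ·) = π` exactly — no information, posterior =
  prior.
* Optimizer: L-BFGS-B, `factr = 1e7`, bounds `[1e−8, 1e6]` on each shape;
  non-convergence after the Nelder-Mead restart is an error, never a
  silent result. Standard errors via the numerically differentiated
  Hessian on the log scale, delta-transformed.
* Bootstrap intervals are percentile type-7 quantiles; a single replicate
  collapses the interval to that value.
* All generators take a mandatory seed, restore the caller's RNG state,
  and are byte-for-byte reproducible; the pipeline derives per-stage
  subseeds from one global seed so stages can be re-run independently.
* Knot selection errors out only when *no* candidate count is fittable
  (e.g. a two-valued main variable).

## Test scale

The suite verifies closed forms exactly and statistical properties at
sizes chosen to keep Monte-Carlo error well inside the asserted margins:
parameter recovery at 200,000 patients (2% relative error), prevalence
recovery at 100,000 (±0.01), bootstrap coverage with 100 outer
repetitions of 200-replicate intervals on 2,000-patient cohorts (coverage
asserted ≥ 89/100, the lower edge of the central 95% range of
Binomial(100, 0.95)), null-uniformity of the log-rank and spline-Cox
p-values over 200 simulations checked by Kolmogorov–Smirnov, and GOF
calibration over 200 refits.

## Known limitations

* The exchangeable-nodes assumption ignores nodal topography and surgeon-
  or hospital-level heterogeneity in dissection thoroughness.
* The corrected prevalence treats (α, β) as known when inflating strata;
  parameter uncertainty enters only through the bootstrap, not the point
  correction.
* The survival generator cannot certify behavior under non-proportional
  hazards or informative censoring, and recurrence outcomes are out of
  scope (overall survival only).
* Subgroup refits (e.g. by thyroiditis status) are supported generically
  by filtering the cohort before `fit_bb_mle()`, but no subgroup-specific
  defaults ship with the package.
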