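---
title: "Modelling longitudinal weight trajectories with panel-observed multistate Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling longitudinal weight trajectories with panel-observed multistate Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtmsm)
```

## The model

Primary-care weight data are *panel data*: a patient's weight is recorded
only when they happen to visit, so we observe their current weight status at
irregular times, never the moment a threshold was crossed.  `wtmsm`
categorises weight relative to the patient's baseline into five ordered
states — 1: ≥10% loss, 2: 5–10% loss, 3: within ±5% of baseline,
4: 5–10% gain, 5: ≥10% gain — and models movement between *adjacent* states
as a continuous-time Markov chain.  The transition intensity from state $r$
to adjacent state $s$ for a patient with covariate vector $z(t)$ is

$$q_{rs}(z) = q^0_{rs}\, \exp\{\beta_{rs}^\top z\},$$

a proportional-intensity form: $q^0_{rs}$ is the baseline rate (per day) and
$\exp(\beta)$ are hazard ratios.  Covariates comprise fixed demographics and
time-varying weight-management-treatment (WMT) exposures: nutrition
counseling in the prior 90 days, early/late meal-replacement program
participation, any anti-obesity medication (GLP1RA pooled in), and binned
time since bariatric surgery.

Because exposures are piecewise-constant with changepoints known exactly
from event data, the transition-probability matrix over an observation
interval is an ordered product of matrix exponentials,
$P = \prod_j \exp\{Q(z_j)\,\Delta t_j\}$, which is *exact* under the model —
no approximation is introduced by interval splitting.  The likelihood of a
patient's observation sequence multiplies the $(s_i, s_{i+1})$ entries of
these interval matrices, and the total log-likelihood is maximised by BFGS
over $(\log q^0, \beta)$.  A "value-at-interval-start" compatibility mode
(`timing = "start"` in `msm_data()`) is provided because analysis tooling
conventions differ; changepoint splitting is the default since it is exact.

Standard errors come from the inverse of the numerically differentiated
observed information at the optimum.  Confidence intervals for derived
quantities (state probabilities, AMEs, scenario summaries) use multivariate
normal simulation from $\hat\theta, \hat\Sigma$ with percentile intervals
(`B = 1000` by default; the seed is an explicit argument).

### Numerical implementation

The likelihood is evaluated in compiled code.  Matrix exponentials are
computed through an eigendecomposition cache keyed on the rate vector:
adjacent-state (birth–death) generators with positive rates are
diagonalisable, so $\exp(Qt) = V e^{\Lambda t} V^{-1}$ after one
decomposition per distinct intensity matrix.  Ill-conditioned eigensystems
fall back to Padé scaling-and-squaring (`arma::expmat`), and the plain-R
reference path (`interval_probability()`) uses `Matrix::expm` throughout, so
the two routes cross-check each other in the test suite.  The analytic
likelihood gradient uses the Fréchet derivative of the matrix exponential in
the eigenbasis; each parameter direction is rank-one, which reduces the
per-segment cost to a handful of bilinear forms.  Tiny negative entries from
the eigenbasis reconstruction are clamped to $[0,1]$ and rows renormalised;
a zero transition probability yields a log-likelihood of $-\infty$ rather
than an error, so the optimiser backs away from impossible configurations.

### Boundary and window conventions

Cut points follow the "10% or greater loss" / "5% or greater gain" phrasing:
loss thresholds are inclusive on the loss side ($w \le 0.90b$ is state 1,
$w \le 0.95b$ state 2), gain thresholds inclusive on the gain side
($w \ge 1.05b$ state 4, $\ge 1.10b$ state 5), and the stable state is the
open interval.  Tie handling at exact thresholds is not standardised in the
field; this convention is documented in `derive_weight_states()` and the
synthetic generator samples weights on open intervals so boundary cases
never arise in simulated data.  Exposure windows are left-closed: a
dietitian visit on day $e$ keeps `nutrition_90d` on over $[e, e+90)$, so an
event "today" counts today and no changepoint is double-counted.
Meal-replacement "months 1–6" is implemented as days 0–183 since the first
program visit and "months 6–24" as days 184–730 (30.5-day months;
calendar months are patient-specific).  Surgery bins change at 91, 181 and
365 days after surgery.

## The synthetic-data generator

No patient-level data are distributable, so the package ships a generator
(`simulate_population()`) whose defaults emulate the study conditions of a
primary-care obesity cohort:

* **Baseline intensities.**  Calibrated once so that a reference patient
  without WMT exposure has one-year occupancy close to the field-typical
  pattern: ≈5% at ≥10% loss, ≈10.6% at 5–10% loss, ≈67.7% stable, ≈11.6% at
  5–10% gain, ≈4.8% at ≥10% gain (per-day rates in `default_true_params()`).
* **WMT effects.**  Loss-direction hazard ratios ordered as nutrition <
  medication < meal replacement < surgery, with gain-direction ratios below
  one — the qualitative pattern reported for these treatments.
* **Uptake.**  Defaults of 6.3% (nutrition), 0.4% (meal replacement), 2.6%
  (medication) and 1.0% (surgery), reflecting the low utilization such
  cohorts show.  Uptake is *confounded* by construction — logistic in
  baseline BMI, comorbidity, sex and age — precisely so the propensity
  matching stage has selection bias to remove.
* **Observation.**  A homogeneous Poisson visit process (default 6
  visits/year over 730 days of follow-up); weights observed at visits are
  drawn uniformly on the open relative-weight band of the latent state
  (open-ended bands truncated at ±20%), so states derived from emitted
  weights reproduce the latent path exactly.
* **Plumbing for the cohort rules.**  Two prior primary-care visits ≥358
  days apart with pre-baseline BMI below 30, a small fraction (2%) failing
  the visit rule, and rare truncation events (death, pregnancy, metastatic
  cancer; 1%) exercise eligibility, truncation and cleaning logic.

What it does **not** emulate: measurement error in weights, EHR coding
noise, visit processes correlated with weight change (informative
observation), drug-specific dose effects, or realistic anthropometric
drift.  Passing tests therefore demonstrate that the *machinery* is correct
and that parameters generating the data are recovered — not that the model
assumptions hold in any particular real cohort.

## Analysis pipeline

`build_panel()` applies eligibility (the 358-day visit rule at the first
qualifying weight, ≥2 BMI readings in [12, 100], truncation), anchors each
trajectory at the first obese (BMI ≥ 30) weight, excludes patients with WMT
exposure before baseline, and codes exposure timelines.
`fit_propensity()` + `match_stratified()` select unexposed comparators 1:1
within the 16 sex × race (majority/nonmajority) × ethnicity × any-condition
strata by minimum-total-distance assignment on |logit propensity|
differences — optimal rather than greedy matching, solved exactly per
stratum by a shortest-augmenting-path algorithm, with no caliper (matching
every exposed patient mirrors the study design this emulates).
`balance_table()` reports standardized mean differences with the usual
|SMD| < 0.1 adequacy criterion.

`compute_utilization()` reports prospective WMT use among patients with a
full year of recorded follow-up on both sides of the index weight (per-patient
flags are attached for marginal models), and `two_year_loss_share()` reports
the fraction of obese patients achieving ≥5% loss two years on under *both*
candidate denominators — all obese patients at the index year, and only
those with follow-up weight data — because the natural denominator of that
share is genuinely ambiguous.

Cross-sectional year contrasts use a hand-rolled GEE with exchangeable
working correlation (moment estimators for the dispersion and correlation,
HC0-style sandwich covariance clustered on patient) and average marginal
effects by counterfactual averaging with delta-method intervals.  Age enters
linearly in adjusted models; splines were considered and rejected since the
contrast of interest is the year term.

One-year predictions (`state_probabilities()`) hold an idealized exposure
over the horizon; program phases and surgery bins advance deterministically
(a 364-day horizon ends in the 181–364 surgery bin — the ≥365 bin is never
reached, which is the documented default).  Idealized meal replacement is
early-phase for days 0–183 then late-phase; an `mr_mode = "early"`
alternative is flagged in the profile.  Population counterfactuals propagate
each patient's *actual* first-year exposure segments, zero WMT components
one at a time or all at once, and summarise: AME (observed minus no-WMT mean
probability of ≥5% loss), attributable fraction (AME / observed mean),
linear fold-increase scenarios (mean at multiplier $m$ equals no-WMT mean
$+\,m\times$AME; `fold_means` selects whether "$k$-fold" maps to $m=k$ or
$m=k+1$, both readings being defensible), a resampling alternative that
copies exposed patients' histories onto sampled unexposed patients, and the
tipping point — the smallest multiplier at which the ≥5%-loss mean exceeds
the ≥5%-gain mean with a CI excluding zero.

### Per-transition covariate masks

Not every exposure coefficient is estimable on every transition: late-phase
meal replacement barely occurs while patients sit in gain states, and
post-90-day surgery exposure is concentrated in loss states.
`default_wmt_structure()` encodes the pooling used in practice — fine
surgery bins only on transitions out of loss states, a pooled ">90 days"
level out of the baseline state, only the 0–90 bin out of gain states, and
late-phase meal replacement only out of loss states; everything is
configurable through the mask matrix of `transition_structure()`.

## Problem sizes and design choices in the shipped checks

The test suite and `scripts/acceptance.R` rerun every stage on generated
data.  Chosen sizes: Monte-Carlo oracles use $10^5$ Gillespie paths
(acceptance) or $2\times10^4$ (unit tests) with 3-standard-error bands; the
parameter-recovery experiment simulates 2000 patients with ~6 visits each
over two years, loss-side hazard ratio 2.0 and gain-side 0.7, with 12 (test
suite) or 16 (acceptance script) replicates; the end-to-end pipeline in the
acceptance script simulates 6000 patients.  The recovery experiment raises
WMT uptake to ~45% so that every one of the eight transitions accrues
exposed observation time — at realistic single-digit uptake the
gain-state-under-exposure coefficients are practically unidentified with
n = 2000, which is a property of the design, not a defect of the estimator
(the pipeline run at realistic uptake correspondingly reports wide or
unavailable intervals for those cells, mirrored by the masks above).

## Known limitations

* The Markov assumption: transition intensities depend on the current state
  and current covariates only, not on time since entering the state.
* States derived from single weight measurements are treated as exact;
  misclassification (hidden-Markov extensions) is out of scope.
* Death and other truncation events censor follow-up rather than entering
  the model as absorbing states.
* Wald/percentile intervals are uncorrected for multiplicity.
* The GEE implementation covers the Gaussian-identity and binomial-logit
  cases with exchangeable correlation used here, not arbitrary families or
  working structures.
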