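---
title: "A literature-coefficient risk model for diabetic retinopathy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A literature-coefficient risk model for diabetic retinopathy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drrisk)
```

## The model and its assumptions

`drrisk` implements a Rothman–Keller style risk assessment model for
diabetic retinopathy (DR) among type 2 diabetics. Instead of fitting a
logistic regression to one cohort, the linear predictor is assembled from
published meta-analytic effect estimates: each factor's coefficient is the
natural log of its pooled odds ratio, and the intercept is the log-odds of
the local DR prevalence *p*,

$$\mathrm{logit}(P) = \ln\frac{p}{1-p} + \sum_i \beta_i X_i,
\qquad \beta_i = \ln(\mathrm{OR}_i),$$

so that a patient with every factor at baseline is predicted exactly the
local base rate. The headline output is the relative-risk score
$\mathrm{LP} = P/p$, read as "LP times the risk of the local diabetic
population".

This construction leans on strong assumptions worth keeping in view:

- **Transportability**: pooled ORs estimated in heterogeneous study
  populations are treated as exchangeable log-odds effects in the local
  population.
- **Additivity / independence of effects**: factors enter additively on
  the logit scale with no interactions, and the ORs — each marginal to its
  own meta-analysis — are combined as if mutually adjusted.
- **Prevalence anchoring**: the intercept calibrates the *average*
  patient, not the full risk distribution; predicted probabilities are not
  otherwise calibrated against observed incidence (a stated non-goal).

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `prevalence` | 0.278 | proportion | local DR prevalence among type 2 diabetics; override per site |
| coefficient `mode` | `"printed"` | — | `"printed"` = the published 13-value set; `"derived"` = `ln(OR)` recomputed from the evidence table |
| FPG threshold | 6.1 | mmol/L | fasting plasma glucose "elevated" above this (impaired-fasting-glucose cut) |
| HbA1c threshold | 6.5 | % | "elevated" at or above this (diagnostic cut) |
| `lp_cutoff` | 2.24 | fold vs prevalence | published high-risk LP cut-off |
| `p_star` | 0.5 | probability | dividing node on the simulated sorted curve |
| simulation marginals | 0.5 per binary level; uniform over the 3 lipid levels | — | the original draw's marginals are unreported; the uninformative default is explicit and configurable |
| cohort `control_marginals` | 0.3 exposure per factor | proportion | plausible background exposure rates; configurable |
| cohort `effect_scale` | 1 | — | multiplier λ on the log-OR scale; 0 = null cohort |

The two classification rules deliberately differ at the boundary: under
`p_half` a probability of exactly 0.5 is **high** risk (the node belongs
to the high side), while under `lp_cutoff` an LP exactly at the cut-off is
**low** (the published rule is "greater than 2.24"). Both conventions are
frozen in tests.

The LP cut-off 2.24 is shipped as a documented constant, not derived:
0.5/0.278 ≈ 1.80, so the published 2.24 does not follow from the P = 0.5
node at the default prevalence, and no derivation is available to
reimplement. `find_cutoff_node()` reports the LP equivalent of whatever
node it locates, which makes the discrepancy visible rather than hiding
it.

## Printed versus derived coefficients

Two coefficient sets coexist by design. The **printed** set is the
published 13-value set (intercept −0.949) and is the default, because the
published worked example — logit 1.177, LP 2.75 — is a digit-exact sum of
those printed values and is the package's primary regression anchor. The
**derived** set recomputes everything from the evidence table. A
reconciliation report compares them term by term and, with the shipped
table, flags exactly two discrepancies:

```{r}
cs <- build_coefficient_set(prevalence = 0.278, mode = "printed")
subset(cs$reconciliation, flagged)
```

- **Smoking**: the printed −0.083 is not `ln` of the table's OR 0.68
  (= −0.386), and that OR also falls outside its own printed CI
  (0.86–0.98) — the evidence row is stored as printed and flagged, never
  silently "fixed" (−0.083 would correspond to OR ≈ 0.92, roughly the
  CI's geometric mean, but guessing is not reconstruction).
- **Intercept**: printed −0.949 versus `ln(0.278/0.722)` = −0.954,
  consistent with the source having used a prevalence nearer 27.9%. Both
  values are retained; `"printed"` keeps −0.949.

One further erratum: the myopia coefficient appears in the source once as
−0.357 and once as −0.375; `ln(0.70)` = −0.357, so −0.357 is canonical and
the other value is treated as a typo.

Coefficients are rounded half-to-even at 3 decimals, the published
presentation precision; `round()` in R implements exactly this rule.

## The Monte Carlo dividing node

`run_cutoff_simulation()` draws independent exposure profiles from
per-factor marginals, scores them, sorts the predicted probabilities
ascending, and reports the first rank reaching `p_star` (default 0.5),
with `all-below` / `all-above` sentinels when the curve never or always
reaches it. The default draw of 1000 profiles matches the original
procedure's size; seeds are recorded in the returned config so any run is
reproducible from its own metadata.

## What the synthetic cohort emulates — and what it does not

The original external validation used 60 questionnaire patients (30 DR,
30 non-DR) that are not deposited, so its AUC of 0.912 and
sensitivity/specificity of 0.867 **are not reproduction targets**: any
synthetic cohort tuned to match them would be curve-fitting, not
validation. Instead `generate_cohort()` provides a principled stand-in:

- Controls draw each factor independently from baseline marginals
  (default 0.3 exposure).
- Cases draw from odds-tilted marginals: for a binary factor with control
  exposure probability $q_0$ and odds $o_0 = q_0/(1-q_0)$,
  $q_1 = \mathrm{OR}^\lambda o_0 / (1 + \mathrm{OR}^\lambda o_0)$, so the
  population exposure OR is exactly $\mathrm{OR}^\lambda$. The three-level
  lipid-duration factor uses the multinomial analogue (each non-baseline
  level's odds against "none" multiplied by its $\mathrm{OR}^\lambda$),
  which preserves the level-vs-baseline ORs exactly while keeping the
  levels mutually exclusive, so generated cohorts are directly scoreable.

What passing tests on these cohorts show: the generator hits its target
ORs (each factor within 3 SE at 50,000 per arm), null cohorts are
undiscriminating (AUC ≈ 0.5 at 2,000 per arm), and model discrimination
rises with effect scale. What they do **not** show: performance on real
patients. Real exposures are correlated (the generator draws factors
independently within group), real continuous markers are measured rather
than generated directly in their binarized state, and the real cohort's
exposure distributions are unreported, so no default can claim
faithfulness.

## Validation machinery

ROC/AUC, sensitivity and specificity are implemented directly: thresholds
sweep the unique score values descending with ties grouped (one point per
unique score), positives predicted at score ≥ threshold, and AUC taken as
the trapezoidal area — which equals the Mann–Whitney concordance with
ties counted one half. The tests hold the implementation to that identity
with a brute-force pairwise oracle (tolerance 1e−10) and cross-check
against `pROC` where available; the implementation itself never calls an
external ROC routine. A Youden-optimal point is reported alongside any
requested fixed threshold, each clearly labelled, since it is unknown
which the original operating point was.

## Numerical choices and degenerate inputs

- Inverse logit goes through `plogis()`, which saturates smoothly at
  double-precision limits rather than overflowing.
- AUC invariance under monotone transforms holds exactly in real
  arithmetic, but two analytically equal logit sums can differ in the last
  bit and then collide after the inverse-logit map, regrouping ties; the
  invariance test therefore allows a 1e−4 tolerance.
- Empirical 2×2 odds ratios apply the Haldane–Anscombe 0.5 correction
  whenever a cell is zero, with a `corrected` attribute so the caller can
  tell.
- Degenerate configurations fail loudly: empty evidence tables, ORs ≤ 0,
  prevalences outside (0,1), single-class ROC labels, marginals that do
  not sum to 1, and odds-tilting a baseline probability of 0 or 1 are all
  errors, not silent NAs.

## Problem sizes

The test suite runs at sizes chosen to make each check statistically
decisive while staying desk-scale: 1000-profile cut-off simulations
(matching the original draw), 2,000-per-arm cohorts for the null-AUC band
(±0.05 comfortably exceeds Monte Carlo noise there), 50,000 per arm for
parameter recovery (3-SE bands of a few percent), and 10,000-profile
draws for stochastic monotonicity checks at two seeds.

## Known limitations

- No uncertainty propagation: CI bounds ride along in the evidence table
  but never widen the score (a stated non-goal).
- No calibration or time-to-event dimension; the score is cross-sectional.
- Within-group factor independence in the synthetic cohort understates
  real-world exposure correlation, typically inflating apparent
  discrimination at λ = 1 relative to a correlated world.
- The 2.24 LP cut-off is inherited, not derivable from the shipped
  machinery; sites should consider re-deriving an operating point from
  local data via `youden_point()`.
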