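---
title: "Screening CBC trios for IV fluid contamination: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening CBC trios for IV fluid contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbccontam)
```

## The problem

A blood specimen drawn from, or downstream of, an intravenous catheter can
be admixed with the running IV fluid. Because no IV fluid carries cells or
hemoglobin, a contaminated complete blood count (CBC) shows a proportional
drop in hemoglobin (Hgb), platelets (Plt), and white cells (WBC) that
*resolves* on the next properly collected specimen — an
anomaly-with-resolution pattern. When the artifactual Hgb falls below a
transfusion decision limit, the error can trigger a red-cell transfusion
the patient did not need.

There is no gold-standard label for these events in historical data, which
motivates the approach implemented here: **train on simulation, screen
retrospectively**. Contamination has a known, simple generative model —
linear dilution — so labeled training data can be manufactured from real
(or realistic) serial results, and a supervised classifier trained on that
simulation can then audit a full year of results at scale.

## The dilution model

For analyte $a$ with patient value $v_a$ and fluid concentration $f_a$,
contamination at mixture ratio $\rho \in [0, 1)$ (the volume fraction of
fluid in the specimen) yields

$$x_a = (1 - \rho)\,v_a + \rho f_a.$$

For CBC analytes $f_a = 0$ for every fluid, so the panel scales uniformly
by $(1-\rho)$ and fluid identity is unrecoverable from a CBC alone. For
chemistry panels the fluid matters: normal saline *raises* sodium and
chloride while diluting everything else; D5W floods glucose. The bundled
fluid table (`fluid_compositions()`) covers the common fluids in reporting
units. Two dilutions compose as
$1-(1-\rho_1)(1-\rho_2)$; this identity and the $\rho = 0$ identity are
asserted exactly in the test suite.

Simulated severities are drawn from a Beta(1.5, 8) truncated to
$[0.02, 0.95]$: mostly mild events with a heavy tail, sampled by inverse
CDF so truncation is exact. The shape is a package default (the
distribution of real events is not identifiable from retrospective data);
everything about it is configurable via `mixture_ratio_dist()`.

## CBC trios and features

A *trio* is a current CBC plus its most recent prior and earliest
subsequent complete CBC within 48 h (`build_trios()`). Draws missing
either neighbour are not scoreable — this is what restricts the screen to
mostly-inpatient specimens. Values reported as `">1500"` or `"<0.1"` are
coerced to their bound; non-numeric strings are dropped. Two decisions
here were genuinely open and are exposed as switches:

* *post draw*: "most recent subsequent" is ambiguous; the default takes
  the **earliest** subsequent draw (the next result a clinician saw),
  `post_rule = "latest"` takes the other reading.
* *deltas*: the default stores **absolute** signed changes
  (`current − prior`, `post − current`, in reporting units);
  `delta_mode = "relative"` divides by the reference value.

The model features are the nine raw values (per analyte: current,
delta-prior, delta-post), the leading $k = 5$ principal components of
those features (standardized, fit on the simulated 50%-contaminated
training set), or both (default). Because dilution is linear and
proportional across analytes, PC1 of the simulated training set aligns
with the anomaly-with-resolution axis — the test suite requires
$|r(\mathrm{PC1}, \text{label})| \ge 0.5$ and the explainability module
confirms PC1 ranks among the top contributors. Raw features are kept
alongside the components because residual biological and analytic
variation still carries signal. Loadings are sign-fixed (largest loading
positive, then PC-label correlation non-negative) so runs are exactly
reproducible.

## Detector, threshold, severity

The classifier is a gradient-boosted tree ensemble (xgboost) with
deliberately shallow trees and aggressive subsampling — depth 3, learning
rate 0.1, 300 rounds, 80% row and column subsampling, single-threaded for
determinism — to resist overfitting simulation artifacts. Cross-validation
is **grouped by patient**: a patient's overlapping trios never straddle a
fold boundary, and the PCA transform is refit inside each training fold.
The shipped bundle is refit on the full training set.

The operating threshold defaults to 0.75, and `calibrate_threshold()`
re-derives it as the smallest grid point (step 0.005) whose empirical
positive predictive value exceeds 0.80 — the smallest valid threshold
maximizes sensitivity subject to the PPV constraint. auROC is computed as
the Mann–Whitney pairwise-concordance statistic (ties get half credit) and
auPR by stepwise precision–recall integration with tied scores entering
as blocks; both are verified against brute-force enumeration.

Severity is estimated by a companion gradient-boosted *regressor*
(`train_ratio_regressor()`, depth 4, 400 rounds) on the same features,
trained on the simulated positives with their known $\rho$, rather than by
the closed-form inversion $\rho = 1 - x/v$ — the patient's uncontaminated
baseline $v$ is never observed noise-free. Estimates are clipped to
$[0, 0.99]$. At the default study scale the regressor recovers held-out
severities with RMSE $\le 0.05$ and $|$bias$| \le 0.02$ over
$\rho \in [0.05, 0.6]$, and is strictly monotone across a noise-free
$\rho$ grid.

## Transfusion rule set and BMP cross-check

A transfusion is *potentially unnecessary* when all three hold: (1) the
current CBC was predicted contaminated; (2) the post-transfusion Hgb
exceeds 8 g/dL (above the usual empiric-transfusion justification); (3)
the post Hgb exceeds both the prior and the current Hgb (excluding
ongoing blood loss). Inequalities are strict — a post Hgb of exactly
8.0 g/dL is not flagged. Transfusions match the trio whose current draw is
latest before administration; context odds ratios use a Haldane–Anscombe
0.5 correction when a cell is empty.

As orthogonal evidence, predicted-contaminated CBCs with
$\hat\rho > 0.10$ are paired to any basic metabolic panel collected
within 5 minutes, and BMP severities are estimated by the same regression
machinery retrained on simulated BMP dilutions with a configured fluid
(default normal saline). BMP tubes are drawn before CBC tubes on a typical
collection, so co-contaminated BMPs tend to run slightly *higher* — the
synthetic generator encodes this as
$\rho_{BMP} = \rho_{CBC} \cdot U(1.0, 1.3)$ for jointly contaminated
draws, and the cross-check reports the OLS slope and $R^2$ of
$\hat\rho_{BMP}$ on $\hat\rho_{CBC}$ among co-contaminated pairs
(undefined below 3 pairs; the "BMP evidence" cutoff mirrors the CBC 0.10
filter since no independent convention exists).

## Explanations

Per-prediction attributions use the exact tree-path Shapley algorithm on
the **margin (log-odds) scale**, where additivity is exact for tree
ensembles: base value plus contributions reproduces the margin output to
numerical precision, a constant feature receives exactly zero, and a
single stump matches the two-player closed form — all asserted in tests.
Global importance ranks features by median absolute contribution with
alphabetical tie-breaks.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` produces serial results with the structure the
pipeline assumes:

| element | default | basis |
|---|---|---|
| Hgb baseline | Normal(11.5, 2.2) g/dL, truncated \[3, 20\] | inpatient-plausible marginal |
| Plt baseline | lognormal, median 220 ×10³/µL, GSD 1.6 | idem |
| WBC baseline | lognormal, median 8 ×10³/µL, GSD 1.7 | idem |
| within-patient SD | Hgb 0.35 g/dL; Plt 0.09, WBC 0.11 (log) | within-subject biological variation estimates (CV ≈ 3% / 9% / 11%) |
| lag-1 autocorrelation | 0.85 | short-interval serial stability; see below |
| analytic CV | Hgb 1%, Plt 4%, WBC 3% | modern analyzer imprecision |
| draw cadence | gamma, mean 12 h | inpatient phlebotomy rhythm |
| transfusion response | +1.0 g/dL per unit, before noise | conventional rule of thumb |
| bleed mimicker | 2% of patients, −3 g/dL, no rebound | stresses specificity |

Serial values follow a stationary AR(1) around the patient baseline (log
scale for Plt/WBC). The between/within split and the autocorrelation are
not identifiable from any published table; the within-patient SDs follow
published biological-variation estimates, and the autocorrelation and
analytic CVs were fixed so that the cross-validated separability of
simulated dilutions on the synthetic cohort lands where a well-behaved
simulation-trained delta-check pipeline is expected to operate (mean CV
auROC ≈ 0.99); they were set once and are plain `cohort_config()` fields.

The generator deliberately omits: correlated multi-analyte physiology
(sepsis, marrow suppression), fluid resuscitation and hemoconcentration
(the classic mimickers of — and covers for — true contamination),
diagnosis-specific trajectories, pediatric ranges, and hematocrit.
Passing tests on this cohort therefore demonstrate *internal* correctness
of the pipeline under its own generative assumptions, not real-world
operating characteristics: in particular, sensitivity on clean linear
dilutions (~0.9 at threshold 0.75) is far above what expert-labeled real
data support at the same threshold, because real contamination is messier
than its simulation. The end-to-end audit consequently predicts ~2.7–3.5%
prevalence at a 2% injected rate (detected injections plus a 1–1.6%
false-positive floor from chance concordant dips), at the upper edge of
the plausibility band around the injected rate.

## Numerical and bookkeeping choices

* Timestamps are minute-resolution UTC; exact ties are broken by an
  insertion sequence number (latest report wins).
* Dilution never re-rounds to analyzer reporting precision by default —
  rounding discards signal; censored-string emission is configurable.
* The 48-h window is boundary-inclusive.
* All stochastic entry points take integer seeds, restore the caller's
  RNG state, and xgboost runs single-threaded, so identical configuration
  reproduces every output bit for bit.
* Study sizes used by the packaged checks: ~22,000 trios (5,000 synthetic
  patients) for detector cross-validation; 10,000/~2,000 train/held-out
  trios for severity recovery; 1,200 + 1,500 patients for the end-to-end
  audit. All are `cohort_config()`/`audit_config()` fields.

## Limitations

The screen is retrospective by construction — it needs the *post* result,
so it cannot prevent an unnecessary transfusion, only quantify and
localize the problem. Severity estimates below $\rho \approx 0.05$ are
not separable from biological noise. The transfusion rule set encodes one
defensible definition of "potentially unnecessary"; boundary cases
(post-Hgb exactly 8 g/dL, multi-unit episodes assessed independently) are
documented decisions, not clinical judgments. Real-data validation —
expert chart review, paired-panel confirmation beyond the synthetic
cross-check, prospective evaluation — is outside what a synthetic cohort
can establish.
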