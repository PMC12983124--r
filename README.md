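# cbccontam

Retrospective screening of complete blood count (CBC) results for IV fluid
contamination, and auditing of the red-blood-cell transfusions those
contaminated results may have triggered.

## The problem

Specimens drawn from or downstream of an intravenous catheter can be
admixed with the running fluid. No IV fluid carries cells or hemoglobin,
so a contaminated CBC shows a proportional drop in hemoglobin (Hgb),
platelets (Plt), and white cells (WBC) that rebounds on the next properly
collected specimen — an *anomaly-with-resolution* pattern. When the
artifactual Hgb dips below a decision limit, a patient may receive a
transfusion they did not need. There is no gold-standard retrospective
label for these events, so the package trains on *simulated* contamination
instead: dilution has a known generative model,

    x_a = (1 - rho) * v_a + rho * f_a

for analyte `a`, patient value `v_a`, fluid concentration `f_a`, and
mixture ratio `rho` (the volume fraction of fluid in the specimen; `f_a = 0`
for all CBC analytes). Labeled training data are manufactured by diluting
the *current* result of a random half of observed CBC "trios"
(prior/current/post within 48 h) at severities drawn from a truncated
Beta(1.5, 8) on [0.02, 0.95].

The pipeline, intended for clinical-laboratory informaticists and patient
blood management teams:

1. **trio building** — censored-value coercion (`">1500"` → 1500), 48-h
   neighbor attachment, delta computation (`build_trios()`);
2. **detection** — gradient-boosted trees (shallow, subsampled) on raw
   features plus the leading principal components of the simulated
   training set, 5-fold patient-grouped cross-validation, operating
   threshold 0.75 calibrated to PPV > 0.80 (`train_detector()`,
   `calibrate_threshold()`);
3. **severity** — a boosted regressor estimates `rho` for flagged panels
   (`train_ratio_regressor()`, `estimate_mixture_ratio()`);
4. **transfusion audit** — a transfusion is *potentially unnecessary* when
   the preceding CBC was predicted contaminated, the post-transfusion Hgb
   exceeds 8 g/dL, and it exceeds both the prior and current Hgb
   (`assess_transfusions()`);
5. **orthogonal evidence** — basic metabolic panels drawn within 5 min of
   a flagged CBC are scored with a BMP-feature severity model and the two
   estimates compared (`pair_cbc_bmp()`, `crosscheck()`);
6. **explanations** — exact tree-path Shapley attributions on the margin
   scale (`attribute()`, `global_importance()`);
7. **synthetic cohort** — a seeded generator of serial CBC/BMP results and
   transfusion records with within-patient AR(1) correlation, so the whole
   pipeline runs and is tested without institutional data
   (`generate_cohort()`).

## Worked example

```r
library(cbccontam)

cfg     <- cohort_config(n_patients = 800, seed = 2025)
cohort  <- generate_cohort(cfg)
tx      <- generate_transfusions(cohort, cfg)   # adds Hgb increments
trios   <- build_trios(tx$cohort)
labeled <- simulate_training_set(trios, fraction = 0.5, seed = 20251)
detector <- train_detector(labeled, nfolds = 5, seed = 2025)
detector
#> <detector_bundle> combined features (14 cols), threshold 0.750, n_train 3621
#>   CV (5 folds): mean auROC 0.9866, mean auPR 0.9895
```

Five-fold patient-grouped cross-validation on ~3.6k trios (half carrying
simulated dilutions) separates contaminated from clean trios with mean
auROC 0.987: on this synthetic cohort the anomaly-with-resolution pattern
is nearly fully recoverable. Applying the bundle back to the *clean* trios
flags 37 of 3621 (1.0%) — the false-positive floor from natural concordant
dips. The full audit chains every stage (training cohort, injection at a
chosen rate, prediction, severity, transfusion rules, BMP cross-check):

```r
res <- run_audit(audit_config(contamination_rate = 0.02, seed = 2025))
res
#> <audit> 9568 CBCs, 6522 trios (68%)
#>   predicted contaminated: 229 (3.51% of trios)
#>   severity: median rho_hat 0.10, 50% > 0.10, 20% > 0.20
#>   transfusions: 81, matched 50 (62%), flagged 3 (6.0% of matched)
#>   BMP cross-check: 32 pairs, 53% co-contaminated, slope 1.08, R^2 0.96
```

Reading this: 68% of synthetic CBCs have both neighbors and are scoreable;
with contamination injected into 2% of draws, 3.5% of trios are flagged
(detected injections plus the ~1.5% false-positive floor); flagged trios
carry a median estimated mixture ratio of 0.10; 6% of trio-matched
transfusions meet all three "potentially unnecessary" criteria; and where
a paired BMP exists, its independent severity estimate regresses on the
CBC estimate with slope near 1. Feature attributions recover the intended
signal — the leading principal component and the Hgb deltas dominate:

```r
head(global_importance(attribute(detector, labeled)), 3)
#>   feature         median_abs_contribution  rank
#> 1 hgb_delta_post                    3.11      1
#> 2 hgb_delta_prior                   2.77      2
#> 3 PC1                               0.998     3
```

A thin CLI wraps the same functions
(`inst/cli/cbccontam simulate-cohort | build-trios | simulate-contamination
| train | predict | audit`), reading/writing CSV (Parquet with the arrow
package) and exiting 2/3 on configuration/data errors.

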