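# slopekit

Tools for a question that sits between developmental clinical research and
transcriptomics: **when toddlers with autism enter standardized early
intervention, can their rate of skill growth be predicted before treatment
starts — from clinical scores, and from blood leukocyte gene expression?**

The package implements the full inference chain for a longitudinal cohort
(≈41 toddlers, skill assessments every 3 months, one pre-treatment blood
draw on a 3-batch microarray):

1. **Trajectory model.** A random-intercept/random-slope linear mixed model
   `y_it = β₀ + β₁·t + b₀ᵢ + b₁ᵢ·t + ε`, REML-estimated, from which each
   subject's *treatment slope* (β₁ + b₁ᵢ, outcome units/month) is
   extracted via BLUPs. A group model tests early (<24 months at start)
   versus later starters with age×group interaction, days in treatment,
   intensity and pre-treatment Mullen composite as fixed effects.
2. **Slope-variability permutation test.** SD(late) − SD(early) against a
   label-permutation null, add-one p-value `(1+b)/(B+1)`.
3. **Expression preprocessing.** Quantile normalization, top-50% variance
   filtering (20,194 probes → exactly 10,097), and per-fold
   train-fit/test-apply residualization of batch, sex and RIN.
4. **Nested leave-one-out LASSO.** Outer LOOCV, inner 10-fold penalty
   selection on a 100-point log grid, in-fold covariate removal and
   standardization, cross-validated MSE and R², significance from a
   full-pipeline permutation null, and a prioritization refit naming the
   treatment-relevant genes. The solver is an exact λ-homotopy
   (LARS-lasso) with a coordinate-descent reference implementation.
5. **Annotation.** Hypergeometric odds-ratio enrichment against gene-list
   collections with Benjamini–Hochberg FDR, a network edge-count
   permutation test, and a voxelwise one-sample t-map (BH-FDR, q < 0.05)
   over per-gene spatial expression volumes.
6. **Synthetic cohorts.** `simulate_cohort()` states a cohort with the
   study's structure (start-age distribution matching mean 22.77 / SD 4.08
   on 13–27 months, visit schedule, random effects, early-start gain,
   inflated late-start slope SD, nuisance batch/sex/RIN structure, a
   co-expressed causal gene module calibrated to a target predictive R²,
   clinical scores on instrument-like scales, gene sets, a network and a
   truth record), so every stage is testable offline.

## Worked example

Trajectory stage on the default synthetic cohort:

```r
library(slopekit)
coh <- simulate_cohort(cohort_config(seed = 1))
fit <- fit_lmm(coh$visits)
slopes <- extract_treatment_slopes(fit)
grp <- coh$subjects$start_group[match(slopes$subject_id,
                                      coh$subjects$subject_id)]
sd_difference_test(slopes$slope, grp, B = 10000, seed = 1)
#> SD-difference permutation test: SD(late) = 9.486 , SD(early) = 5.36
#> observed diff = 4.126 ; p = 0.05989 (B = 10000 )
```

Late starters' slopes are almost twice as variable as early starters'
(the generator doubles the late-group slope SD); with only 41 subjects
this particular draw sits just above the 0.05 line — variability tests at
this n are genuinely hard.

Prediction stage on a cohort with a detectable expression signal (a
3-probe co-expressed causal module, target R² = 0.3):

```r
coh <- simulate_cohort(cohort_config(n_probes = 50, n_causal = 3,
                                     causal_cor = 0.8, target_r2 = 0.3,
                                     late_slope_sd_inflation = 1, seed = 1))
slopes <- extract_treatment_slopes(fit_lmm(coh$visits))
cov <- coh$subjects[, c("batch", "sex", "rin")]
pm <- permutation_test_mse(t(coh$expression), slopes$slope,
                           covariates = cov, B = 99, seed = 1)
pm
#> permutation_null: observed MSE = 11.89 ; p = 0.04 (B = 99 )
pm$observed_fit
#> cv_result (LOOCV): n = 41 ; MSE = 11.89 ; R^2 = 0.135

prioritize_features(t(coh$expression), slopes$slope, covariates = cov,
                    seed = 1)
#> prioritized_set: 11 features with nonzero weight at lambda = 0.3267
```

Reading the numbers: each subject's slope was predicted by a model that
never saw that subject (MSE 11.89 is the mean squared held-out error in
slope units²; R² = 0.135 means 13.5% of slope variance predicted), and
only 4 of 99 pipeline reruns on shuffled slopes matched it (p = 0.04).
The prioritization refit keeps 11 of 50 probes. At n = 41 roughly half of
simulated cohorts at this signal strength fail to reach significance —
the methods vignette quantifies this power honestly.

## Command line

```sh
Rscript inst/cli/slopekit simulate --config cohort.json --outdir data --seed 7
Rscript inst/cli/slopekit slopes --visits data/visits.tsv --out slopes.tsv
Rscript inst/cli/slopekit sdtest --slopes slopes.tsv --groups data/subjects.tsv --perms 10000 --seed 7
Rscript inst/cli/slopekit preprocess --expr data/expression.tsv --keep-fraction 0.5 --out filtered.tsv
Rscript inst/cli/slopekit predict --features filtered.tsv --slopes slopes.tsv \
    --covariates data/subjects.tsv --perms 1000 --seed 7 --out result.json
```

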