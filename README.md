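# labelboot

Propagating multiclass classification uncertainty into downstream
survival estimation.

## The problem

In oncology health-services research, a stratification variable such as
cancer stage is often missing from the analysis data (e.g. insurance
claims) and is predicted from proxy features by a classifier developed on
an earlier cohort. The usual practice assigns each patient the single
most probable class and treats that label as observed in a stratified
Kaplan-Meier survival analysis — silently ignoring all labeling
uncertainty. `labelboot` implements a pipeline that carries that
uncertainty through to the survival estimates:

1. **Set-valued classification with bounded per-class error.** Given any
   estimated conditional probability function P̂(y | x) (reference
   implementation: main-terms multinomial logistic regression), each
   class y receives a threshold t̂ᵧ calibrated by split conformal
   inference so that P(y ∈ label set | Y = y) ≥ 1 − αᵧ in finite samples
   under exchangeability. The label set of an observation is
   {y : P̂(y | x) ≥ t̂ᵧ}; it may be empty (null) or contain several
   classes (ambiguous). The threshold is the smallest calibration
   true-class probability whose inclusive rank exceeds
   (mᵧ + 1)αᵧ − 1, with mᵧ the class-y calibration count.
2. **Weighted-labeling bootstrap.** The validation cohort is resampled
   with replacement; every resampled observation gets one label drawn
   uniformly from its label set (uniformly over all classes for null
   sets). Classification metrics and class-stratified Kaplan-Meier
   summaries (median survival, 90- and 365-day survival, Greenwood
   variance) are computed per resample; results are reported as means
   with percentile 95% intervals.
3. **Naive comparators.** Single-pass argmax labeling with Greenwood
   confidence intervals (`run_standard_practice()`) and argmax labeling
   with an ordinary cohort bootstrap (`run_naive_bootstrap()`).

A calibrated synthetic-data generator reproduces a three-class,
three-scenario simulation design (class balance ≈ 37/49/13%, Weibull
survival with a = 1, b = 90 days, administrative censoring at 365 days),
and `run_study()` runs the full Monte Carlo comparison of the three
methods. See the vignette in `vignettes/weighted-labeling.Rmd` for the
model, the calibration of the generator, and all numerical conventions.

## Worked example

Simulate one scenario-2 replicate ("accurate but uncertain" classifier),
calibrate thresholds at αᵧ = 0.10, and run the weighted-labeling
bootstrap:

```r
library(labelboot)

cfg  <- sim_config()
rep2 <- make_replicate(scenario = 2, cfg, seed = 2026)
sp   <- split_development(rep2$development, seed = 2026)
fs   <- rep2$feature_set

fit   <- fit_prob_estimator(subset_features(rep2$development[sp$part1], fs))
calib <- rep2$development[sp$part2]
th    <- estimate_thresholds(predict_proba(fit, calib$features[, fs]),
                             calib$labels, alphas = 0.10)
th
#> <threshold_set>
#>  class threshold alpha n_calib
#>      1    0.1461   0.1     182
#>      2    0.2892   0.1     241
#>      3    0.0263   0.1      76

pv   <- predict_proba(fit, rep2$validation$features[, fs])
sets <- assign_label_sets(pv, th)
round(empirical_coverage(sets, rep2$validation$labels), 3)
#> [1] 0.893 0.896 0.948
```

Each class's label sets contain the true class for ≈ 90% of its
validation observations, as targeted. The rare, hard class 3 gets a very
low threshold (0.026): its predicted probabilities run low, so bounding
its miscoverage forces many ambiguous sets:

```r
ambiguity_distribution(sets)
#>   class set_size proportion
#> 1   all        0      0.000
#> 2   all        1      0.432
#> 3   all        2      0.455
#> 4   all        3      0.113

run <- run_weighted_bootstrap(rep2$validation, pv, th,
                              n_boot = 200, seed = 2026)
sm  <- summarize_bootstrap(run)
subset(sm$metrics, class == "macro")
#>    class     measure  mean lower upper
#> 13 macro    accuracy 0.744 0.725 0.763
#> 14 macro sensitivity 0.623 0.594 0.656
#> 15 macro specificity 0.811 0.797 0.825
#> 16 macro         ppv 0.595 0.570 0.623

subset(sm$bias, quantity == "surv_90_pp")
#>   stratum   quantity   mean lower upper
#> 2       1 surv_90_pp -1.614 -4.54  1.16
#> 5       2 surv_90_pp -0.948 -3.53  1.81
#> 8       3 surv_90_pp  7.963  4.05 12.26
```

The bias table compares survival summaries stratified by the bootstrap
labels against those stratified by the true class, per resample: here
90-day survival in the predicted class-3 stratum runs ≈ 8 percentage
points above the truth (ambiguous class-2/3 cases dilute the severe
stratum), while strata 1–2 are within ± 2 points.

The same machinery applies to user data from CSV via `apply_to_cohort()`
or the thin command-line front end in `inst/cli/labelboot.R`
(`simulate`, `study`, `classify` subcommands).

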