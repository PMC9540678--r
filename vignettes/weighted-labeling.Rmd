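---
title: "Propagating set-valued classification uncertainty into survival estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating set-valued classification uncertainty into survival estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labelboot)
```

## The problem

In registry-linked claims analyses a key stratification variable — such as
cancer stage at diagnosis — is often unobserved in the analysis cohort and
must be predicted from proxy features. The standard practice is to fit a
multiclass classifier on a development cohort, assign each analysis-cohort
patient the single most probable class (argmax), and then treat those
labels as observed in downstream estimation, for example a stratified
Kaplan-Meier analysis of survival by stage. This discards all
classification uncertainty: survival estimates inherit misclassification
bias, and their confidence intervals ignore the labeling step entirely.

`labelboot` implements a remedy built from three pieces:

1. a **set-valued classifier** that assigns each observation a *set* of
   plausible class labels with a per-class coverage guarantee,
2. a **weighted-labeling bootstrap** that converts those label sets into a
   distribution of single-labeled data sets, and
3. downstream **stratified Kaplan-Meier estimation** run on every
   resampled labeling, so the reported intervals carry both sampling and
   labeling uncertainty.

Two naive comparators are provided: single-pass argmax labeling
(`run_standard_practice()`) and argmax labeling with an ordinary bootstrap
of the analysis cohort (`run_naive_bootstrap()`).

## The set-valued classifier

Let $O = (X, Y)$ with $Y \in \{1, \dots, K\}$ and let $\hat P(y \mid x)$
be any estimated conditional class-probability function (the package's
reference estimator is a main-terms multinomial logistic regression via
`nnet::multinom`; penalized-regression and random-forest adapters share
the same contract). The least-ambiguous classifier with bounded error
levels thresholds each class's probability at a class-specific cutoff:
$$\hat C_y = \{x : \hat P(y \mid x) \ge \hat t_y\},$$
and an observation's label set is $\{y : x \in \hat C_y\}$. Sets may be
empty (*null*) or contain several labels (*ambiguous*); both are
informative about how confidently the classifier separates the classes.

Thresholds come from **split conformal calibration**. The development
cohort is split in half (stratified on the label): the estimator is fit
on $\mathcal I_1$ and applied to $\mathcal I_2$. Within the class-$y$
calibration stratum $\mathcal I_{2,y}$, with per-class error level
$\alpha_y$, the threshold is the smallest true-class predicted
probability whose inclusive rank strictly exceeds
$(|\mathcal I_{2,y}| + 1)\,\alpha_y - 1$:
$$\hat t_y = \min_{i \in \mathcal I_{2,y}}
  \Big\{ \hat P(Y_i \mid X_i) : \textstyle\sum_{j \in \mathcal I_{2,y}}
  I\{\hat P(Y_j \mid X_j) \le \hat P(Y_i \mid X_i)\} >
  (|\mathcal I_{2,y}| + 1)\alpha_y - 1 \Big\}.$$
Under exchangeability of calibration and deployment data this bounds each
class's miscoverage at $\alpha_y$ in finite samples. Implementation
choices worth noting:

* The threshold is always an element of the calibration probabilities —
  an order statistic, never an interpolated value. Ties are handled by
  the inclusive $\le$ count itself; the unit tests check equivalence with
  a brute-force scan of the defining condition on small tied inputs.
* Set membership uses the inclusive comparison
  $\hat P(y \mid x) \ge \hat t_y$, so a probability exactly at the
  threshold is in the set.
* $\alpha_y = 0$ forces $\hat t_y$ to the class minimum, covering every
  calibration point of that class.
* Raising $\alpha_y$ weakly raises $\hat t_y$ and weakly shrinks every
  label set (tested as a property).
* Null sets are preserved in all classifier outputs; they are only
  "filled in" during bootstrap label selection.
* Probability matrices must be row-stochastic within $10^{-8}$; rows
  inside tolerance are renormalized, anything further off is an error.
* A class absent from the calibration half is an error (no threshold is
  estimable), and coverage for a class with no validation observations is
  reported missing rather than zero.

The default error levels are $\alpha_y = 0.10$ for every class, i.e. a
90% coverage target per class.

## The weighted-labeling bootstrap

Downstream analyses need one label per observation. The weighted-labeling
bootstrap (`run_weighted_bootstrap()`) draws `n_boot` resamples of the
validation cohort with replacement; for every *resampled observation* one
label is selected uniformly at random from its conformal label set — so a
singleton set always contributes its label, a double set contributes each
member with probability 1/2, and a null set falls back to a uniform draw
over all $K$ classes. Classification metrics and stratified Kaplan-Meier
summaries are computed on each resample; point estimates are means of the
per-resample statistics with percentile 95% intervals.

Two deliberately resolved ambiguities:

* **Label redraw policy.** When a row appears twice in one resample it
  receives two independent label draws. The alternative (one draw per
  original row per resample) propagates strictly less labeling
  uncertainty; the independent-draw reading matches the view that each
  resampled observation carries its own label uncertainty. The choice is
  recorded in the run metadata.
* **Argmax ties** break toward the lowest class index so naive labeling
  is deterministic.

Reproducibility: a root seed spawns one child seed per resample, so runs
are identical across invocations and independent of execution order.

## Survival estimation

`km_fit()` wraps `survival::survfit` and re-expresses the product-limit
estimate over the distinct event times, with the Greenwood variance
$\hat S(t)^2 \sum_{t_i \le t} d_i / (n_i(n_i - d_i))$. Conventions:

* Tied deaths and censorings: deaths are processed first (the standard
  product-limit convention).
* The median is the smallest event time with $\hat S(t) \le 0.5$ and is
  reported missing when the curve never reaches 0.5 within follow-up —
  common for the mildest disease stratum under one-year follow-up.
* Greenwood confidence intervals are plain-scale normal intervals
  truncated to $[0, 1]$; no log–log transform is applied, keeping the
  interval exactly the named Greenwood form. With no events before the
  horizon the interval degenerates at 1.
* A horizon beyond the last observed time returns the survival at the
  last time with a warning.
* Bias of predicted-class-stratified estimates against observed-class
  estimates is reported in days for the median and in percentage points
  for survival probabilities; a relative-percent column is also emitted
  since "percent bias" is ambiguous between the two readings.
* A median confidence interval for the single-pass method is out of
  scope; Greenwood intervals apply to the survival probabilities.

## The synthetic cohort generator

`sim_config()` / `make_replicate()` emulate a three-class disease-staging
cohort at $N = 2000$: a development cohort of 1000 (split 500/500 for the
weighted method) and a validation cohort of 1000, stratified on the class
label. Covariates are six standard-normal continuous variables
(`x1..x6`), seven Bernoulli binaries with prevalences 0.10–0.50
(`b1..b7`), and two Poisson counts with means 1 and 3 (`c1`, `c2`).
Class labels are drawn from per-observation multinomial-logit
probabilities; survival times are Weibull with shape $a = 1$ and scale
$b = 90$ days, scaled per class as $b\,e^{-y\beta}$ with $\beta = 0.4$
(higher classes die faster, giving well-separated strata), and censored
administratively at 365 days:
$$T_i = \big(-\log(U_i)\, b\, e^{-Y_i \beta}\big)^{1/a}, \qquad
U_i \sim \mathrm{Uniform}(0, 1).$$
The product reading of the scale term is used: with $a = 1$, $b = 90$
each class is exponential with mean $90 e^{-y\beta}$ days, so the
one-year follow-up censors only a small fraction and median survival sits
on the scale of weeks to months — consistent with survival biases being
meaningfully expressed in days. (A rate reading, $b$ as a divisor, would
put nearly all deaths within hours and make a 365-day horizon
meaningless.) Only administrative censoring is simulated; no random
loss to follow-up mechanism is described for this design.

Labels are *drawn stochastically* from the per-observation class
probabilities rather than assigned by argmax of the true probabilities:
argmax assignment would make the labels a deterministic function of the
covariates and allow near-perfect classification, incompatible with the
intended accuracy regime.

### The three scenarios and their calibration

The three study scenarios share one data-generating process and differ
only in which covariates the classification algorithm may use:

* **Scenario 1 — accurate and certain:** all 15 covariates.
* **Scenario 2 — accurate but uncertain:** the strongest predictors
  (`x1`, `x4`, `b1`) withheld.
* **Scenario 3 — inaccurate and uncertain:** only `x3` plus otherwise
  uninformative covariates; no class-3 signal survives, so argmax never
  predicts class 3.

The label-model coefficients are not derivable from first principles;
they were fixed once by calibrating against anchor statistics with
`calibrate_scenarios()`: marginal class balance of approximately
37/49/13 percent, a scenario-2 naive macro-averaged accuracy of about
0.82, and the scenario ambiguity profile (roughly three quarters of
scenario-1 validation observations in single-label sets, about half in
scenario 2). Two structural choices came out of that calibration:

* Class-1-versus-2 discrimination is concentrated on covariates visible
  in scenario 2 (`x2`, `x3`), with the scenario-2-hidden signal split
  between a moderate continuous covariate (`x1`) and a *rare strong
  binary* (`b1`, prevalence 0.10). The rare binary is what lets
  scenario 2 be simultaneously fairly accurate and visibly uncertain: it
  caps attainable accuracy by flipping a minority of cases while leaving
  the visible signal crisp enough to produce many single-label sets.
* The class-3 signal is kept moderate (`x4` hidden, `x5` and `b2`
  visible) so that class 3 — the rare class, 13% — remains genuinely
  hard: its conditional probabilities run low, naive labeling
  under-covers it severely, and its label sets are the most ambiguous.
  This is the qualitative regime the method is designed to expose.

`calibrate_scenarios()` itself adjusts intercepts by the multinomial
log-ratio correction (recovering the closed-form intercept-only solution
$a_y = \log(p_y / p_K)$ when slopes are zero) and the global coefficient
scale by damped proportional steps, each evaluated by pilot simulation
at a fixed seed, so calibration is deterministic. Overriding the label
model marks the configuration uncalibrated and `generate_labels()`
refuses to run until calibration is re-asserted.

### What the generator does and does not emulate

The generator reproduces the *structure* of a staged-cancer claims
cohort — class imbalance with a rare severe class, classifiers of varying
informativeness, class-dependent survival on a days-to-months scale,
administrative one-year censoring. It does not emulate real claims data:
covariates are independent, the label model is exactly multinomial-logit
(so the reference estimator is well-specified), and there is no
covariate shift between development and validation. Passing tests on
synthetic data therefore demonstrate the machinery and its finite-sample
coverage behaviour under exchangeability, not robustness to model
misspecification or distribution drift.

## Study runner and problem sizes

`run_study()` executes the full pipeline per replicate — generate, fit
(whole development cohort for the naive methods, first half for the
weighted method), calibrate thresholds, label, bootstrap, summarize —
and stores per-replicate records from which `summarize_study()` rebuilds
every table deterministically. The coverage table reports the standard
deviation of per-replicate coverages as the Monte Carlo SE: with
hundreds to a thousand replicates the SE *of the mean* would be an order
of magnitude smaller than the conventionally reported parenthetical
values, so the across-replicate SD is the quantity of record (the SE of
the mean is recoverable as `mc_se / sqrt(n_reps)`).

Full-size runs use 1000 repetitions and 500 bootstrap resamples. The
package's own acceptance checks run at desk scale — 200 replicates per
scenario for coverage, balance and ambiguity, and 100 replicates with 50
resamples for the bootstrap accuracies — sizes at which the Monte Carlo
error of every checked mean is far below the tolerance applied to it.
Per-replicate failures are logged with their seeds for replay; a study
aborts only if more than 1% of replicates fail.

## Known limitations

* Coverage is marginal per class, not conditional on covariates; the
  split-conformal guarantee also says nothing once exchangeability
  breaks (coding changes, treatment drift).
* Only the split-conformal construction is implemented — no
  cross-conformal, jackknife+, or CV+ variants.
* Bootstrap intervals are percentile intervals; no BCa or studentized
  corrections.
* Kaplan-Meier is the only outcome model; Cox regression or parametric
  survival models would slot in behind the same labeling machinery but
  are not provided.
* The multinomial-logit reference estimator is unregularized by design;
  with many features relative to the fitting half, one of the penalized
  adapters is the better plug-in.
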