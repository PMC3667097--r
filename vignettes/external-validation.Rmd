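---
title: "Externally validating a published Cox model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Externally validating a published Cox model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxval)
```

## The problem

A prognostic Cox model is developed on one cohort and published. Before it
can inform clinical decisions it must be shown to perform on independent
data. Validating a Cox model is harder than validating a logistic model for
two reasons: follow-up is right-censored, and the Cox partial likelihood
never estimates the baseline hazard, so a publication that reports only
hazard ratios does not, by itself, let anyone compute an absolute survival
probability.

`coxval` takes the perspective of a validator who has patient-level data but
*no access* to the derivation data. What can be checked depends on the level
of information the publication carries:

* **L1** — the regression coefficients (hence the prognostic index, PI).
* **L2** — L1 plus risk-group definitions and their Kaplan–Meier curves.
* **L3** — L2 plus an estimate of the baseline survival function
  $S_0(t)$.

The package implements the corresponding toolkit: regression on the PI and
misspecification checks (L1), discrimination measures (L1), risk-group
Kaplan–Meier comparisons, between-group tests and hazard ratios (L2), and a
strict observed-versus-predicted calibration assessment (L3).
`run_validation()` assembles exactly the methods the supplied information
level permits and refuses, by name, anything it cannot do (no calibration
section without a baseline).

## The prognostic index

The published model is represented by `published_model()`: an ordered list
of covariate transformations with coefficients, plus a centering constant.
The PI for subject $i$ is

$$\mathrm{PI}_i = \sum_k \hat\beta_k \, f_k(x_{ik}) - c,$$

where $c$ is the mean linear predictor in the derivation data, so that
$\mathrm{PI} = 0$ is "average risk" and the baseline curves below are curves
at the mean PI. The transformation vocabulary — identity, power (power 0
meaning $\ln$), power times log, and indicator — encodes fractional
polynomial (FP) terms and dummy variables directly; spline or other bases
can be precomputed as columns and declared `identity`. Coefficients are
never re-estimated: the model is applied exactly as published.

Each transform carries an explicit `scale` divisor because published FP
models are frequently fitted to rescaled covariates (an age term like
$\mathrm{age}^3$ is numerically absurd on a scale of years unless age was
divided by some constant first) and publications do not always print the
scaling. When the scaling is not reported it cannot be reconstructed from
the coefficients alone; `coxval` therefore requires it to be stated in the
model spec rather than guessing. This is the single most common obstacle to
exact numerical reproduction of a published PI.

## Risk groups

`cox_cutpoints()` forms groups at fixed centiles of the PI, following the
minimal-information-loss grouping of a Normal-scale score. For four groups
the centiles are 16/50/84 (mean and roughly ±1 SD on a Normal scale); for
2, 3 and 5 groups the default tables are 50; 27/73; and 11/35/65/89.
Because no standard fixes the details, two conventions are chosen once and
logged in every report:

* centiles use the type-7 (linear-interpolation) empirical quantile;
* intervals are closed on the left and open on the right, the lowest
  unbounded below, so a PI exactly on a cutpoint joins the higher-risk
  group.

Cutpoints computed in one dataset transfer as absolute PI values to any
other dataset, which is what makes group-wise comparisons between cohorts
meaningful.

## Method 1: the calibration slope

`calibration_slope()` fits a Cox model in the validation data with the PI as
its sole covariate. Slope 1 means the published effect strength is
preserved; < 1, attenuation. The likelihood-ratio test of slope = 1
compares against the model holding the PI as an offset (coefficient fixed at
1). Two caveats are attached to the result verbatim: the P-value ignores
uncertainty in the published coefficients (anti-conservative), and a small
slope can reflect a narrower case mix rather than a wrong model — if the
validation cohort is more homogeneous, the SD of the PI and every
discrimination measure shrink even when the model is correct.

On the dataset whose own Cox fit produced the PI the slope is exactly 1;
this identity is used as a machine-precision check of the whole
PI-construction and fitting path (it is also the quantity
`scripts/acceptance.R` recomputes).

## Method 2: misspecification and proportional hazards

`misspecification_test()` refits the model's transformed covariate columns
with the PI as a fixed offset:

$$\ln h(t) = \ln h_0(t) + x'\beta^* + \mathrm{PI}.$$

Each $\beta^*_k$ estimates how far the validation data pull covariate $k$
away from its published coefficient. The joint test of $\beta^* = 0$ (LR by
default against the offset-only model; Wald also computed, since "joint
test" fixes neither) is the primary statistic — per-covariate tests are
reported but flagged secondary, the joint test protecting the type-1 error.
Derivation-side uncertainty is deliberately ignored: the published
coefficients are treated as fixed constants, which is the only option
without the derivation covariance matrix.

`ph_check()` is the Grambsch–Therneau scaled-Schoenfeld test on the Cox fit
of the PI, with Kaplan–Meier time scaling by default (identity and rank
transforms selectable). Its caveat: a drifting PI effect need not ruin
discrimination, but calibration should then be examined closely.

## Method 3: discrimination

Three measures, all computable from the PI and (except $K$) the outcome:

* **Harrell's $c$** — the proportion of evaluable pairs in which the
  member with the higher PI fails first. Under right censoring a pair is
  evaluable when the shorter time is an event; pairs tied on time count
  only when exactly one member has an event; PI ties score 1/2. $c$ is
  biased away from 0.5 by heavy censoring.
* **Gönen–Heller $K$** — the model-based concordance probability. Under
  proportional hazards the chance that the lower-PI member of a pair
  outlives the other is a logistic function of the PI difference, so
  $$K = \binom{n}{2}^{-1}\sum_{i<j}\frac{1}{1+\exp(-|\mathrm{PI}_i-\mathrm{PI}_j|)}.$$
  The outcome never enters, so $K$ is unaffected by censoring. A tied pair
  contributes 1/2 (the logistic limit), so a degenerate constant PI yields
  $K = 0.5$ with a warning.
* **Royston–Sauerbrei $D$** — order the PI, replace values by rankits
  (Blom's approximation $\Phi^{-1}((i-3/8)/(n+1/4))$, tied values averaged),
  divide by $\kappa = \sqrt{8/\pi} \simeq 1.596$, and fit a Cox model to the
  result; the coefficient is $D$, a log hazard ratio between the prognostic
  halves of an idealised Normal PI. Exact expected order statistics differ
  from Blom's scores by $O(10^{-3})$ at validation sample sizes, which is
  negligible relative to the SE of $D$.

Explained variation follows as
$R^2_D = (D^2/\kappa^2) / (\sigma^2 + D^2/\kappa^2)$ and
$R^2_{PM} = s^2/(\sigma^2 + s^2)$ with $s$ the PI standard deviation and
$\sigma^2 = \pi^2/6 \simeq 1.645$ playing the role of the residual variance
on the log relative-hazard scale. $c$, $D$ and $R^2_D$ depend on the PI only
through ranks; $K$ does not (it is location- but not rank-invariant); and
$R^2_{PM}$ needs no outcome at all.

Standard errors for $c$ and $K$ use the exact delete-one jackknife over
subjects, which for these pairwise U-statistics is cheap (the per-subject
pair sums are already available) and asymptotically equivalent to the
projection variance; a bootstrap SE is selectable for $K$. The SE of $D$
comes from its Cox fit, and the SE of $R^2_D$ by the delta method.

## Methods 4–6: risk-group comparisons

With L2 information the package draws Kaplan–Meier curves per risk group
(product-limit estimates with Greenwood standard errors) for visual
assessment of discrimination and rough calibration, and tabulates hazard
ratios of each group against the lowest-risk reference via a dummy-variable
Cox model (`group_hazard_ratios()`); groups without events are flagged
rather than forced to a number. The between-group logrank test
(`logrank_test()`) is implemented because it is common practice, but every
result carries a deprecation note: a significant P-value only rejects the
hypothesis that the groups coincide, which is rarely informative.

## Method 7: calibration via a transportable baseline

The missing piece for absolute predictions is $S_0(t)$. The package's
approach makes it transportable in three numbers and two powers:

1. In the derivation data, estimate the baseline cumulative hazard with the
   PI as a fixed offset (`baseline_cumhaz()`, a Breslow-type estimator that
   reduces to Nelson–Aalen when all PI values are zero).
2. Approximate $\ln H_0(t)$ by the best FP2 function of time
   (`fit_fp2_log_cumhaz()`): ordinary least squares of $\ln H_0(t_i)$ on
   each basis pair from the power set $\{-2,-1,-0.5,0,0.5,1,2,3\}$
   (power 0 meaning $\ln t$, a repeated power $(p,p)$ giving $t^p$ and
   $t^p\ln t$), keeping the smallest residual sum of squares. OLS is
   unweighted by design; weighting by risk-set size is not attempted. A
   non-monotone winning fit earns a warning, since a cumulative hazard
   cannot decrease.
3. Publish (or serialize with `write_baseline()`) the powers and
   coefficients. A look-up table of $(t, S_0)$ pairs is supported as an
   alternative publication format, interpolated linearly on the
   $\ln H_0$ scale to stay positive and monotone.

Validation then proceeds: $S^{val}(t;\mathrm{PI}_i) = S_0(t)^{\exp(\mathrm{PI}_i)}$
per subject; average those curves (the probabilities, not the PIs — plugging
in a group-mean PI differs by Jensen's inequality) over each risk group at
the observed validation times; and superimpose or tabulate them against the
group Kaplan–Meier curves (`observed_vs_predicted()`, default report times
2 and 5). Finally `compare_baselines()` overlays the transported smooth
curve on the validation data's own offset-constrained empirical baseline;
the summary statistic is the maximum absolute survival-scale difference over
the deciles of the validation event times.

Uncertainty in the smooth baseline comes from `bootstrap_band()`: resample
subjects, refit the Cox model on the PI, recompute the Breslow baseline at
the replicate's mean linear predictor, refit the FP2 form, and evaluate on a
fixed grid of 100 equally spaced times between the first and last event
time; the band is mean ± 1.96 SD on the $\ln H_0$ scale, back-transformed.
The default of 100 replicates is adequate for a pointwise band; the seed is
a required argument so bands are always reproducible.

Evaluation outside the fitted time range is refused by default. The FP2
form has no support beyond the derivation follow-up, so the intended
workflow is to truncate the validation follow-up at the derivation maximum
(`truncate_followup()`) rather than extrapolate; an `extrapolate = TRUE`
escape hatch exists and warns.

## The synthetic-data generator

`simulation_scenario()`/`generate_samples()` produce derivation/validation
pairs with known structure so that every method can be exercised against a
known truth. Event times come from a Weibull baseline by inversion,
$T = (-\ln U / (\lambda e^{lp}))^{1/\nu}$, chosen because the closed-form
survival $\exp(-\lambda t^\nu)$ serves as an oracle; a piecewise-exponential
baseline is available for non-smooth hazards. The defaults emulate a
node-positive breast-cancer setting: cohorts of 1546 and 686, time in years,
$\lambda = 0.18$, $\nu = 0.9$ (event-free median about 4.5 years at average
risk, roughly two-thirds of subjects with an event by 7 years), three
covariates (two standard Normal, one balanced binary) with coefficients
(0.4, −0.3, 0.5) giving a linear-predictor SD near 0.6, and administrative
censoring at 7 years.

Controlled departures drive the negative tests: a slope multiplier $\gamma$
on the validation linear predictor (the calibration slope should recover
it), a baseline hazard multiplier $\rho$ (the baseline-agreement check
should flag it), case-mix shrinkage of the covariate SDs (all discrimination
measures should drop), and a time-varying coefficient
$\beta(t) = \beta(1 + \delta \ln(1+t))$ on one covariate to break
proportional hazards — the shift inside the logarithm keeps the hazard
integrable at $t \to 0$, where a bare $\ln t$ form diverges for part of the
covariate distribution; event times under this perturbation are found by
numerically inverting the cumulative hazard per subject.

What the generator does *not* emulate: the correlation structure and skewed
marginals of real prognostic factors, measurement differences between
cohorts, informative censoring, and competing risks. Passing tests
therefore demonstrate that the estimators are correct under proportional
hazards with independent censoring — not that any particular clinical model
validates.

`apparent_scenario()` closes the loop: it fits a Cox model to a derivation
arm and packages coefficients, centering, Cox-centile cutpoints and FP2
baseline exactly as a publication would, so the entire pipeline can run
end-to-end without external data.

## Numerical choices and degenerate inputs

* Ties in the partial likelihood: Efron's method by default (better
  small-sample behaviour), Breslow selectable; convergence and covariance
  come from the fitter's Newton iterations with the observed information.
* Constant PI: the slope and $D$ are degenerate — the slope errors, $D$
  returns 0 with a warning, $K$ returns 0.5 with a warning.
* Collinear covariate columns in the misspecification test are refused with
  the offending names rather than silently dropped.
* Bootstrap replicates with too few events (fewer than eight distinct event
  times) are redrawn and counted.
* Monotone likelihood (separation) in any Cox fit raises a numerical error
  rather than returning a divergent coefficient.
* All file formats are plain text: YAML for model specs, scenarios and FP2
  baselines (lossless round-trip), CSV for data, step curves and look-up
  baselines.

The package's tests run its simulations at deliberately moderate sizes —
cohorts of a few hundred to two thousand subjects, 100–400 Monte-Carlo
replicates — which keeps the whole suite to well under a minute while
leaving Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

The scheme requires a PI that assigns each patient a time-constant relative
hazard: stratified Cox models (no unique baseline) and models with
time-dependent effects are out of scope, as the validation logic itself
presumes proportional hazards. Missing covariate values are an error, never
imputed. Model updating or recalibration after a failed validation is a
different exercise and is not provided. Individual-level calibration
(without risk groups) is not attempted; group-free approaches exist
elsewhere (e.g. the `rms` package's `val.surv`).
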