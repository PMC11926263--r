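---
title: "Probabilistic prolactin thresholds for adenoma invasiveness: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic prolactin thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

The outcome is binary cavernous sinus invasion `y`; the biomarker is serum
prolactin (PRL, µg/L), entering as `x = log10(PRL)`. The regression is

$$\operatorname{logit} P(y_i = 1) = \alpha + u_{g(i)} + \beta x_i, \qquad
u_g \sim \mathcal N(0, \sigma_u),$$

with `g(i)` the patient's gender. The assumptions that matter:

* **Monotone risk.** Invasion risk is non-decreasing in PRL (`β > 0` in
  practice). Posterior draws with `β ≤ 0` contradict this premise; they are
  excluded from threshold inversion, tallied, and a stratum whose exclusion
  fraction exceeds 5% is flagged unreliable.
* **Gender acts as a level shift.** A single slope is shared; gender moves
  the intercept only. Age and BMI never enter the model — they stratify
  the patient set on which thresholds are computed (see below).
* **Complete cases only.** Records missing PRL or the outcome are dropped,
  never imputed; sex must always be observed because of the offset.

### Priors

The source analysis does not state priors, chain counts, or whether the
offset scale was hierarchical, so these are package choices: `α ~ N(0, 5)`
and `β ~ N(0, 2.5)` are weakly informative on the logit scale (a slope of
2.5 per decade of PRL is already a very strong effect), and
`σ_u ~ Half-Normal(1)` keeps the two-level offset hierarchy proper — with
only two gender levels, `σ_u` is weakly identified and essentially
prior-driven; what the data identify well are the sums `α + u_g`. All are
exposed through `prior_config()`.

### Sampler

No probabilistic-programming backend is assumed. The sampler is an
adaptive random-walk Metropolis on the centred block
`(α, u_female, u_male, β)` — initial proposal covariance from the inverse
curvature at the posterior mode, Haario-style covariance adaptation and
Robbins–Monro scale tuning (target acceptance 0.234) during warmup, frozen
afterwards — combined with a univariate slice-sampling Gibbs update for
`log σ_u`, whose full conditional involves only the two offsets and is
data-free. The centred-plus-slice construction was adopted after the
non-centred pure-random-walk variant showed the classic funnel pathology
(`σ_u` effective sample sizes an order of magnitude below the rest).
Defaults: 4 chains × 1000 kept draws, 1000 warmup steps, thinning 5;
split-R̂ and bulk/tail ESS are computed for every parameter and the overall
convergence verdict requires max R̂ ≤ 1.01 and min ESS ≥ 400.

## From posterior to thresholds

Per stratum:

1. compute each patient's posterior-mean invasion probability;
2. find the probability cutoff `p*` maximising the Kolmogorov–Smirnov
   distance between the class-conditional empirical CDFs of those
   probabilities (candidates are the observed values; ties break to the
   smallest candidate, compared in integer arithmetic so floating-point
   noise cannot flip the argmax);
3. invert `p*` through **every** posterior draw,
   `T = 10^{(\operatorname{logit} p^* - \alpha - u)/\beta}`, giving one
   threshold per draw;
4. summarise by median, central 95% credible interval, and the mode
   ("most likely estimate") of a Gaussian KDE fitted on `log10 T`
   (Silverman bandwidth, argmax clamped to the observed support). Mode
   estimation is done on the log scale because threshold distributions are
   right-skewed on the natural scale.

**Why a single `p*` rather than a per-draw K-S step.** Within a
single-gender stratum the predicted probability is, under every draw, a
strictly monotone transform of PRL; a per-draw K-S cutoff therefore always
selects the same patient boundary, and inverting it returns the same
observed PRL value for every draw — a zero-width "distribution". Deriving
one `p*` from the posterior-mean probabilities and propagating only the
inversion through the draws yields genuine posterior threshold
distributions and is the package default (`method = "mean_probability"`);
the degenerate per-draw variant is retained as a cross-check switch because
its fixed point is exactly the raw-scale empirical optimal cutpoint.

**Mixed strata.** For cohort-wide ("all patients") thresholds the inversion
offset is the gender-count-weighted mean of `u_female` and `u_male` in the
stratum. **Subgroup rows** (age/BMI cells) restrict the K-S patient set but
reuse the full-cohort posterior fit: small cells stay estimable and the fit
is not redone per cell. Cells with fewer than two members of either class
are reported as inestimable rather than forced.

## Youden baseline and evaluation

The classical comparator maximises `J = sens + spec − 1` over observed PRL
values with positivity rule `PRL ≥ c` (high PRL indicates invasion — the
invasive class median is an order of magnitude above the non-invasive one).
Uncertainty comes from a 1000-member patient bootstrap, class-stratified by
default so small strata cannot yield single-class resamples (a plain
bootstrap with redraw-and-tally is the switch). `max J` equals the
two-sample K-S distance between the class-conditional PRL CDFs; the test
suite checks this identity against an independent K-S implementation.

Threshold evaluation propagates each draw's threshold into exact confusion
counts on the stratum's observed data (sensitivity, specificity, PPV, NPV;
zero-denominator ratios are reported missing, never zero) and summarises by
mean and central 95% interval. AUROC is computed on raw PRL as the
normalised rank-sum (ties count half) with a class-stratified bootstrap
interval: within one gender the model score is a monotone transform of PRL
so the two AUROCs coincide, and a posterior AUROC within a single stratum
would be degenerate under a monotone link. AUROC intervals are therefore
bootstrap intervals and labelled as such in all outputs.

## The synthetic cohort: what it emulates, what it does not

The generator draws sex ~ Bernoulli(0.711), per-sex log-normal PRL, and
invasion through the same logistic link the inference assumes — so
parameter-recovery tests are meaningful by construction. Default
parameters were obtained once by solving four moment conditions by
numerical integration (sex-specific invasion rates 21/106 and 35/43;
class-conditional PRL medians 126 and 1510 µg/L) with `β = 2` and per-sex
log10 SDs 0.55/0.65 held fixed, then frozen:
`µ_f = 2.1442, µ_m = 3.4413, α = −5.4843, u = ∓0.5163`. Age
(truncated normal, mean 38, SD 14, ≥ 18 years) and BMI (mean 26.5, SD 5,
≥ 14 kg/m²) are independent covariates used only for stratification; the
published cohort gives no generative model for them, and values were chosen
to bracket the printed medians (33 years, 26.8 kg/m²). A 18/149 PRL
missingness rate reproduces the published 149 → 131 complete-case step.
Per-record sub-seeding makes cohorts bit-reproducible and prefix-stable
when `n` grows.

What a green test does **not** establish: the generator shares the model's
functional form, so recovery tests validate the implementation, not the
model's adequacy for real patients; real cohorts have age- and
size-dependent PRL, assay artefacts (hook effect), macroprolactin, and
informative missingness, none of which are simulated. The generator also
cannot (and is not meant to) reproduce the published threshold values
themselves — only their structure: female ≪ cohort-wide ≪ male.

## Numerical choices and degenerate inputs

* Bernoulli log-likelihood uses the `log1p(exp(·))` split, finite for
  |linear predictor| up to ~700.
* The MAP optimisation can diverge for prior-only fits (`σ_u → 0`
  degeneracy); the sampler then falls back to a prior-scale start.
* K-S distances are compared on integer counts; the `J`-at-threshold and
  AUROC computations are exact count arithmetic in doubles.
* Age/BMI subgroup boundaries put equality in the upper category
  (≥ 50 years, ≥ 30 kg/m²).
* Single-gender inputs drop the offset hierarchy (recorded in the result);
  single-class outcomes are refused outright.
* Reported acceptance simulations use a reduced MCMC budget per fit
  (2 chains × 500 kept draws) to keep the suite inside a strict CPU
  budget; the criterion thresholds are unchanged, and measured pipeline
  Monte-Carlo error (~±10% on a recovered median threshold at n = 2000,
  dominated by flat-top argmax flips of the K-S objective, not by chain
  length) is documented where a tolerance had to be quantified.

## Known limitations

* With two gender levels, `σ_u` is prior-driven; the gender offsets should
  be read as regularised fixed effects.
* Thresholds snap to the candidate grid induced by observed probabilities;
  no interpolation between patients is attempted (determinism is preferred
  over smoothness).
* Subgroup thresholds inherit the full-cohort fit; a per-subgroup refit
  switch exists but small cells will produce wide, prior-dominated
  intervals.
* Descriptive p-values (chi-square, Wilcoxon rank-sum) are exploratory
  only, unadjusted, and never feed the threshold machinery.
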