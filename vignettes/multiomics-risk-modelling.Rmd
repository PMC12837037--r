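---
title: "Sex-specific multi-omics extension of 10-year cardiovascular risk models under a case-cohort design"
author: "survomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific multi-omics extension of 10-year cardiovascular risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survomics)
```

## The modelling problem

People with type 2 diabetes (T2D) carry a markedly elevated risk of major
adverse cardiovascular events (MACE: cardiovascular death, non-fatal
myocardial infarction, non-fatal stroke). Clinical 10-year risk scores for
this population — the base model here uses the eight SCORE2-Diabetes
covariates: age, current smoking, systolic blood pressure, total and HDL
cholesterol, age at diabetes diagnosis, HbA1c and eGFR, with sex handled by
stratification — discriminate only moderately. `survomics` implements a
two-stage procedure that asks whether adding molecular layers (a plasma
protein signature selected by bootstrap-LASSO, a small fixed panel of
pre-selected metabolites, and a cardiovascular polygenic score) improves
10-year MACE prediction, separately for men and women.

Because proteomic assays are expensive, such studies measure omics under a
**case-cohort design**: a random sub-cohort is drawn from the full T2D
cohort and every MACE case outside it is added. All survival models in the
package therefore maximise the Barlow-weighted Breslow partial likelihood:
a non-case sub-cohort member carries weight $1/\alpha$ while at risk
($\alpha$ = sub-cohort sampling fraction), a case carries weight 1 at its
own event time, and a case outside the sub-cohort enters the risk set only
at its failure. With $\alpha = 1$ the machinery reduces exactly to an
unweighted Cox model; standard errors are reported both model-based and as
robust (sandwich) estimates aggregated by subject, the latter being the
valid choice under the weighted pseudo-likelihood.

## The two-stage procedure

**Stage 1 — protein selection.** On the (larger) proteomics sample:
proteins failing QC (more than 20% missing values, or more than 25% of
observed values at the detection limit) are removed; remaining missing
data are completed by single missForest-style imputation (iterative
random-forest chained equations); then, per sex, `stability_selection()`
draws `B` bootstrap resamples, refits a LASSO-penalised weighted Cox model
in each — the eight clinical covariates force-included and unpenalised,
the penalty `lambda_min` re-selected by ten-fold cross-validation inside
every resample — and retains the proteins active in at least 95% of
resamples. The retained signature is refit without penalty, adjusted for
all clinical covariates.

**Stage 2 — sequential layer addition.** On the nested subset with
complete multi-omics data, each single-layer extension of the base model
is evaluated; the layer with the largest statistically significant gain in
Harrell's C becomes the reference, and remaining layers are added greedily
while the correlated-C-index test stays significant (two-sided p < 0.05).
The gate is discrimination only; reclassification metrics (categorical NRI
over the predefined 0–15% / >15–30% / >30% absolute-risk bands, continuous
NRI, IDI) and decile calibration are reported alongside at every step. The
procedure runs for the total population and per sex; "overall" metrics are
computed on pooled sex-specific predictions rather than a single pooled
model, because the underlying models are sex-specific by construction.

```{r example, eval = FALSE}
cfg <- analysis_config(sim = sim_config(seed = 1), B = 100, seed = 2)
res <- run_full_analysis(cfg)
print(res)
```

## The synthetic cohort generator

No individual-level data ship with the package; `generate_cohort()`
produces cohorts with the statistical structure the analysis assumes, plus
the ground truth needed for recovery tests.

* **Covariates** come from a Gaussian copula: every feature has a standard
  normal latent score; clinical covariates are mapped to natural units
  with means/SDs typical of a T2D population aged 40–69 (age 60.3 ± 6.6 y,
  SBP 144.5 ± 17.7 mmHg, total cholesterol 4.5 ± 1.0 mmol/L, HDL
  1.2 ± 0.3 mmol/L, age at diagnosis 55.0 ± 6.5 y, HbA1c 51.8 ± 12.9
  mmol/mol, eGFR 88.3 ± 16.1 mL/min/1.73 m², 10.7% current smokers), while
  omics features stay on the standardised latent scale. Pairwise Spearman
  targets $\rho_S$ are converted to latent Pearson correlations via
  $\rho_P = 2\sin(\pi\rho_S/6)$; a non-positive-definite target is
  rejected with the offending pairs named. Defaults plant one strong
  within-layer protein pair ($\rho_S = 0.64$), a few moderate pairs
  (≤ 0.47) and weak cross-layer correlations.
* **Outcomes** follow a sex-specific Weibull proportional-hazards law with
  linear predictor $\sum_f \beta_{\text{sex},f} z_f$, administrative
  censoring at the 10-year horizon and exponential dropout (default rate
  0.01/y — cohort attrition in volunteer biobanks is low). When the
  Weibull scale is not given it is calibrated by deterministic bisection
  on the analytic expected event fraction, so a target observed incidence
  is hit exactly in expectation. Default targets are 13.6% (men) and 8.2%
  (women) in the full cohort, chosen so the case-cohort analysis sample
  shows ≈15.4% cases at the reference sex ratio.
* **Design.** The default full cohort has 2364 subjects, 59.7% male, and a
  sub-cohort fraction of 0.707. These values are implied jointly by the
  reference frame the generator emulates: a sub-cohort of ≈1672 with ≈191
  cases, ≈79 appended outside cases, an analysis sample of ≈1751 with
  15.4% cases. A nested random subset (fraction 0.565) plays the role of
  the complete-multi-omics sample (≈990).
* **Effects.** Default true effects are sparse and sex-specific: 8
  male-only, 6 female-only and 1 shared protein (log hazard ratios
  0.28–0.45 per SD), 7 metabolites with weak effects (3 shared, 3
  male-only, 1 female-only), and a weak male-only polygenic-score effect.
  Clinical effects have the conventional signs (risk increases with age,
  smoking, SBP, HbA1c; decreases with HDL, eGFR).
* **Missingness** is injected at per-variable rates mirroring the
  reference frame (HDL 12.0%, eGFR 6.0%, HbA1c 6.9%, total cholesterol
  5.8%, age at diagnosis 6.6%, smoking 0.8%, SBP 0.3%; proteins mostly
  complete, with a handful at 2%, a few in the 10–19% range and one above
  the QC limit). The default
  mechanism is missing-at-random: the masking probability is a logistic
  function of age and sex only (both always fully observed), with the
  intercept calibrated by bisection to the target rate. A handful of
  proteins are left-censored at a configurable quantile so the
  below-detection-limit QC rule is exercised.

What the generator does **not** emulate: real assay noise structure
(plate/batch effects, heteroscedastic NPX values), non-proportional
hazards, competing risks, informative censoring, measurement error in
clinical covariates, and realistic biological correlation networks beyond
the specified pairs. Tests passing on these cohorts therefore validate the
statistical machinery and the faithfulness of the workflow — not the
clinical performance of any particular signature on real data.

## Numerical methods and their settings

**Weighted Cox solver.** Newton–Raphson with step-halving on
counting-process data (Barlow weighting is expressed by row expansion:
pre-event and at-event rows with different weights). Convergence when the
maximal score component is ≤ 1e-8 or the relative log-likelihood change is
≤ 1e-10; cap 30 iterations. Ties are handled by Breslow's approximation —
standard for weighted pseudo-likelihoods, and event times are continuous
in the intended applications. A coefficient exceeding 15 on the per-SD
scale after convergence or iteration cap is treated as monotone-likelihood
separation: the estimate is capped and flagged with a warning rather than
silently returned. Exactly collinear predictor matrices are rejected. The
Breslow baseline cumulative hazard is stored with the linear predictor
centred at the weighted covariate mean, so `predict_absolute_risk()`
computes $1 - \exp(-H_0(t)e^{lp})$ directly.

**Penalised path.** The L1-penalised weighted partial likelihood is solved
over a grid of 100 penalties log-spaced from $\lambda_{\max}$ (the
smallest penalty with all penalised coefficients zero) down to
$10^{-3}\lambda_{\max}$, by an active-set sign-constrained Newton method
with warm starts: at each grid point the problem is solved exactly on the
current active set (a penalised coefficient may not cross zero within one
step; crossings are clamped and dropped), then the exact
partial-likelihood gradient is scanned over all predictors, violators of
the Karush–Kuhn–Tucker conditions join the active set, and the cycle
repeats until the certificate holds to 1e-7. The maximal KKT violation is
stored with every returned path. Penalised covariates are standardised by
the weighted mean/SD of the fitting sample; coefficients are reported on
the native scale.

**Cross-validation.** Ten folds stratified on event status; the
cross-validated error is the Verweij–van Houwelingen partial-likelihood
deviance $-2\{\ell_{\text{all}}(\hat\beta_{-k}) -
\ell_{\text{train}}(\hat\beta_{-k})\}$, which remains well defined when a
fold alone has too few events (the basic fold-wise form is available).
Fold fits run at a looser optimality tolerance (1e-3) with the exhaustive
KKT scan strided to every third grid point — the held-out deviance is flat
at that precision — while the returned full-sample path always carries the
strict certificate.

**Stability selection.** Resampling is stratified jointly on case status
and sub-cohort membership, preserving the case-cohort composition so the
Barlow fraction is recomputable per resample (naive whole-sample
resampling, also available, can distort the design). Per-resample paths
are truncated once more than 25 penalised covariates are active — about
three times the largest plausible signature — and inner fits run at
tolerance 1e-4; both bound compute in the dense path tail without
affecting which features can reach a 95% retention threshold.

**Evaluation.** Harrell's C is computed by exact $O(n^2)$ pair
enumeration (the earlier time must be an event; at tied times an event is
comparable with a censored subject; tied scores count 1/2), unweighted on
the analysis sample by default — the reference protocol is silent on
weighting discrimination, so both the unweighted convention (standard
Harrell) and weighted risk inputs are possible by scoring with any risk
vector. The difference between two correlated C-indices is tested with a
U-statistic projection estimate of the variance of the difference,
accounting for the covariance between the two concordance estimates, with
a two-sided normal p-value. Censoring in NRI enters through Kaplan–Meier
event probabilities within reclassification groups; in IDI through
inverse-probability-of-censoring weights at the horizon; on fully observed
data both reduce to plain proportions/means, which the tests exploit as
hand-computable oracles. Bootstrap confidence intervals are percentile
with seeded resampling (200 resamples by default in the pipeline; 1000 in
standalone calls). Decile calibration in the orchestrated pipeline is
assessed on the random sub-cohort only: the sub-cohort is representative
of the full cohort, while the appended outside-sub-cohort cases would
inflate the observed Kaplan-Meier event rates relative to the model's
cohort-scale absolute risks.

**Imputation.** The chained-equations loop (initialise by mean/mode, visit
variables by ascending missingness, re-predict each incomplete variable by
a random forest of 100 trees, stop at the first iteration where the change
statistic increases and return the previous iterate; normalised squared
change for continuous variables, disagreement proportion for
binary/categorical) is authored in the package; the forests themselves are
`ranger` ones, grown single-threaded with derived seeds so imputation is
fully reproducible. Iteration caps and tree counts are configuration
defaults, not claims about the reference protocol, which names only the
method.

## Design choices made where the design was open

* The clinical base model is **refit in-cohort** rather than using
  published external coefficients; an external-coefficient path exists via
  `model_spec()` but the reported metrics all come from in-cohort fits,
  matching how the reference results are presented.
* Barlow's original time-dependent weighting (case weight switching to 1
  at the event) is used rather than Prentice or self-weighted variants.
* Per-SD hazard ratios standardise the biomarker by the Barlow-weighted
  stratum SD by default (design-consistent for the full cohort); the
  unweighted SD is a switch.
* The layer-addition gate is the correlated-C p-value only, not NRI/IDI,
  since the stopping rule concerns discrimination.
* The bootstrap-resample count is the single knob scaled in the packaged
  examples and acceptance runs (B = 100 rather than 1000): selection
  frequencies are binomial proportions whose threshold comparison is
  stable at that resolution, while the per-resample protocol (ten-fold CV,
  full re-standardisation and re-weighting) is kept exactly.

## Problem sizes used by the packaged validation runs

The test-suite and the acceptance script exercise the machinery at sizes
chosen to be statistically informative on a single CPU: concordance
oracles at n ≤ 500 over 20 fixtures; weighted-fit unbiasedness over 200
case-cohort draws from one 8000-subject cohort (sub-cohort fraction 0.2);
correlated-C calibration over 500 null replicates at n = 400; stability
selection recovery with 4 planted proteins (|β| ≥ 0.40/SD) among 150
nulls at n = 1500 and ≈15% events over 12 seeded runs, plus 8 pure-noise
runs, at B = 100; imputation benchmarks over 20 seeds at n = 1000; decile
calibration at n = 10000; and the full pipeline at the default cohort
frame (2364 subjects) with a 160-protein panel. Each run states its seed;
all randomness flows through it.

## Known limitations

* Competing risks are ignored (events are a single composite); absolute
  risks are cause-specific complements of the all-cause-censored survival.
* Time-varying covariates and non-proportional hazards are out of scope.
* The stability-selection retention frequency is interpreted per sex on
  sex-stratified data; no cross-sex borrowing is attempted.
* The correlated-C variance is asymptotic; at very small event counts
  (< ~30 per stratum) the per-sex comparisons are unstable, and the
  package warns accordingly.
* The path truncation (`dfmax`) bounds the deepest penalties explored in
  resamples; cross-validated minima denser than the cap resolve to the
  densest fitted grid point.
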