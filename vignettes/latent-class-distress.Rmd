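---
title: "Latent classes of health risk and quality-of-life outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent classes of health risk and quality-of-life outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskclass)
```

## The problem

Surveillance surveys of adult health collect many correlated dichotomous
indicators. `riskclass` groups 24 such indicators into four domains —
risky behaviors (5 items), health conditions (8), health care access (5),
preventive services (6) — summarizes each domain with a latent class
model, and then asks how membership in the resulting risk classes relates
to two health-related quality-of-life outcomes: frequent physical and
frequent mental distress, defined as reporting 14 or more physically
(respectively mentally) unhealthy days out of the past 30. Dichotomizing
the day counts at 14+ follows the convention widely used for "frequent
distress" in surveillance work.

All 24 indicators are coded so that 1 is the adverse state (current
smoking, no coverage, *no* mammogram, ...). This polarity convention is
load-bearing: it makes a class's mean endorsement probability a risk
score, which is how classes are ordered and labelled.

## Stage 1: weighted latent class models

### Model

For a domain with J binary items, a K-class model has prevalences
$\pi = (\pi_1,\dots,\pi_K)$ and endorsement probabilities
$\rho_{cj} \in (0,1)$. Items are conditionally independent given class,
so a respondent with observed item set $\mathrm{obs}(i)$ and design
weight $w_i$ contributes

$$w_i \log \sum_{c=1}^{K} \pi_c \prod_{j \in \mathrm{obs}(i)}
  \rho_{cj}^{y_{ij}} (1-\rho_{cj})^{1-y_{ij}}$$

to the weighted log-likelihood. Cells missing by item nonresponse *and*
cells structurally missing (questions not asked because of the sex, age,
or cervix eligibility gates) are both simply excluded from the product —
a missing-at-random treatment. A record with nothing observed contributes
zero. Because the likelihood depends on the data only through distinct
response patterns, estimation collapses records to patterns with summed
weights; this is exact, and makes the EM cost independent of sample size.

### Estimation

`lca_fit()` maximizes the weighted likelihood by EM. Choices that matter:

* **Starts.** 20 random initializations by default ($\rho \sim$
  Uniform(0.2, 0.8), $\pi$ uniform), keeping the best final likelihood.
  Bernoulli-mixture likelihoods are multimodal; single-start EM is not
  trustworthy. Per-start seeds derive deterministically from one master
  seed, so fits are bit-reproducible.
* **Convergence.** Stop when the relative log-likelihood change falls
  below `tol = 1e-6` (default), or at `max_iter = 1000`. The per-iteration
  likelihood sequence is retained (`loglik_trace`) and is non-decreasing
  up to numerical noise — a property the test suite asserts across 100
  seeded fits.
* **Clamping.** M-step estimates of $\rho$ are clamped to
  $[10^{-6}, 1-10^{-6}]$, preventing $\log 0$ without materially moving
  interior solutions.
* **Weights.** Design weights are normalized to mean 1 before fitting.
  Point estimates are invariant to rescaling all weights; normalization
  additionally keeps the log-likelihood on the scale of the unweighted
  sample size, which matters for BIC.
* **BIC.** $\mathrm{BIC} = -2\,\ell + p\log n$ with
  $p = (K-1) + KJ$ and $n$ the *unweighted* respondent count.
  `lca_select()` fits $K = 1..K_{\max}$ (default 4) and takes the
  minimum. Pseudo-likelihood information criteria under weighting have no
  single convention; using the unweighted count with mean-1 weights is a
  defensible, and above all internally consistent, choice.
* **Ordering.** Classes are permuted so the risk score
  $s_c = \frac{1}{J}\sum_j \rho_{cj}$ is non-increasing (ties broken by
  larger $\pi$ first): class 1 is always the highest-risk class, and with
  three classes the labels low/intermediate/high attach to classes 3/2/1.
  Ordering resolves label switching between runs and gives the regression
  stage a stable reference level.
* **Posteriors.** `lca_posterior()` applies Bayes' rule over observed
  cells; a fully missing record gets the prior $\pi$. Modal assignment
  breaks ties toward the lower class index.

Covariates do not enter the measurement model: the latent class stage
sees only the indicators and weights. Degenerate requests (more classes
than distinct observed patterns) are fitted but flagged with a warning.

## Stage 2: weighted logistic regression

Modal class assignments — not posterior probabilities — enter the outcome
models as categorical covariates with the low-risk class as reference,
mirroring how such results are tabulated (reference rows printed as
`1 [Reference]`). Using hard assignments ignores classification error,
which attenuates class coefficients when entropy is low; bias-corrected
three-step estimators are out of scope and the limitation is stated here
deliberately.

`fit_weighted_logistic()` obtains point estimates by iteratively
reweighted least squares (`stats::glm`, quasibinomial family) and pairs
them with the sandwich covariance (`sandwich::sandwich`), the
with-replacement approximation appropriate when no stratum/PSU structure
is available — the synthetic data carry none. Wald 95% intervals and
two-sided p-values follow; no multiple-testing adjustment is applied.
Records missing the outcome or any covariate are dropped listwise and
counted; constant predictors (a single-class domain) are dropped with a
warning; exact collinearity is an error naming the aliased columns, and
quasi-separation is flagged. `prevalence_table()` reports weighted
outcome prevalences by demographic level with normal-approximation CIs
from the same variance family.

## The synthetic generator

`population_spec()` + `simulate_survey()` generate the survey the tests
and examples run on, emulating a statewide BRFSS-like landline sample:

* n = 4786 with a 3096/1690 female/male split, and demographic margins
  (three age groups, three race/ethnicity groups, three education levels,
  five employment categories) matching a typical adult sample of that
  size. These are the default study conditions; all are configurable.
* **Latent structure.** Each domain has three true classes by default,
  with prevalences 9/31/60% (behaviors), 6/18/76% (conditions), 10/7/83%
  (access) and 21/52/27% (preventive services) and endorsement profiles
  shaped like the published low/intermediate/high narrative for these
  domains. The profile *values* are synthetic, implementer-chosen numbers
  — no exact profiles are publicly printed. Domain memberships are drawn
  independently across domains: the real dependence structure between
  domains is unknown, and modelling it would add assumptions the tests
  do not need.
* **Raw responses, not indicators.** The generator draws each indicator
  from $\rho^*$, then emits a *raw* answer that the recoding module maps
  back to exactly that indicator value (a binge-drinking man gets a
  maximum-drinks answer of at least 5; an obese respondent a BMI in
  [30, 45]). The recoder is therefore exercised on every simulated
  record, and generator and recoder cannot drift apart.
* **Structural missingness.** Sex/age/cervix-gated screening questions
  are unasked for ineligible respondents; 80% of women have an intact
  cervix by default. Independent item nonresponse is injected at a
  configurable rate (default 2%) on top, never touching structural cells.
* **Weights.** weight = (age × sex post-stratification factor) ×
  lognormal(0, 0.5) noise — independent of the indicators given
  demographics, mimicking calibration weighting without modelling the
  telephone frame.
* **Outcomes.** Distress indicators are drawn from a logistic link on
  true class memberships and demographics; the default coefficients make
  conditions and access drive physical distress, with behaviors adding to
  mental distress, and preventive services null for both. Day counts are
  then drawn uniformly within the implied side of the 14-day cut.
* True class labels live in a sidecar (`$truth`) that `write_survey()`
  never emits, so estimation code cannot leak them.

What the generator does *not* emulate: stratified/clustered sampling
(weights are the only design feature), within-domain residual item
dependence, informative missingness, measurement error in self-report,
and between-domain correlation. Passing tests therefore validate the
estimators under conditional independence and MAR — the model's own
assumptions — not robustness to their violation in real data.

## Separation and what "recovery" can promise

Two separation regimes appear throughout the package:

* The **default profiles** are moderately separated, as realistic
  prevalence data are. At n ≈ 4800 the BIC choice between 2 and 3 classes
  is genuinely borderline there: the intermediate class is weakly
  identified and BIC, a conservative criterion, often merges it. This is
  a property of the information in the data, not an estimator defect.
* The **recovery profiles** (`separated_domain_spec()`: the classic
  0.9/0.5/0.1 shape, adjacent-class differences ≈ 0.4 on every item) are
  the study condition for parameter- and class-count recovery tests. The
  choice of 0.4 rather than the 0.3 floor is deliberate and statistical:
  near 0.3 the likelihood is flat enough that the *maximum-likelihood
  estimates themselves* scatter 0.06–0.09 from the truth at n = 5000 (we
  verified this by running an independently coded EM started at the
  truth — it converges to the same displaced optimum), so elementwise
  tolerances of ±0.05 (ρ) and ±0.03 (π) are only meaningful promises
  above that separation. Under the 0.4-separation condition the package
  recovers π and ρ within those tolerances in ≥ 90% of seeded
  replicates, selects K = 3 over K = 1..4 by BIC at survey scale, and
  changes recovered ρ by < 0.02 on average when 10% item nonresponse is
  injected at n = 10000.

## Numerical and edge-case behaviour

* Pattern counts: complete-data response patterns per domain enumerate to
  $2^5, 2^8, 2^5$, and — because of the sex gates in the preventive
  domain — $2^4$ for men and $2^5$ for women; `enumerate_patterns()`
  makes this checkable directly. (The preventive domain nominally has 6
  items but at most 5 are applicable to any one respondent.)
* The likelihood implementation is verified to $10^{-10}$ against a
  brute-force summation over latent assignments on small instances.
* Boundary ages at the eligibility gates (exactly 40, 50) are eligible;
  BMI exactly 30 is obese; exactly 14 unhealthy days is frequent
  distress; a man's fourth drink is not a binge and a woman's is.
* Ties: equal risk scores order by larger prevalence; equal posterior
  probabilities assign to the lower (higher-risk) class index.
* Reruns of `run_pipeline()` with the same input and seed are
  bit-identical, and the emitted manifest records everything needed to
  reproduce a run.

## Problem sizes used in the shipped checks

The test suite exercises the estimators at n = 200–5000 with 20 or fewer
replicates per property, the MAR comparison at n = 10000, and regression
coverage with 200 replicates at n = 5000; `scripts/acceptance.R` runs the
class-count selection at n = 4800 with 20 EM starts for each of
K = 1..4. These sizes put Monte-Carlo error comfortably inside the
asserted tolerances while keeping a full run to a few minutes.

## Known limitations

Within-domain conditional independence is assumed, not tested; no
covariates in the measurement model; modal assignment attenuates
second-stage coefficients; BIC's sample-size basis under weighting is a
convention, so absolute BIC values are not comparable to other software's
(the *ranking* across K, which is all that is used, is robust in our
replicates); and while `fit_weighted_logistic()` accepts stratum/PSU
labels for its variance (centering PSU score totals within stratum), the
synthetic generator produces no such design structure, so that path is
exercised only on artificial cluster labels in the tests.
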