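---
title: "Variable importance clouds: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable importance clouds: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicloud)
```

This vignette documents the statistical model behind `vicloud`, the
estimators it implements, and the numerical and design decisions taken where
the method leaves room for choice. The companion README shows the worked
workflow; here the emphasis is on *why* the pieces look the way they do.

## 1. The importance model

Conventional practice reads variable importance off a single fitted logistic
regression — coefficient magnitudes, p-values, or stepwise retention. All of
these are statements about one point in model space, chosen by maximum
likelihood from one sample. Two sources of instability follow: sampling
variability moves the fitted optimum between datasets, and even within one
dataset many models predict almost as well as the optimum while distributing
importance differently (the *Rashomon* effect).

`vicloud` therefore treats importance as a property of the **set of nearly
optimal models**. With mean negative log-likelihood
$L(\beta) = -\tfrac1n \sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]$,
$p_i = \operatorname{expit}(\beta_0 + x_i'\beta)$, a model is *eligible*
when $L(\beta) < (1 + \varepsilon)\, L(\hat\beta)$ with tolerance
$\varepsilon = 0.05$. Using the **mean** rather than summed likelihood makes
the tolerance a pure ratio, independent of the sample size — the intended
reading of "loss within 5% of the minimum".

Eligible models are reached by sampling
$\beta \sim \mathrm{MVN}(\hat\beta,\, m\,\hat\Sigma)$, where $\hat\Sigma$ is
the inverse observed information of the optimal fit and the scaling $m$ is
drawn uniformly from $[u_1, u_2]$. The uniform draw is the
minimal-assumption reading of "scaling bounded between $u_1$ and $u_2$"; the
draw is stored per member so the sampling distribution is auditable.
Ineligible candidates are rejected and sampling continues until exactly
$M$ eligible members exist (default $M = 250$), so the ensemble size is a
constant of the analysis rather than a random outcome. Eligibility is
assessed on the training loss, because the "minimum level" it is compared
against — $L(\hat\beta)$ — is a training quantity.

## 2. Tuning $u_1, u_2$

If $u_2$ is too small the ensemble collapses onto the optimum (importance
uncertainty is understated); too large and rejection sampling becomes
wasteful while the accepted models pile up at the eligibility boundary. The
tuner targets the band in which **70–80% of sampled candidates are
eligible**. It first scans a geometric grid of $(u_1, u_2)$ pairs
($u_1 \in 2^{-6..3}$, $u_2/u_1 \in \{2,4,8\}$, 200 pilot draws each,
proportions compared to the 0.75 midpoint). Because the eligibility
proportion is monotone non-increasing in the overall scale of the pair, a
best grid point outside the band is refined by bisection on that scale at
the chosen $u_2/u_1$ ratio until the pilot proportion lands inside the
band; if that fails the tuner stops with the full diagnostic table rather
than proceeding with an uncalibrated ensemble. The plain grid alone can
step over the band entirely on small cohorts, where the eligible scale
window is narrow — the bisection stage exists for exactly that case.

## 3. Per-model Shapley importance

Importance of variable $j$ to model $\beta$ is its Shapley value in the
coalition game $v(S)$ = expected loss when the design columns of variables
outside $S$ are replaced by **background** draws (marginal/interventional
imputation), averaged over explanation rows. Key choices:

* **Marginal, not conditional, imputation.** Conditional value functions
  need a joint density model of the predictors; marginal replacement is the
  standard global-importance (SAGE) practice and is exactly computable on
  a finite background sample. Consequence: correlated variables can share
  importance differently than a conditional formulation would.
* **Grouped play.** All $L-1$ indicator columns of a categorical variable
  join or leave a coalition together, so a 4-level variable is one player,
  not three. This also makes the value invariant to the choice of reference
  level (verified against the exact oracle in the tests).
* **Estimator.** Permutation sampling: for each sampled permutation of the
  $d$ variables, walk it from the empty coalition, recording each
  variable's incremental loss reduction. Each walk evaluates the increments
  on a mini-batch of (explanation row, background row) pairs
  (`batch_size`, default 10) — an average of single-pair walks that
  reduces per-walk variance at negligible cost, since the linear predictor
  updates incrementally per variable. Permutations are **antithetic** by
  default (each order paired with its reverse on the same batch); the
  standard error is the CLT estimate over independent units, i.e. over
  pair-averages when antithetic sampling is on.
* **Telescoping.** Within a walk the increments sum exactly to
  $v(\varnothing) - v(\text{full})$ on that walk's sample, so the Shapley
  efficiency identity holds to machine precision for the reported
  estimates — a structural invariant the tests assert at $10^{-9}$.
* **Oracle.** `exactShapleyOracle()` enumerates all $2^d$ coalitions with
  exact background averaging for $d \le 6$ and is the reference the
  sampling estimator is validated against (agreement within 3 SEs, error
  shrinking at the Monte-Carlo rate).

Explanation data: for large training sets a random half of the training
rows is used (the halving threshold defaults to $n \ge 3000$, e.g.
4494 → 2247), otherwise the full training set; the background pool is a
random subset of the explanation rows (default 100). This keeps the
per-model cost linear in the walk budget while leaving the estimand
unchanged.

## 4. Pooling and significance

The $M$ per-model estimates $s_{mj} \pm \mathrm{se}_{mj}$ are combined by
DerSimonian–Laird random-effects meta-analysis: $Q$, $C$ and
$\tau^2_j = \max(0, (Q - (M-1))/C)$ in closed form, random-effects weights
$1/(\mathrm{se}^2 + \tau^2)$, and the 95% **prediction interval**
$\bar s_j \pm t_{M-2,0.975}\sqrt{\tau^2_j + \mathrm{se}^2_{\text{pooled}}}$
(Higgins–Thompson df). The PI — not the narrower confidence interval of the
pooled mean — is the inferential object: it describes the importance a *new*
near-optimal model would assign, which is what "importance across the
Rashomon set" means. Significance is "PI entirely above zero". DL was chosen
over iterative REML for determinism and speed at $M = 250$; signed
estimates are pooled so negative importance (a variable whose inclusion
hurts this model) remains representable.

Degenerate inputs: pooling requires $M \ge 3$ (the $t$ df); if every SE is
zero, heterogeneity is carried by $\tau^2$ = sample variance alone; an
*isolated* zero SE — a Monte-Carlo artifact when all sampled increments for
a variable coincide, e.g. a rare binary under a small walk budget — is
floored at the smallest positive SE observed for that variable, keeping the
inverse-variance weights finite and the result deterministic.

## 5. Model building and evaluation

`backwardAIC()` is pure backward elimination on whole variables (one-hot
blocks never split): at each step the variable whose removal most decreases
$\mathrm{AIC} = 2k + 2nL$ is dropped, stopping when no removal decreases
it; dropped variables never re-enter (re-entry available behind a flag).
`assistedSelection()` prescreens to the significantly important variables
and then runs the same elimination, so its final model is always a subset
of the significant set — the mechanism by which a robustly non-significant
sensitive variable stays out of the model.

Evaluation: AUC from the tie-corrected Mann–Whitney rank statistic;
operating threshold = the unique score minimizing the Euclidean distance to
the ROC corner (ties broken toward higher specificity, then the higher
threshold); classification at score ≥ threshold (boundary rows are
positive). There is no single canonical CI method for such summary tables,
so all evaluation CIs use one uniform mechanism — the percentile bootstrap
over test rows (default 2000 resamples) — rather than mixing an analytic
DeLong-type AUC interval with bootstrap intervals for the ratios.

## 6. The synthetic cohort generator

No OHCA registry data are distributable, so the generator is a first-class,
tested module that emulates the *structure* the analysis assumes:

* 20 variables — 11 binary, 6 continuous, plus race (4 levels), time of day
  (3) and arrest location (3) — encoding to 24 design columns;
* registry-like marginals: published-style prevalences for the binary and
  categorical variables, and log-normal durations parameterised from
  median/quartile summaries via $\mu = \ln(\text{median})$,
  $\sigma = (\ln q_3 - \ln q_1)/(2 z_{0.75})$. A two-parameter log-normal
  reproduces the median and the quartile *ratio* exactly; the individual
  quartiles are exact only when symmetric in logs, and agree at the ~1%
  level for the durations used;
* dependence through a Gaussian copula on one latent normal per variable,
  with a modest hand-set block structure linking clinically related pairs
  (shockable rhythm–defibrillation 0.45, medication–epinephrine 0.60,
  witnessed–bystander CPR 0.30, duration–duration 0.2–0.35, age–rhythm
  −0.20). Monotone quantile maps make rank correlations increase with the
  latent correlation, which the tests verify;
* a logistic outcome with **known coefficients**: a strong shockable-rhythm
  effect (+1.6 log-odds), moderate intervention and location effects, and
  deliberately null blocks for gender, race, time of day and three duration
  variables — 13 of 20 variables carry signal. The intercept (1.8823) was
  calibrated once by Monte-Carlo bisection to a 15.4% outcome prevalence.

What the generator does *not* emulate: real registries have missingness,
measurement error, nonlinear effects, higher-order dependence and temporal
drift. Passing tests on this generator therefore demonstrate that the
estimators recover *known* structure under realistic marginals and
dependence — not that any particular real-data finding is reproduced.

## 7. Problem sizes, seeds and reproducibility

Everything downstream of data generation is a pure function of
(data, configuration, seed); the pipeline derives per-stage seeds from the
master seed by a fixed counter scheme (master × 1000 + stage offset) and
logs them. The test suite exercises the significance-recovery and
fairness-route properties at n = 4000 with M = 50 members and a
60-walk budget over 20 replicates, and the acceptance script runs the full
n = 7490 / 60–40-split workflow at the same reduced budget — sizes chosen
so the whole suite completes in minutes on one core while leaving the
Monte-Carlo error comfortably below the effects being tested. The
defaults (M = 250, 200 walks) are the recommended analysis settings.

## 8. Known limitations

* Marginal imputation spreads importance among strongly correlated
  predictors in a way that need not match a conditional formulation.
* The ensemble explores model space through the curvature of one optimal
  fit ($m\,\hat\Sigma$); under severe misspecification the cloud inherits
  that geometry.
* DL's $\tau^2$ is known to be biased low under strong heterogeneity with
  small $M$; at the default $M = 250$ this is immaterial, but very small
  ensembles should be interpreted cautiously.
* Backward AIC is a heuristic search; it is used here as the established
  comparator and final-model builder, not as an optimal subset method.
* Complete cases only: records with missing values are rejected at
  validation, by design.
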