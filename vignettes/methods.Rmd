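---
title: "Methods: longitudinal claims-based frailty trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal claims-based frailty trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(frailtraj)
library(dplyr)
```

This vignette documents the statistical methods implemented by frailtraj, the
conventions behind each default, and the numerical choices that matter for
reproducing results. The package studies how a claims-based frailty index
changes over the year after adjuvant chemotherapy initiation in an older
breast-cancer cohort, against a matched noncancer comparator cohort, entirely
on synthetic Medicare-like claims.

## 1. The claims-based frailty score

The score is a predicted probability of frailty from a logistic model over
demographics plus 20 binary claims indicators (durable medical equipment,
neurologic and geriatric conditions, ambulance services, and two
screening-service indicators that signal routine preventive care and carry
negative weights):

$$\text{score} = \operatorname{logit}^{-1}\Big(\beta_0 + \beta_a(\text{age}-65)
 + \beta_{\text{race}} + \sum_j \beta_j\, \text{flag}_j\Big).$$

Indicators are ascertained over a **half-open 180-day lookback window**
`[anchor - 180, anchor)`: the anchor day itself is excluded so claims generated
by same-day treatment cannot leak into the window anchored on the treatment
date. All window logic in the package flows through `in_window()`, and the
boundary behaviour is pinned by tests (day −1 and day −180 are in; day 0 and
day −181 are out). Flags are binary — repeat claims never accumulate — which
makes scoring invariant to claim duplication and row order.

The originally published coefficient values are not reproduced here; the
package ships a documented synthetic default (`default_frailty_model()`) with
the published *sign structure* (deficits positive, screening negative) and an
intercept calibrated so the default synthetic cohort scores near 0.04 at
chemotherapy initiation. Any coefficient set can be supplied via
`read_frailty_model()` (YAML). `apply_sensitivity()` zeroes the two
screening-indicator coefficients for the sensitivity analysis in which score
changes cannot be driven by deferred routine care.

```{r score-example}
model <- default_frailty_model()
bundle <- simulate_population(sim_config(n_chemo = 200, seed = 1))
anchors <- tibble::tibble(person_id = bundle$cancer$person_id,
                          anchor = bundle$cancer$chemo_start_date)
iv <- extract_indicators(bundle$claims, bundle$persons, anchors)
summary(frailty_score(iv, model)$score)
```

## 2. Cohorts: eligibility chain and matched comparators

`build_chemo_cohort()` applies, in order: age ≥ 65 at diagnosis; stage I–III;
primary surgery within 90 days of diagnosis (closed interval); no neoadjuvant
chemotherapy; adjuvant chemotherapy within 90 days after surgery; and
continuous fee-for-service enrollment from diagnosis (or 180 days before the
index date, whichever is earlier) through the index date — the chemotherapy
initiation date. Every step is recorded in an exclusion ledger.

`match_comparators()` samples up to 5 noncancer comparators per case, matched
exactly on year of birth and region, **with replacement across match groups**
(a popular comparator can serve several cases) but without duplication within
a group. Comparators inherit the case's index date and must be alive on it
and continuously enrolled for the 180 days before it. Baseline covariates for
both arms: the Gagne combined comorbidity score over the 180-day preindex
window (cancer conditions excluded when scoring a cancer cohort),
categorized as <0 / 0 / 1 / 2 / ≥3, and a preindex flu-vaccination flag.

## 3. Weighting

**SMR weights** (`fit_propensity()`, `smr_weights()`): chemo rows get weight
1; comparator rows get the propensity odds $\hat p/(1-\hat p)$, standardizing
the comparator covariate distribution to the chemo cohort. With a saturated
propensity model this balances weighted comparator covariate means to the
chemo means *exactly* (to numerical precision) — a property the test suite
asserts at 1e-10. Comparator weights above the 99th percentile are capped by
default; truncation never raises the maximum weight.

**Attrition weights** (`build_attrition_panel()`, `fit_attrition_models()`,
`ipaw_weights()`): discrete-time pooled logistic hazard models, one per cause
(death; disenrollment before death), over two person-periods (index to 4
months; 4 to 10 months), each with period-specific intercepts
(`factor(period)`) plus baseline covariates, time-varying Gagne score and the
lagged frailty score. The weight at timepoint $k$ is the inverse cumulative
product of the cause-specific retention probabilities. Two identities anchor
correctness: with constant retention 0.8 per period the T3 weight is
$1/0.8^2 = 1.5625$; and with intercept-only models and a *single* active
cause, the weight among persons observed at T3 is exactly the inverse
empirical two-period retention. (With two simultaneous causes the product of
per-cause retentions is not the empirical joint retention, so the exactness
statement requires the single-cause setting.)

## 4. The weighted GEE benchmark

`fit_gee()` estimates the marginal mean model

$$E[Y] = b_0 + b_1\,\text{arm} + b_2\,T2 + b_3\,T3 + b_4\,\text{arm}{\times}T2
 + b_5\,\text{arm}{\times}T3$$

with gamma variance function ($V(\mu) = \phi\mu^2$), identity link, AR(1)
working correlation, and a cluster-robust sandwich covariance. The solver is
Fisher scoring on the estimating equations with moment estimators for $\phi$
(weighted Pearson) and the AR(1) parameter (weighted lag-1 residual moment).
No GEE package is used. Observation weights (SMR × IPAW) multiply the
residual in the estimating function,
$\sum_i D_i' V_i^{-1} W_i (y_i - \mu_i) = 0$, the convention under which
inverse-probability weights yield unbiased estimating equations (rather than
entering the variance as prior weights).

Numerical notes:

* On a saturated design under independence working correlation the solution
  equals the weighted cell means — a closed-form oracle used in tests.
* Doubling an observation's weight is equivalent to duplicating its cluster
  for the point estimates, $\phi$, and the AR(1) moment (the sandwich differs,
  as it must).
* Single-arm panels deactivate the arm main effect *and* the interactions
  (which would otherwise duplicate the time dummies); those terms report NA.
* Monte-Carlo recovery at n = 20 000 is unbiased within Monte-Carlo error and
  interaction CI coverage sits in the low-to-mid 90s (asserted in the
  acceptance tests).

## 5. Trajectory clustering

`score_series()` produces 13 monthly scores (days 0, 30, …, 360), each with
its own 180-day lookback; anchors on/after death or after the end of
continuous coverage are omitted, so missingness is always a suffix
(monotone dropout). `build_trajectories()` enforces this and drops persons
with fewer than 3 observed months.

`kmeans_long()` clusters under the missing-aware rescaled distance
$d^2(a,b) = (T/T_{\text{obs}})\sum_{t \in \text{shared}} (a_t-b_t)^2$.
Center updates are anchor-wise means weighted by each person's
$T/T_{\text{obs}}$ factor. This is the update that actually minimizes the
rescaled within-cluster sum (plain anchor-wise means do not under
missingness, and can violate monotone descent); on complete data it reduces
to plain means. The within-cluster sum is nonincreasing across iterations,
restarts keep the best solution, and small instances (n ≤ 100) get a
single-move refinement pass after Lloyd convergence — together these make the
solver attain the exhaustive-partition optimum on small instances, which the
test suite checks by brute force.

Seeding matters: with class shares down to 1%, uniform restart seeding
essentially never proposes a seed in a rare class. The first start is a
deterministic farthest-first (Gonzalez) traversal and the remaining starts
use k-means++ distance-squared sampling.

The number of clusters is chosen by the Calinski–Harabasz criterion
(`select_k()`), and `label_clusters()` applies rule-based shape labels:
*robust* if the center rises less than 0.02 above baseline; otherwise
*resilient* if at least half the rise is recovered by month 12; otherwise
*nonresilient*; plus a low/medium/high baseline tag at cutpoints 0.1 and 0.2.
Gaussian-kernel posteriors with pooled within-cluster variance quantify
assignment confidence.

```{r clustering-example}
s <- simulate_trajectories(1500, noise_sd = 0.006, seed = 2)
traj <- build_trajectories(s$trajectories)
sol <- select_k(traj, k_range = 2:7, n_starts = 10, seed = 3)
label_clusters(sol)
```

## 6. Predictors of nonresilience

`build_design()` codes the predictor table: age centered at 65; race with
API and AI/AN collapsed to *Other* and missing race at the reference (White);
region (ref West); stage (ref I); surgery (ref breast-conserving); grade
(ref well differentiated, missing at reference); Gagne category with the ≤0
bins merged as reference; flu vaccination; and the 20 baseline indicator
flags. `fit_nonresilience()` is maximum-likelihood logistic regression with
Wald CIs; (near-)separation is a hard error rather than a silently huge OR.

## 7. The synthetic generator and its scope

`simulate_population()` emits persons, enrollment spells, coded claims and
cancer records plus a latent truth table that no analysis stage reads. Chemo
cases draw one of six latent trajectory classes
(mixture 0.78/0.15/0.01/0.04/0.01/0.01); comparators get a gently drifting
latent level. Indicator claims are Bernoulli draws per 30-day block with
window probability $\operatorname{logit}^{-1}(a_j + b_j \cdot
\text{latent})$; death and disenrollment are per-month logistic hazards in
the current latent level (informative attrition), with a chemo-arm shift on
the death hazard.

Two structural facts shaped the calibration of the defaults (done once at
design time, then frozen):

* Because every score anchor looks back 180 days, the scored series is
  approximately a 6-month moving average of the latent series; the acute
  latent excursion therefore peaks at month 2 so the *score* peaks near
  month 4 and eases by month 10.
* The latent→score map must be approximately linear over the operating range
  [0.03, 0.35]; the indicator loadings are designed so common office-based
  indicators saturate early (concave) while rare equipment indicators stay
  rare with small slopes (convex), and the two effects roughly cancel.
  A strongly convex map would let the rare late-rising classes dominate the
  10-month mean and erase the chemo-arm recovery.

The generator targets the qualitative study pattern (chemo mean rises to 4
months and partially recovers by 10 months while staying above baseline;
comparator mean drifts gently up; deaths ≈ 3% vs 1% by 10 months), not exact
published mean levels: the claims→score channel cannot hit every published
level simultaneously, and pattern fidelity was prioritized.

## 8. Open numerical choices, and why

* **Cluster-count selection needs stronger separation than membership
  recovery.** With 1%-share classes, Calinski–Harabasz prefers merging a rare
  class until the between-class gap is ≈ 8–10× the within-class SD, even
  though memberships (ARI) recover at ≈ 5×. Count-recovery checks therefore
  use `noise_sd = 0.006` with the default curves.
* **Truncation percentiles** for SMR and IPAW weights default to 0.99,
  applied to the comparator (SMR) or all (IPAW) weights; truncation can only
  lower weights.
* **GEE convergence** is declared at a 1e-10 step; non-convergence is a hard
  error, not a silent return.
* **Propensity/outcome logistic separation** aborts: weights and ORs from a
  separated fit are meaningless.
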