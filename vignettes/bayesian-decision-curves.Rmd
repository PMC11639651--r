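---
title: "Bayesian decision curves: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian decision curves: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postDCA)
```

This vignette documents the statistical models behind `postDCA`, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical and design decisions taken where more than
one defensible option existed.

## Net benefit and its posterior

At a decision threshold $t$ (the predicted risk above which we
intervene), net benefit prices one false positive at
$w_t = t/(1-t)$ true positives:

$$NB_t = \frac{TP_t - FP_t \, w_t}{n}
       = Se_t \, p - (1 - Sp_t)(1 - p)\, w_t,$$

where the second form rewrites the counts in terms of the prevalence
$p$, sensitivity $Se_t$ and specificity $Sp_t$ of the strategy at that
threshold. Treat-all has $NB = p - (1-p)w_t$; treat-none has $NB = 0$.
These identities are exact on any finite population, and the test suite
asserts them against direct count evaluation.

### Binary outcomes: conjugacy, no MCMC

Modeling disease status and the positive-prediction indicator jointly,
the likelihood factorizes into three independent Bernoulli pieces (one
per parameter), so with independent $\text{Beta}(\alpha_j, \beta_j)$
priors the joint posterior is the product of marginals:

$$p \sim \text{Beta}(D+\alpha_0,\ ND+\beta_0), \quad
  Se_t \sim \text{Beta}(TP_t+\alpha_1,\ FN_t+\beta_1), \quad
  Sp_t \sim \text{Beta}(TN_t+\alpha_2,\ FP_t+\beta_2).$$

Independent marginal draws therefore *are* joint posterior draws; the
suite verifies the closed form against a brute-force grid Bayes update
of the Bernoulli likelihood (sup-norm below $10^{-6}$) and checks that
empirical correlations between the three margins vanish. Specificity is
parameterized directly (not its complement) so that priors read the way
users think about test accuracy.

Two structural points carry most of the statistical value:

* **The prevalence draws are shared** by every strategy and every
  threshold within one analysis. Cross-curve contrasts (model minus
  treat-all, model minus competitor) are therefore computed on
  index-aligned draws and are much tighter than the marginal intervals
  suggest. For the same reason the interrogation functions refuse to
  operate on independently re-sampled draws — re-sampling would destroy
  exactly the correlation that makes the contrasts precise.
* **Case-control designs**: the sample case fraction estimates nothing,
  so `external_prevalence = c(cases, noncases)` replaces the prevalence
  posterior with $\text{Beta}(\text{cases}+\alpha_0,
  \text{noncases}+\beta_0)$ built from external population data,
  propagating prevalence uncertainty instead of plugging in a point
  estimate.

### Survival outcomes: Beta × censored Weibull

With a prediction horizon $\tau$ and predicted event risks
$\hat r_\tau$, net benefit becomes

$$NB_{t,\tau} = (1 - S)\,p - S\,p\,w_t, \qquad
  p = P(\hat r_\tau > t), \quad S = S(\tau \mid \hat r_\tau > t).$$

The positivity indicator is Bernoulli, giving $p$ a conjugate Beta
posterior. Follow-up among positive predictions is modeled as Weibull
with right censoring, $S(\tau) = \exp\{-(\tau/\sigma)^\alpha\}$; its
posterior has no closed form and is sampled by MCMC (JAGS, latent-time
augmentation for censored records). Because the likelihood factorizes
across the positivity indicator and the two arms of follow-up, the
event-time distribution among *negative* predictions is a nuisance
component that never needs to be sampled. One algebraic point is worth
recording: the survival function is implemented in the standard
shape–scale form $\exp\{-(\tau/\sigma)^\alpha\}$, the only form
consistent with the censored-Weibull likelihood used for fitting.

For the treat-all curve the positivity probability is identically 1 and
the relevant survival is the cohort's: a single Weibull fit to all
patients is shared across thresholds. (The alternative — re-using the
per-threshold machinery with an everyone-positive indicator — gives the
same posterior at every threshold while costing one MCMC run per
threshold, so the shared fit is both the cheaper and the cleaner
reading.)

Default priors: uniform Beta(1, 1) on all probability parameters;
Half-Student-$t(5, 0, 1.5)$ on the Weibull shape and
Half-Student-$t(30, 0, 100)$ on the scale. The shape prior puts roughly
equal mass on increasing ($\alpha > 1$) and decreasing hazards; the
scale prior is vague over plausible time scales (its units are the time
units of the data — months in all shipped settings). A Gamma option
exists for both parameters but has no canonical default; it requires
explicit `(shape, rate)` pairs.

## Interrogation statistics

All four statistics are draw-wise functionals of the joint posterior,
with strict inequalities throughout (the posteriors are continuous, so
ties are null events, and strictness keeps degenerate identical-strategy
comparisons well defined — an identical pair has superiority probability
0, not ½):

* $P(\text{useful}) = P(NB > \max\{NB_{\text{all}}, 0\})$, defined for
  model strategies;
* $P(\text{best})$: probability of strictly exceeding the draw-wise
  maximum over *all* other strategies, defaults included. With one model
  it reduces exactly to $P(\text{useful})$; with several,
  $P(\text{best}) \le P(\text{useful})$ and the values sum to 1 across
  strategies;
* pairwise superiority $P(NB_1 - NB_2 > c)$ with margin $c \ge 0$ (in
  net-true-positive units, e.g. differential test harm), returned with
  the full difference draws for density displays (66% and 95% intervals
  in the standard figure);
* $EVPI = E[\max_s NB_s] - \max_s E[NB_s]$, per threshold, with the
  inner maximum computed within each joint draw. Jensen's inequality
  makes it non-negative; no smoothing across thresholds is applied.

Reported probabilities are Monte-Carlo estimates with standard error at
most $\sqrt{0.25/M}$; with the default $M = 4000$ that is under 0.008.
Raw values are kept in all exports (nothing is clamped in data files).

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| threshold grid | 0 to 0.5 by 0.01 | false negatives assumed at least as costly as false positives; fully overridable, all $t \in [0,1)$ |
| positivity rule | prediction $> t$ | strict; ties count as negative, so a 0/1 test is positive at every $t \in (0,1)$ |
| draws $M$ | 4000 | binary: Beta sampling, essentially free; survival: `chains × draws` retained MCMC draws |
| MCMC | 4 chains, 1000 warmup + 1000 kept | convergence gate: split-$\hat R > 1.01$ raises an error carrying the diagnostics (downgradable to a warning); the gate is calibrated to this default — short chains make split-$\hat R$ noisy, and `rhat_max` should be relaxed accordingly |
| horizon $\tau$ | none | must be explicit for survival analyses; same units as the time column |
| priors | uniform / half-$t$ | per-threshold prior tables for $Se$/$Sp$ are accepted (`data.frame(threshold, shape1, shape2)`, optionally nested per strategy) as the hook for threshold-dependent informative priors; their construction is left to the analyst |
| margin $c$ | 0 | pairwise comparisons only; must be $\ge 0$ |

## Degenerate inputs and numerical choices

* **No positive predictions at a threshold.** The conjugate posteriors
  remain proper (prior-dominated); the survival model falls back to
  direct prior draws. Nothing collapses to zero — a warning is emitted
  and a `zero_positives` flag travels into every output table. This is
  the regime where bootstrap-based intervals degenerate, and it is the
  main practical argument for the parametric posterior.
* **No data at all** (zero external counts, empty record set): the
  posterior *is* the prior, returned as such.
* **Times must be strictly positive** (Weibull support); validation is
  complete-case, and rows with missing values are rejected with their
  indices reported rather than imputed — the per-threshold counts that
  feed the posterior are only defined on complete records.
* **Event coding**: `event = 1` means the event was observed; data
  sources that code *censoring* as 1 must be flipped at ingestion (the
  reader documents this).
* **Reproducibility**: every stochastic entry point takes a seed;
  derived seeds (per replicate, per MCMC chain) come from a
  deterministic integer stream kept below $2^{31}$, so any replicate of
  a simulation study can be re-run in isolation bit-for-bit.

## What the synthetic-data engine emulates

The binary generator draws $x_1, x_2 \sim$ iid Exp(1), true risks from a
logistic model, outcomes from those risks, and companion predictions
from a second coefficient vector with *inflated* slopes — predictions
too extreme in both directions, the signature of an overfit model. The
six shipped settings cross maximum achievable AUC (0.65, 0.85) with
prevalence (1%, 5%, 30%). The survival generator draws standard-normal
covariates, Weibull proportional-hazards event times by inverse-CDF
sampling (verified against an accept–reject sampler of the same
hazard), Uniform(0, 24)-month censoring, and model risks
$1 - \exp\{-\lambda \tau^\gamma e^{x^\top \hat\beta}\}$ — the true
baseline with exaggerated coefficients, so miscalibration enters purely
through the coefficients, mirroring the binary design. Validation sets
are drawn without replacement, sized as
$n = \text{round}(E[\text{events}]/\text{event rate})$ with a default of
100 expected events (333 / 2,000 / 10,000 patients at prevalences
30% / 5% / 1%); for survival populations the event rate is the realized
fraction of non-censored events.

Two honest caveats. First, the labels on the survival settings are
rounded descriptors: under its printed parameters, `surv_c095_s50` has
an exact marginal 12-month survival of 0.475, not 0.50 (numerical
integration over the covariate distribution; the acceptance suite
measures this on a 2-million-patient population and reports that setting
as out of band rather than adjusting it). Second, the data the
generators produce is idealized — independent patients, no covariate
shift between "development" and "validation", smooth unimodal risk
distributions, non-informative censoring. Passing coverage tests on
these populations says the posterior machinery is calibrated when its
assumptions hold; it does not certify calibration under informative
censoring, clustered data or distribution shift.

The simulation harness itself scores, per threshold: empirical coverage
of 95% credible intervals against the population-oracle true net benefit
(never against sample quantities), mean absolute percentage error, and
bias. Study sizes used by the shipped tests and the acceptance script —
populations of $10^5$ (binary) and $2 \times 10^6$ (survival
calibration), 500 replicates, $M = 4000$ — were chosen so the whole
suite runs comfortably on a single CPU while keeping Monte-Carlo noise
well below the tolerances being asserted.

## Known limitations

* The Weibull family is a working model: in the simulated populations
  the follow-up of the positive-prediction subset is a covariate mixture
  of Weibulls, so the fitted model is mildly misspecified by
  construction. Together with the known small-sample bias of Weibull
  shape estimation this produces slight undercoverage at extreme
  thresholds in some survival settings; the recovery tests therefore
  assert 95% interval coverage of at least 88% rather than the nominal
  value. Orthogonal reparameterizations of the Weibull likelihood are a
  plausible refinement.
* Survival mode runs one MCMC per strategy–threshold cell: a 50-point
  grid is minutes, not seconds. The binary path has no such cost.
* No competing risks, time-varying predictions, repeated measures, or
  multi-setting (meta-analytic) pooling; one validation sample at a
  time.
* EVPI is reported for model validation only; sample-information
  extensions (EVSI) and non-linear implementation utilities are out of
  scope.
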