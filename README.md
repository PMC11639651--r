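# postDCA

Bayesian decision curve analysis (DCA) for validating clinical prediction
models and diagnostic or prognostic tests, for binary and survival
outcomes.

## What problem this solves

When a risk model or test is externally validated, the question that
matters for practice is not its AUC but whether *acting* on its
predictions does more good than harm. DCA answers this with the **net
benefit** at a decision threshold *t* (the predicted risk above which one
intervenes):

    NB_t = (TP_t − FP_t · w_t) / n,        w_t = t / (1 − t)

i.e. true positives per patient, with false positives priced at
`w_t` — the exchange rate implied by the threshold itself. The best
strategy at a threshold is the one with the highest net benefit, always
compared against the defaults of treating everyone
(`NB_all = p − (1 − p) w_t`, with `p` the prevalence) and treating no one
(`NB = 0`).

Observed net benefit is subject to sampling noise. `postDCA` estimates
the *posterior distribution* of every decision curve:

* **Binary outcomes.** The joint model of disease status and positive
  predictions factorizes, so with independent Beta priors the posterior
  is exactly `Beta(D+α₀, ND+β₀) × Beta(TP+α₁, FN+β₁) × Beta(TN+α₂, FP+β₂)`
  for (prevalence, sensitivity, specificity) — no MCMC, a full DCA takes
  well under a second. Net benefit draws follow from
  `NB = Se·p − (1−Sp)(1−p)·w_t`.
* **Survival outcomes.** At horizon τ,
  `NB = (1 − S(τ|r̂>t))·P(r̂>t) − S(τ|r̂>t)·P(r̂>t)·w_t`. The positivity
  probability gets a conjugate Beta posterior; the event-time
  distribution among positive predictions is modeled as a right-censored
  Weibull sampled by MCMC (half-Student-t priors on shape and scale by
  default), and `S(τ) = exp{−(τ/σ)^α}`.

Because the posteriors are full joint distributions (with the prevalence
parameter shared across all curves, which makes between-curve contrasts
far more precise than the marginal intervals suggest), the decision
curves can be *interrogated*:

* `p_useful` — P(strategy beats both defaults) at each threshold;
* `p_best` — P(strategy beats every other strategy under consideration);
* `pairwise_superiority` — P(NB₁ − NB₂ > c) with a harm margin `c ≥ 0`;
* `evpi` — expected value of perfect information,
  `E[max_s NB_s] − max_s E[NB_s]`: the expected net benefit lost by
  deciding under current uncertainty.

A synthetic-data module reproduces the canonical logistic and Weibull
proportional-hazards populations (with miscalibrated companion models
emulating overfitting) and a harness measures credible-interval coverage
and estimation error against population oracles.

## Worked example

Validate a (deliberately miscalibrated) risk model and a binary
standard-of-care test with 81% sensitivity / 88% specificity on a
simulated external validation sample with 100 expected events:

```r
library(postDCA)
set.seed(2026)
pop <- generate_binary_population("binary_auc085_prev30", 1e5)
val <- sample_validation_set(pop, expected_events = 100)
soc <- simulate_binary_test(val$outcome, se = 0.81, sp = 0.88)
dat <- binary_validation_data(val$outcome,
                              list(model = val$predictions$model, soc = soc))
fit <- dca_binary(dat, threshold_grid(min = 0.05, max = 0.45, step = 0.10),
                  M = 4000, seed = 1)
res <- interrogate(fit)
subset(res, strategy == "model",
       select = c(threshold, nb_mean, nb_lo, nb_hi, p_useful, p_best, evpi))
```

```
 threshold nb_mean  nb_lo nb_hi p_useful p_best     evpi
      0.05   0.267 0.2185 0.317    0.122 0.1215 0.000447
      0.15   0.222 0.1731 0.273    0.968 0.1775 0.001804
      0.25   0.192 0.1440 0.246    1.000 0.0428 0.000365
      0.35   0.165 0.1133 0.217    1.000 0.0198 0.000138
      0.45   0.133 0.0777 0.191    1.000 0.0155 0.000136
```

Reading this: from *t* = 0.15 upward the model is almost certainly
useful (`p_useful` near 1 — it beats treating everyone and treating no
one), yet it is rarely the *best* available strategy (`p_best` small),
because the simulated standard-of-care test has higher net benefit in
this sample. A direct comparison confirms it:

```r
pairwise_superiority(fit, "model", "soc", t = 0.25)$prob
#> [1] 0.043
evpi(fit, 0.25)
#> [1] 0.000365
```

So at the 25% threshold there is only a 4% posterior probability that
the model beats the test, and committing to the apparently best strategy
today costs an expected 0.0004 net true positives per patient relative
to knowing the truth — about 4 per 10,000 decisions.

Survival outcomes work the same way through `dca_survival()` (explicit
prediction horizon required); `run_dca()` / `run_simulation()` drive the
whole workflow from a YAML/JSON config, and
`inst/scripts/dca-cli.R` wraps them for the shell.

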