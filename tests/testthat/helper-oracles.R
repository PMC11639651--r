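# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: grid Bayes updates, brute-force loops and
# resampling stand in for the closed forms they check.

# Posterior CDF of a Bernoulli success probability by brute force: a
# trapezoid-rule Bayes update of prior(theta) * theta^k (1-theta)^(n-k)
# on a uniform grid, normalized by its own integral. Evaluation points
# are snapped to grid nodes. Assumes prior shapes >= 1 (finite density).
grid_posterior_cdf <- function(k, n_minus_k, prior_shape1, prior_shape2,
                               at, n_grid = 1e6) {
  theta <- seq(0, 1, length.out = n_grid + 1)
  f <- theta^(k + prior_shape1 - 1) * (1 - theta)^(n_minus_k +
                                                     prior_shape2 - 1)
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  idx <- round(at * n_grid) + 1
  stopifnot(max(abs(theta[idx] - at)) < 1e-12)
  cdf[idx]
}

# Sample net benefit by direct evaluation of the count definition
# NB = (TP - FP * t/(1-t)) / n.
sample_nb_binary <- function(outcome, pred, t) {
  z <- pred > t
  (sum(z & outcome == 1) - sum(z & outcome == 0) * t / (1 - t)) /
    length(outcome)
}

# Minimal percentile bootstrap of the sample net benefit (frequentist
# comparator oracle, 500 resamples).
boot_nb_binary <- function(outcome, pred, t, B = 500) {
  n <- length(outcome)
  stat <- replicate(B, {
    idx <- sample.int(n, n, replace = TRUE)
    sample_nb_binary(outcome[idx], pred[idx], t)
  })
  quantile(stat, c(0.025, 0.975), names = FALSE)
}

# Accept-reject sampler for Weibull proportional-hazards event times with
# linear predictor eta: density f(t) = g l t^(g-1) e^eta exp(-l t^g e^eta),
# using a uniform proposal over an upper support bound.
ar_weibull_ph <- function(n, gamma, lambda, eta) {
  rate <- lambda * exp(eta)
  t_max <- (-log(1e-9) / rate)^(1 / gamma)
  dens <- function(t) gamma * rate * t^(gamma - 1) * exp(-rate * t^gamma)
  f_max <- max(dens(seq(1e-6, t_max, length.out = 20000)))
  out <- numeric(0)
  while (length(out) < n) {
    m <- 4 * (n - length(out))
    cand <- runif(m, 0, t_max)
    keep <- runif(m) < dens(cand) / f_max
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}

# Right-censored Weibull(alpha, sigma) sample with uniform censoring
# calibrated so that the expected censored fraction equals `frac`.
make_censored_weibull <- function(n, alpha, sigma, frac) {
  p_cens <- function(b) {
    integrate(function(t) pweibull(t, alpha, sigma, lower.tail = FALSE),
              0, b)$value / b
  }
  b <- uniroot(function(b) p_cens(b) - frac, c(sigma / 20, sigma * 50))$root
  tt <- rweibull(n, alpha, sigma)
  cc <- runif(n, 0, b)
  list(time = pmin(tt, cc), event = as.integer(tt <= cc),
       true_time = tt, censor_bound = b)
}

# Construct a tiny decision curve set from per-strategy draw vectors at a
# single threshold (helper for the hand-enumerated interrogation examples).
tiny_set <- function(draws, t = 0.1) {
  decision_curve_set(lapply(draws, function(x) matrix(x, nrow = 1)),
                     threshold_grid(t))
}

expect_threshold_grid_equal <- function(a, b) {
  expect_equal(a$threshold, b$threshold)
  expect_equal(a$weight, b$weight)
}
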