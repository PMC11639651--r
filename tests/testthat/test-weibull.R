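test_that("censored log-likelihood matches explicit per-record terms", {
  # exponential special cases: alpha = 1, sigma = 2, t = 2
  expect_equal(weibull_censored_loglik(1, 2, times = 2, events = 1),
               log(1 / 2) - 1)
  expect_equal(weibull_censored_loglik(1, 2, times = 2, events = 0), -1)
  expect_error(weibull_censored_loglik(-1, 2, 1, 1), "positive")
  expect_error(weibull_censored_loglik(1, 0, 1, 1), "positive")

  withr::with_seed(14, {
    alpha <- 1.7; sigma <- 8
    tt <- rweibull(50, 1.4, 9)
    ev <- rbinom(50, 1, 0.6)
    # hand-written density and survival terms
    f <- function(t) (alpha / sigma) * (t / sigma)^(alpha - 1) *
      exp(-(t / sigma)^alpha)
    S <- function(t) exp(-(t / sigma)^alpha)
    oracle <- sum(log(f(tt[ev == 1]))) + sum(log(S(tt[ev == 0])))
    expect_equal(weibull_censored_loglik(alpha, sigma, tt, ev), oracle)
  })
})

test_that("survival at the horizon follows the Weibull survival function", {
  expect_equal(survival_at_horizon(1, 5, tau = 5), exp(-1))
  expect_equal(survival_at_horizon(2, 10, tau = 5), exp(-0.25))
  expect_equal(survival_at_horizon(1.3, 7, tau = 1e-9), 1, tolerance = 1e-6)
  expect_error(survival_at_horizon(1, 5, tau = -1))
})

test_that("positivity posterior is the closed-form Beta update", {
  prior_draws <- sample_positivity(0, 0, M = 20000, seed = 5)
  expect_gt(suppressWarnings(ks.test(prior_draws, punif))$p.value, 0.01)
  dr <- sample_positivity(50, 100, M = 50000, seed = 6)
  expect_equal(mean(dr), 51 / 102, tolerance = 2e-3)
  a <- 51; b <- 51
  expect_equal(var(dr), a * b / ((a + b)^2 * (a + b + 1)),
               tolerance = 0.02)
})

test_that("zero survival records return the prior, with a warning", {
  expect_warning(
    fit <- sample_weibull_posterior(numeric(0), numeric(0),
                                    chains = 2, draws = 5000, seed = 8),
    "prior")
  expect_true(fit$prior_only)
  # half-t CDF: F(x) = 2 (T_df(x / scale) - 1/2)
  phalf_t <- function(q, df, scale) 2 * (pt(q / scale, df) - 0.5)
  expect_gt(suppressWarnings(
    ks.test(fit$alpha, phalf_t, df = 5, scale = 1.5))$p.value, 0.01)
  expect_gt(suppressWarnings(
    ks.test(fit$sigma, phalf_t, df = 30, scale = 100))$p.value, 0.01)
})

test_that("MCMC recovers Weibull parameters on uncensored data", {
  withr::with_seed(9, {
    tt <- rweibull(600, 1.5, 10)
    fit <- sample_weibull_posterior(tt, rep(1, 600), chains = 2,
                                    warmup = 600, draws = 600, seed = 10)
    expect_equal(mean(fit$alpha), 1.5, tolerance = 0.1)
    expect_equal(mean(fit$sigma), 10, tolerance = 0.1)
    expect_true(all(fit$diagnostics$rhat < 1.02, na.rm = TRUE))
    expect_true(all(fit$alpha > 0) && all(fit$sigma > 0))
    # exponential data: sigma posterior concentrates near the mean time
    ee <- rexp(1500, 1 / 6)
    fe <- sample_weibull_posterior(ee, rep(1, 1500), chains = 2,
                                   warmup = 600, draws = 600, seed = 11)
    expect_equal(mean(fe$sigma), mean(ee), tolerance = 0.1)
    expect_equal(mean(fe$alpha), 1, tolerance = 0.08)
  })
})

test_that("the convergence gate raises a classed error with diagnostics", {
  withr::with_seed(12, {
    tt <- rweibull(80, 1.2, 5)
    err <- tryCatch(
      sample_weibull_posterior(tt, rep(1, 80), chains = 2, warmup = 300,
                               draws = 300, seed = 2, rhat_max = 0.5),
      error = function(e) e)
    expect_s3_class(err, "postDCA_nonconvergence")
    expect_true(is.list(err$diagnostics))
    expect_warning(
      sample_weibull_posterior(tt, rep(1, 80), chains = 2, warmup = 300,
                               draws = 300, seed = 2, rhat_max = 0.5,
                               on_nonconvergence = "warn"),
      "split-Rhat")
  })
})

test_that("positivity permutation leaves net benefit distribution intact", {
  withr::with_seed(13, {
    cw <- make_censored_weibull(400, 1.5, 10, 0.2)
    fit <- sample_weibull_posterior(cw$time, cw$event, chains = 2,
                                    warmup = 500, draws = 2000, seed = 3)
    s <- survival_at_horizon(fit$alpha, fit$sigma, tau = 12)
    p <- sample_positivity(120, 400, M = length(s), seed = 4)
    nb1 <- net_benefit_survival(s, p, 0.2)
    nb2 <- net_benefit_survival(s, sample(p), 0.2)
    expect_equal(mean(nb1), mean(nb2), tolerance = 0.01)
    expect_gt(suppressWarnings(ks.test(nb1, nb2))$p.value, 0.01)
  })
})

test_that("survival net benefit draws follow the formula and its bounds", {
  expect_equal(net_benefit_survival(0.9, 0.5, 0.5), -0.40)
  p <- c(0.3, 0.8)
  expect_equal(net_benefit_survival(c(0, 0), p, 0.3), p)
  expect_equal(net_benefit_survival(c(0.4, 0.9), c(0, 0), 0.3), c(0, 0))
  # S_cohort ~ 1 (huge scale) pins treat-all at -w_t
  expect_equal(net_benefit_treat_all_survival(1, 1e9, tau = 12, t = 0.5),
               -1, tolerance = 1e-6)
  # S_cohort = 0.5 at t = 0.5 -> exactly zero
  sigma_half <- 12 / log(2)  # exp(-(12/sigma)) = 0.5 with alpha = 1
  expect_equal(net_benefit_treat_all_survival(1, sigma_half, 12, 0.5), 0)
  expect_equal(net_benefit_treat_all_survival(1, sigma_half, 12, 0), 0.5)
  withr::with_seed(15, {
    s <- runif(1000); p <- runif(1000); t <- 0.35
    nb <- net_benefit_survival(s, p, t)
    expect_true(all(nb >= -t / (1 - t) - 1e-12 & nb <= 1))
  })
})

test_that("posterior survival among positives agrees with Kaplan-Meier", {
  skip_if_not_installed("survival")
  withr::with_seed(16, {
    cw <- make_censored_weibull(1500, 1.4, 18, 0.15)
    fit <- sample_weibull_posterior(cw$time, cw$event, chains = 2,
                                    warmup = 600, draws = 1000, seed = 5)
    s_post <- mean(survival_at_horizon(fit$alpha, fit$sigma, tau = 12))
    km <- survival::survfit(
      survival::Surv(cw$time, cw$event) ~ 1)
    s_km <- summary(km, times = 12)$surv
    expect_lt(abs(s_post - s_km), 0.02)
  })
})
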