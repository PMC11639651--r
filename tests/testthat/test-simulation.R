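test_that("canonical setting tables have the documented structure", {
  b <- binary_sim_settings()
  expect_equal(nrow(b), 6)
  expect_setequal(unique(b$prevalence), c(0.01, 0.05, 0.30))
  expect_setequal(unique(b$max_auc), c(0.65, 0.85))
  expect_equal(b$b1, -b$b2)          # sign-opposed coefficient pairs
  expect_equal(b$bh1, -b$bh2)
  s <- survival_sim_settings()
  expect_equal(nrow(s), 9)
  expect_setequal(unique(s$max_cstat), c(0.60, 0.90, 0.95))
  expect_setequal(unique(s$surv1yr), c(0.10, 0.20, 0.50))
  expect_true(all(s$censor_max == 24 & s$horizon == 12))
  expect_error(get_sim_setting("nope"), "available")
})

test_that("the shipped settings.yaml matches the in-code tables", {
  path <- system.file("extdata", "settings.yaml", package = "postDCA")
  expect_true(nzchar(path))
  y <- yaml::read_yaml(path)
  b <- binary_sim_settings()
  expect_equal(length(y$binary), nrow(b))
  for (i in seq_len(nrow(b))) {
    expect_equal(y$binary[[i]]$id, b$id[i])
    expect_equal(unlist(y$binary[[i]]$beta),
                 c(b$b0[i], b$b1[i], b$b2[i]), tolerance = 1e-12)
    expect_equal(unlist(y$binary[[i]]$beta_hat),
                 c(b$bh0[i], b$bh1[i], b$bh2[i]), tolerance = 1e-12)
  }
  s <- survival_sim_settings()
  expect_equal(length(y$survival), nrow(s))
  for (i in seq_len(nrow(s))) {
    expect_equal(y$survival[[i]]$gamma, s$gamma[i])
    expect_equal(y$survival[[i]]$lambda, s$lambda[i])
    expect_equal(unlist(y$survival[[i]]$beta), c(s$b1[i], s$b2[i]),
                 tolerance = 1e-12)
  }
})

test_that("binary populations hit the nominal prevalence and maximum AUC", {
  skip_if_not_installed("pROC")
  pop <- generate_binary_population("binary_auc085_prev30", 1e5, seed = 42)
  expect_equal(mean(pop$y), 0.30, tolerance = 0.01 / 0.30)
  auc <- as.numeric(pROC::auc(pROC::roc(pop$y, pop$p_true, quiet = TRUE)))
  expect_equal(auc, 0.85, tolerance = 0.01 / 0.85)
  # identical coefficients make the model predictions the true risks
  setting <- get_sim_setting("binary_auc085_prev30")
  setting[c("bh0", "bh1", "bh2")] <- setting[c("b0", "b1", "b2")]
  ident <- generate_binary_population(setting, 1000, seed = 1)
  expect_equal(ident$p_hat, ident$p_true)
})

test_that("survival times match an accept-reject sampler of the hazard", {
  withr::with_seed(47, {
    setting <- get_sim_setting("surv_c060_s10")
    # fix the covariates: compare conditional time distributions
    eta <- setting$b1 * 0.5 + setting$b2 * (-0.3)
    u <- runif(1e4)
    inv_cdf <- (-log(u) / (setting$lambda * exp(eta)))^(1 / setting$gamma)
    ar <- ar_weibull_ph(1e4, setting$gamma, setting$lambda, eta)
    expect_gt(suppressWarnings(ks.test(inv_cdf, ar))$p.value, 0.01)
  })
})

test_that("simulated binary tests realize their operating characteristics", {
  withr::with_seed(53, {
    y <- rbinom(1e5, 1, 0.3)
    expect_identical(simulate_binary_test(y, 1, 1), as.integer(y))
    expect_true(all(simulate_binary_test(y, 0, 1) == 0))
    z <- simulate_binary_test(y, 0.81, 0.88)
    expect_equal(mean(z[y == 1]), 0.81, tolerance = 0.01 / 0.81)
    expect_equal(1 - mean(z[y == 0]), 0.88, tolerance = 0.01 / 0.88)
  })
})

test_that("population net benefit equals the count-based definition", {
  withr::with_seed(59, {
    pop <- generate_binary_population("binary_auc065_prev30", 5000)
    # perfect test at t = 0 gives the prevalence; never-positive gives 0
    expect_equal(true_net_benefit_binary(pop, pop$y, 0), mean(pop$y))
    expect_equal(true_net_benefit_binary(pop, rep(0, 5000), 0.3), 0)
    for (t in c(0.1, 0.25, 0.4)) {
      expect_equal(true_net_benefit_binary(pop, "p_hat", t),
                   sample_nb_binary(pop$y, pop$p_hat, t))
    }
  })
})

test_that("survival oracle reduces to treat-all and integrates the model", {
  withr::with_seed(61, {
    pop <- generate_survival_population("surv_c060_s20", 5e4)
    setting <- attr(pop, "setting")
    # everyone positive: oracle equals the treat-all form with p = 1
    all_pos <- rep(1, nrow(pop))
    t <- 0.25
    s_all <- mean(pop$true_time > 12)
    expect_equal(true_net_benefit_survival(pop, t, predictions = all_pos),
                 (1 - s_all) - s_all * t / (1 - t))
    expect_equal(true_net_benefit_survival(
      pop, 0.2, predictions = rep(0, nrow(pop))), 0)
    # quadrature-style oracle: exact conditional survival given covariates
    pos <- pop$risk > t
    s_exact <- mean(exp(-setting$lambda * 12^setting$gamma *
                          exp(setting$b1 * pop$x1[pos] +
                                setting$b2 * pop$x2[pos])))
    p <- mean(pos)
    nb_exact <- (1 - s_exact) * p - s_exact * p * t / (1 - t)
    expect_equal(true_net_benefit_survival(pop, t), nb_exact,
                 tolerance = 0.01, ignore_attr = TRUE)
  })
})

test_that("validation sample sizes follow the expected-events rule", {
  pop30 <- generate_binary_population("binary_auc065_prev30", 2e4, seed = 2)
  v30 <- sample_validation_set(pop30, 100, seed = 3)
  expect_equal(v30$n, 333)
  pop05 <- generate_binary_population("binary_auc065_prev05", 2e4, seed = 2)
  expect_equal(sample_validation_set(pop05, 100, seed = 3)$n, 2000)
  pop01 <- generate_binary_population("binary_auc065_prev01", 2e4, seed = 2)
  expect_equal(sample_validation_set(pop01, 100, seed = 3)$n, 10000)
  expect_error(sample_validation_set(pop01, 10000, seed = 1), "exceeds")
  rows <- attr(v30, "rows")
  expect_equal(length(unique(rows)), 333)   # no duplicates
  expect_equal(v30$outcome, pop30$y[rows])
})

test_that("the simulation harness is deterministic and rep-accounted", {
  r1 <- run_simulation_study("binary_auc085_prev30", n_reps = 5,
                             population_size = 2e4, M = 500, seed = 4)
  expect_equal(attr(r1, "n_reps"), 5)
  expect_equal(unique(r1$n_ok), 5)
  expect_equal(nrow(r1), 9)
  r2 <- run_simulation_study("binary_auc085_prev30", n_reps = 5,
                             population_size = 2e4, M = 500, seed = 4)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  one <- run_simulation_study("binary_auc085_prev30", n_reps = 1,
                              population_size = 2e4, M = 500, seed = 9)
  expect_true(all(one$coverage %in% c(0, 1)))
})

test_that("coverage is insensitive to doubling the posterior draw count", {
  rA <- run_simulation_study("binary_auc085_prev30", n_reps = 60,
                             population_size = 5e4, M = 2000, seed = 14)
  rB <- run_simulation_study("binary_auc085_prev30", n_reps = 60,
                             population_size = 5e4, M = 4000, seed = 14)
  expect_lt(abs(mean(rA$coverage) - mean(rB$coverage)), 0.05)
})
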