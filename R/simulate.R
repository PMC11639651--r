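#' Canonical binary-outcome simulation settings
#'
#' Six logistic-regression data-generating processes crossing maximum
#' achievable AUC (0.65, 0.85: low and high signal-to-noise) with outcome
#' prevalence (1\%, 5\%, 30\%). Covariates are iid Exp(1); the true
#' linear predictor is `b0 + b1 x1 + b2 x2` with sign-opposed
#' coefficients. The companion model under validation (`bh*`) inflates
#' the covariate coefficients (calibration slope < 1 on the logit scale,
#' i.e. overly extreme predictions, the signature of overfitting) with an
#' intercept adjusted to keep the predicted prevalence near the truth.
#'
#' @return Data frame with columns `id`, `max_auc`, `prevalence`,
#'   `b0`, `b1`, `b2`, `bh0`, `bh1`, `bh2`.
#' @export
binary_sim_settings <- function() {
  s <- function(id, auc, prev, b0, or, bh0, mult) {
    data.frame(id = id, max_auc = auc, prevalence = prev,
               b0 = b0, b1 = -log(or), b2 = log(or),
               bh0 = bh0, bh1 = -log(or) * mult, bh2 = log(or) * mult)
  }
  rbind(
    s("binary_auc065_prev01", 0.65, 0.01, -4.750, 1.50, -5.000, 1.25),
    s("binary_auc065_prev05", 0.65, 0.05, -3.100, 1.50, -3.900, 3.00),
    s("binary_auc065_prev30", 0.65, 0.30, -0.900, 1.55, -1.200, 3.00),
    s("binary_auc085_prev01", 0.85, 0.01, -5.600, 2.57, -6.900, 1.50),
    s("binary_auc085_prev05", 0.85, 0.05, -3.755, 2.95, -7.300, 3.00),
    s("binary_auc085_prev30", 0.85, 0.30, -1.300, 4.50, -2.250, 3.00))
}

#' Canonical survival-outcome simulation settings
#'
#' Nine Weibull proportional-hazards data-generating processes crossing
#' the maximum achievable C-statistic (0.60, 0.90, 0.95) with 1-year
#' survival (10\%, 20\%, 50\%). The baseline hazard is
#' \eqn{h_0(t) = \gamma \lambda t^{\gamma - 1}} (so the baseline scale in
#' shape-scale form is \eqn{\sigma = \lambda^{-1/\gamma}}), covariates are
#' standard normal with proportional-hazards coefficients `b1`, `b2`, and
#' the model under validation exaggerates them (`bh*`). Censoring is
#' Uniform(0, 24) months (two-year maximum follow-up); the prediction
#' horizon is 12 months.
#'
#' @return Data frame with columns `id`, `max_cstat`, `surv1yr`, `gamma`,
#'   `lambda`, `b1`, `b2`, `bh1`, `bh2`, `censor_max`, `horizon`.
#' @export
survival_sim_settings <- function() {
  s <- function(id, cstat, s1, gamma, lambda, hr1, hr2, mult) {
    data.frame(id = id, max_cstat = cstat, surv1yr = s1,
               gamma = gamma, lambda = lambda,
               b1 = log(hr1), b2 = log(hr2),
               bh1 = log(hr1) * mult, bh2 = log(hr2) * mult,
               censor_max = 24, horizon = 12)
  }
  rbind(
    s("surv_c060_s10", 0.60, 0.10, 1.22, 0.12,   1.30, 0.70,  1.01),
    s("surv_c060_s20", 0.60, 0.20, 1.07, 0.12,   1.30, 0.70,  1.01),
    s("surv_c060_s50", 0.60, 0.50, 0.70, 0.12,   1.30, 0.70,  1.01),
    s("surv_c090_s10", 0.90, 0.10, 4.60, 0.0004, 1.95, 0.05,  1.25),
    s("surv_c090_s20", 0.90, 0.20, 4.00, 0.0004, 1.95, 0.05,  1.25),
    s("surv_c090_s50", 0.90, 0.50, 2.90, 0.0004, 1.95, 0.05,  1.25),
    s("surv_c095_s10", 0.95, 0.10, 6.50, 0.0004, 1.95, 0.001, 1.25),
    s("surv_c095_s20", 0.95, 0.20, 5.40, 0.0004, 1.95, 0.001, 1.25),
    s("surv_c095_s50", 0.95, 0.50, 3.10, 0.0004, 1.95, 0.001, 1.25))
}

#' Look up a canonical simulation setting by id
#'
#' @param id A setting id from [binary_sim_settings()] or
#'   [survival_sim_settings()], or a one-row data frame in the same
#'   layout (passed through).
#' @return One-row data frame of setting parameters.
#' @export
get_sim_setting <- function(id) {
  if (is.data.frame(id)) {
    stopifnot(nrow(id) == 1)
    return(id)
  }
  all <- list(binary = binary_sim_settings(),
              survival = survival_sim_settings())
  for (tab in all) {
    hit <- tab[tab$id == id, , drop = FALSE]
    if (nrow(hit) == 1) return(hit)
  }
  stop("unknown setting id '", id, "'; available: ",
       paste(c(all$binary$id, all$survival$id), collapse = ", "),
       call. = FALSE)
}

setting_type <- function(setting) {
  if ("prevalence" %in% names(setting)) "binary" else "survival"
}

#' Generate a binary-outcome population
#'
#' Draws `n` patients from a logistic data-generating process:
#' `x1, x2 ~ iid Exp(1)`, true risk `p = plogis(b0 + b1 x1 + b2 x2)`,
#' outcome `y ~ Bernoulli(p)`, and the miscalibrated model prediction
#' `p_hat` computed from the `bh*` coefficients.
#'
#' @param setting Setting id or one-row data frame
#'   (see [binary_sim_settings()]).
#' @param n Population size. The full-replication scale is 2e6; 1e5 is a
#'   desk-scale preset adequate for population summaries.
#' @param seed Optional seed.
#' @return Data frame with columns `x1`, `x2`, `p_true`, `p_hat`, `y`;
#'   attributes `setting` (the parameter row) and `type = "binary"`.
#' @export
generate_binary_population <- function(setting, n = 1e5, seed = NULL) {
  setting <- get_sim_setting(setting)
  stopifnot(setting_type(setting) == "binary", n >= 1)
  maybe_with_seed(seed, {
    x1 <- rexp(n)
    x2 <- rexp(n)
    p_true <- plogis(setting$b0 + setting$b1 * x1 + setting$b2 * x2)
    p_hat <- plogis(setting$bh0 + setting$bh1 * x1 + setting$bh2 * x2)
    out <- data.frame(x1 = x1, x2 = x2, p_true = p_true, p_hat = p_hat,
                      y = rbinom(n, 1, p_true))
    attr(out, "setting") <- setting
    attr(out, "type") <- "binary"
    out
  })
}

#' Generate a survival-outcome population
#'
#' Event times follow the Weibull proportional-hazards model with hazard
#' \eqn{h(t \mid x) = \gamma \lambda t^{\gamma-1} e^{x^\top \beta}},
#' sampled by inversion:
#' \eqn{T = \{-\log U / (\lambda e^{x^\top\beta})\}^{1/\gamma}}. Censoring
#' times are Uniform(0, `censor_max`); the observed time is the minimum
#' and `event = 1` when the true time comes first. The model prediction
#' is the event risk at the horizon under the exaggerated coefficients,
#' \eqn{\hat r_\tau = 1 - \exp(-\lambda \tau^\gamma e^{x^\top\hat\beta})}
#' (true baseline, miscalibration purely through the coefficients).
#'
#' @inheritParams generate_binary_population
#' @return Data frame with columns `x1`, `x2`, `true_time`,
#'   `censor_time`, `obs_time`, `event`, `risk`; attributes `setting` and
#'   `type = "survival"`.
#' @export
generate_survival_population <- function(setting, n = 1e5, seed = NULL) {
  setting <- get_sim_setting(setting)
  stopifnot(setting_type(setting) == "survival", n >= 1)
  maybe_with_seed(seed, {
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    lp <- setting$b1 * x1 + setting$b2 * x2
    lp_hat <- setting$bh1 * x1 + setting$bh2 * x2
    u <- runif(n)
    true_time <- (-log(u) / (setting$lambda * exp(lp)))^(1 / setting$gamma)
    censor_time <- runif(n, 0, setting$censor_max)
    out <- data.frame(
      x1 = x1, x2 = x2, true_time = true_time,
      censor_time = censor_time,
      obs_time = pmin(true_time, censor_time),
      event = as.integer(true_time <= censor_time),
      risk = 1 - exp(-setting$lambda * setting$horizon^setting$gamma *
                       exp(lp_hat)))
    attr(out, "setting") <- setting
    attr(out, "type") <- "survival"
    out
  })
}

#' Simulate a binary diagnostic test with fixed operating characteristics
#'
#' Each diseased patient tests positive with probability `se`, each
#' non-diseased one with probability `1 - sp`, independently.
#'
#' @param outcomes 0/1 outcome vector.
#' @param se,sp Sensitivity and specificity in `[0, 1]`.
#' @param seed Optional seed.
#' @return Integer 0/1 vector of test results.
#' @export
simulate_binary_test <- function(outcomes, se, sp, seed = NULL) {
  stopifnot(all(outcomes %in% c(0, 1)))
  stopifnot_prob(se, "se"); stopifnot_prob(sp, "sp")
  maybe_with_seed(seed, {
    n <- length(outcomes)
    rbinom(n, 1, ifelse(outcomes == 1, se, 1 - sp))
  })
}

#' Population (oracle) net benefit for a binary strategy
#'
#' Plugs the population sensitivity, specificity and prevalence of the
#' strategy into the prevalence form of net benefit. Deterministic given
#' the population; this is the truth against which the simulation
#' harness measures coverage and error.
#'
#' @param population A [generate_binary_population()] result.
#' @param predictions Prediction vector, or the name of a population
#'   column (default `"p_hat"`, the model under validation).
#' @param t Decision threshold in `[0, 1)`.
#' @return The population net benefit (scalar).
#' @export
true_net_benefit_binary <- function(population, predictions = "p_hat", t) {
  if (is.character(predictions)) predictions <- population[[predictions]]
  stopifnot(length(predictions) == nrow(population), t >= 0, t < 1)
  y <- population$y == 1
  z <- predictions > t
  se <- sum(z & y) / sum(y)
  sp <- sum(!z & !y) / sum(!y)
  prev <- mean(y)
  nb_binary(se, sp, prev, t)
}

#' Population (oracle) net benefit for a survival strategy
#'
#' Evaluates the survival net benefit at horizon `tau` using the true
#' (uncensored) event times: the positivity probability is the population
#' fraction of predictions above `t`, and the conditional survival is the
#' fraction of positive-prediction patients whose true event time exceeds
#' the horizon.
#'
#' @param population A [generate_survival_population()] result.
#' @param t Decision threshold in `[0, 1)`.
#' @param tau Prediction horizon (defaults to the setting's horizon).
#' @param predictions Prediction vector or column name (default
#'   `"risk"`).
#' @return The population net benefit (scalar); 0 when no prediction
#'   exceeds the threshold.
#' @export
true_net_benefit_survival <- function(population, t,
                                      tau = attr(population,
                                                 "setting")$horizon,
                                      predictions = "risk") {
  if (is.character(predictions)) predictions <- population[[predictions]]
  stopifnot(length(predictions) == nrow(population), t >= 0, t < 1,
            tau > 0)
  pos <- predictions > t
  p <- mean(pos)
  if (p == 0) return(0)
  s <- mean(population$true_time[pos] > tau)
  (1 - s) * p - s * p * threshold_weight(t)
}

#' Draw a validation set with a fixed expected number of events
#'
#' Validation-study sample sizes are set so that the expected event count
#' is fixed (default 100): `n = round(expected_events / event_rate)`,
#' drawn uniformly without replacement from the population. For binary
#' populations the event rate is the setting's true prevalence (giving
#' n of 333, 2000 and 10000 at prevalences 30\%, 5\% and 1\%); for
#' survival populations it is the population fraction of observed
#' (non-censored) events within follow-up.
#'
#' @param population A generated population.
#' @param expected_events Target expected number of events (default 100).
#' @param seed Optional seed.
#' @param event_rate Override for the event rate used in the sample-size
#'   computation.
#' @return A [binary_validation_data()] or [survival_validation_data()]
#'   object with a single strategy named `"model"`; the drawn row indices
#'   are attached as attribute `rows`.
#' @export
sample_validation_set <- function(population, expected_events = 100,
                                  seed = NULL, event_rate = NULL) {
  stopifnot(expected_events >= 1)
  type <- attr(population, "type")
  setting <- attr(population, "setting")
  if (is.null(event_rate)) {
    event_rate <- if (identical(type, "binary")) {
      setting$prevalence
    } else {
      mean(population$event)
    }
  }
  stopifnot(event_rate > 0)
  n <- round(expected_events / event_rate)
  if (n > nrow(population)) {
    stop("requested sample size ", n, " exceeds the population (",
         nrow(population), " rows)", call. = FALSE)
  }
  maybe_with_seed(seed, {
    idx <- sample.int(nrow(population), n, replace = FALSE)
    rows <- population[idx, , drop = FALSE]
    out <- if (identical(type, "binary")) {
      binary_validation_data(rows$y, list(model = rows$p_hat))
    } else {
      survival_validation_data(rows$obs_time, rows$event,
                               list(model = rows$risk),
                               horizon = setting$horizon)
    }
    attr(out, "rows") <- idx
    out
  })
}

#' Coverage and error study of the Bayesian decision curve estimator
#'
#' Repeatedly draws validation sets from a simulated population, runs the
#' full Bayesian DCA on each, and scores the model strategy's posterior
#' mean and 95\% credible interval against the population-oracle true net
#' benefit at every threshold. Per-replicate seeds are derived
#' deterministically from the master seed, so individual replicates can
#' be re-run in isolation and the whole study is reproducible
#' bit-for-bit. Replicate failures are recorded, not fatal.
#'
#' @param setting Setting id or one-row parameter data frame.
#' @param n_reps Number of simulation replicates.
#' @param grid A [threshold_grid()] (default 0.05 to 0.45 by 0.05).
#' @param M Posterior draws per replicate (default 4000).
#' @param expected_events Expected events per validation set (default
#'   100).
#' @param population_size Population size (default 1e5).
#' @param seed Master seed.
#' @param priors,mcmc Passed to [dca_binary()] / [dca_survival()].
#' @param level Credible level scored for coverage (default 0.95).
#' @return A `simulation_report`: data frame with per-threshold
#'   `coverage`, `mape`, `bias` and `n_ok`, with the per-replicate
#'   estimates, the oracle truth, the setting and seeds as attributes.
#' @export
run_simulation_study <- function(setting, n_reps = 500,
                                 grid = threshold_grid(min = 0.05,
                                                       max = 0.45,
                                                       step = 0.05),
                                 M = 4000, expected_events = 100,
                                 population_size = 1e5, seed = 1,
                                 priors = NULL, mcmc = list(),
                                 level = 0.95) {
  setting <- get_sim_setting(setting)
  type <- setting_type(setting)
  stopifnot(n_reps >= 1)
  pop <- if (type == "binary") {
    generate_binary_population(setting, population_size,
                               seed = derive_seed(seed, 0))
  } else {
    generate_survival_population(setting, population_size,
                                 seed = derive_seed(seed, 0))
  }
  truth <- vapply(grid$threshold, function(t_k) {
    if (type == "binary") true_net_benefit_binary(pop, "p_hat", t_k)
    else true_net_benefit_survival(pop, t_k)
  }, numeric(1))

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  nt <- nrow(grid)
  est <- lo <- hi <- matrix(NA_real_, n_reps, nt)
  failed <- integer(0)
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      val <- sample_validation_set(pop, expected_events,
                                   seed = derive_seed(seed, 2 * r))
      fit <- if (type == "binary") {
        dca_binary(val, grid, priors = priors, M = M,
                   seed = derive_seed(seed, 2 * r + 1))
      } else {
        suppressWarnings(
          dca_survival(val, grid, priors = priors, mcmc = mcmc,
                       seed = derive_seed(seed, 2 * r + 1),
                       on_nonconvergence = "warn"))
      }
      draws <- fit$nb["model", , , drop = TRUE]
      if (nt == 1) draws <- matrix(draws, nrow = 1)
      list(est = rowMeans(draws),
           q = apply(draws, 1, quantile, probs = probs, names = FALSE))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, r)
    } else {
      est[r, ] <- res$est
      lo[r, ] <- res$q[1, ]
      hi[r, ] <- res$q[2, ]
    }
  }

  ok <- !is.na(est[, 1])
  per_threshold <- do.call(rbind, lapply(seq_len(nt), function(k) {
    covered <- lo[ok, k] <= truth[k] & truth[k] <= hi[ok, k]
    err <- est[ok, k] - truth[k]
    ape <- if (truth[k] == 0) NA_real_ else mean(abs(err) / abs(truth[k]))
    data.frame(threshold = grid$threshold[k],
               coverage = mean(covered), mape = ape, bias = mean(err),
               n_ok = sum(ok))
  }))
  structure(per_threshold,
            class = c("simulation_report", "data.frame"),
            setting = setting, seed = seed, n_reps = n_reps,
            failed = failed, truth = truth,
            estimates = list(est = est, lo = lo, hi = hi),
            level = level)
}

#' @export
print.simulation_report <- function(x, ...) {
  s <- attr(x, "setting")
  cat(sprintf(
    "<simulation_report> setting %s; %d replicates (%d failed); seed %s\n",
    s$id, attr(x, "n_reps"), length(attr(x, "failed")),
    format(attr(x, "seed"))))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
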