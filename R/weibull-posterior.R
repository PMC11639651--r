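#' Log-likelihood of right-censored Weibull data
#'
#' Events contribute the log density and censored records the log survival
#' of a Weibull distribution with shape `alpha` and scale `sigma`:
#' \eqn{f(t) = (\alpha/\sigma)(t/\sigma)^{\alpha-1} e^{-(t/\sigma)^\alpha}},
#' \eqn{S(t) = e^{-(t/\sigma)^\alpha}}.
#'
#' @param alpha,sigma Positive Weibull shape and scale.
#' @param times Positive observed times.
#' @param events 0/1 vector, 1 = event observed, 0 = censored.
#' @return The log-likelihood (scalar).
#' @examples
#' weibull_censored_loglik(1, 2, times = 2, events = 1)  # log(1/2) - 1
#' @export
weibull_censored_loglik <- function(alpha, sigma, times, events) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0 || !is.numeric(sigma) || length(sigma) != 1 ||
      !is.finite(sigma) || sigma <= 0) {
    stop("alpha and sigma must be single positive numbers", call. = FALSE)
  }
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  ev <- events == 1
  sum(dweibull(times[ev], shape = alpha, scale = sigma, log = TRUE)) +
    sum(pweibull(times[!ev], shape = alpha, scale = sigma,
                 lower.tail = FALSE, log.p = TRUE))
}

# Draws from a half-Student-t(df, 0, scale) distribution.
rhalf_t <- function(n, df, scale) abs(rt(n, df = df)) * scale

# Prior-only draws of (alpha, sigma), used when a threshold has no
# positive predictions.
sample_weibull_prior <- function(prior, M) {
  if (prior$family == "half_t") {
    list(alpha = rhalf_t(M, prior$shape[1], prior$shape[3]),
         sigma = rhalf_t(M, prior$scale[1], prior$scale[3]))
  } else {
    list(alpha = rgamma(M, prior$shape[1], rate = prior$shape[2]),
         sigma = rgamma(M, prior$scale[1], rate = prior$scale[2]))
  }
}

# JAGS uses dweib(shape, lambda) with lambda = sigma^-shape; censoring is
# encoded with dinterval and a latent time for censored records.
jags_weibull_model <- function(family) {
  prior_block <- if (family == "half_t") {
    "  alpha ~ dt(0, prec_shape, df_shape) T(0,)
  sigma ~ dt(0, prec_scale, df_scale) T(0,)"
  } else {
    "  alpha ~ dgamma(g_shape1, g_shape2)
  sigma ~ dgamma(g_scale1, g_scale2)"
  }
  paste0("model {
  for (i in 1:N) {
    cens[i] ~ dinterval(t[i], lim[i])
    t[i] ~ dweib(alpha, lambda)
  }
", prior_block, "
  lambda <- pow(sigma, -alpha)
}")
}

# Split-Rhat of Gelman et al.: each chain is halved before computing the
# usual potential scale reduction factor.
split_rhat <- function(draws_by_chain) {
  halves <- do.call(cbind, lapply(seq_len(ncol(draws_by_chain)), function(j) {
    x <- draws_by_chain[, j]
    n2 <- floor(length(x) / 2)
    cbind(x[seq_len(n2)], x[seq_len(n2) + n2])
  }))
  n <- nrow(halves)
  m <- ncol(halves)
  chain_means <- colMeans(halves)
  b <- n * var(chain_means)
  w <- mean(apply(halves, 2, var))
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Sample the posterior of the censored Weibull parameters by MCMC
#'
#' Targets the product of the [weibull_prior()] and the right-censored
#' Weibull likelihood over the supplied records (typically the
#' positive-prediction subset at one threshold). Sampling uses JAGS;
#' convergence is assessed via split-\eqn{\hat R} and effective sample
#' size. Divergent-transition counts are a Hamiltonian Monte Carlo
#' diagnostic and do not apply to this sampler; the field is reported as
#' `NA`.
#'
#' With zero records the prior is returned (as direct draws, with a
#' prominent warning): no data means the posterior *is* the prior.
#'
#' @inheritParams weibull_censored_loglik
#' @param prior A [weibull_prior()].
#' @param chains,warmup,draws MCMC configuration; the retained draw count
#'   is `chains * draws` (default 4 x 1000 = 4000).
#' @param seed Optional seed; chain RNGs are derived deterministically.
#' @param rhat_max Convergence threshold on split-\eqn{\hat R}
#'   (default 1.01).
#' @param on_nonconvergence `"error"` (default) raises an error carrying
#'   the diagnostics; `"warn"` downgrades to a warning.
#' @return A `weibull_posterior_draws` object: vectors `alpha`, `sigma`
#'   (length `chains * draws`), a `diagnostics` list (`rhat`, `ess`,
#'   `divergences`), and a `prior_only` flag.
#' @export
sample_weibull_posterior <- function(times, events,
                                     prior = weibull_prior(),
                                     chains = 4, warmup = 1000,
                                     draws = 1000, seed = NULL,
                                     rhat_max = 1.01,
                                     on_nonconvergence = c("error", "warn")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(inherits(prior, "weibull_prior"), chains >= 1, warmup >= 2,
            draws >= 2, length(times) == length(events))
  M <- chains * draws

  if (length(times) == 0) {
    warning("no records supplied: returning draws from the prior",
            call. = FALSE)
    pd <- maybe_with_seed(seed, sample_weibull_prior(prior, M))
    return(structure(list(alpha = pd$alpha, sigma = pd$sigma,
                          diagnostics = list(rhat = c(alpha = NA_real_,
                                                      sigma = NA_real_),
                                             ess = c(alpha = M, sigma = M),
                                             divergences = NA_integer_),
                          prior_only = TRUE, chains = chains,
                          warmup = warmup, draws = draws),
                     class = "weibull_posterior_draws"))
  }
  stopifnot(all(times > 0), all(events %in% c(0, 1)))

  dat <- list(N = length(times), cens = 1L - as.integer(events),
              lim = as.numeric(times),
              t = ifelse(events == 1, as.numeric(times), NA_real_))
  if (prior$family == "half_t") {
    dat$df_shape <- prior$shape[1]
    dat$prec_shape <- 1 / prior$shape[3]^2
    dat$df_scale <- prior$scale[1]
    dat$prec_scale <- 1 / prior$scale[3]^2
  } else {
    dat$g_shape1 <- prior$shape[1]; dat$g_shape2 <- prior$shape[2]
    dat$g_scale1 <- prior$scale[1]; dat$g_scale2 <- prior$scale[2]
  }

  base_seed <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, 1)
  } else {
    as.integer(seed)
  }
  t_init <- ifelse(events == 1, NA_real_, times * 1.5 + 1e-3)
  spread <- c(0.6, 1, 1.6, 2.4)
  inits <- lapply(seq_len(chains), function(k) {
    list(alpha = spread[(k - 1) %% 4 + 1],
         sigma = max(mean(times), 1e-3) * spread[(k - 1) %% 4 + 1],
         t = t_init,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(base_seed, k))
  })

  adapt <- ceiling(warmup / 2)
  jm <- rjags::jags.model(textConnection(jags_weibull_model(prior$family)),
                          data = dat, inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = TRUE)
  if (warmup - adapt > 0) update(jm, warmup - adapt, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("alpha", "sigma"), n.iter = draws,
                              progress.bar = "none")

  alpha_mat <- sapply(samp, function(ch) as.numeric(ch[, "alpha"]))
  sigma_mat <- sapply(samp, function(ch) as.numeric(ch[, "sigma"]))
  alpha_mat <- matrix(alpha_mat, nrow = draws)
  sigma_mat <- matrix(sigma_mat, nrow = draws)

  diag <- list(
    rhat = c(alpha = if (chains > 1 || draws >= 4) split_rhat(alpha_mat)
                     else NA_real_,
             sigma = if (chains > 1 || draws >= 4) split_rhat(sigma_mat)
                     else NA_real_),
    ess = c(alpha = unname(coda::effectiveSize(samp[, "alpha"])),
            sigma = unname(coda::effectiveSize(samp[, "sigma"]))),
    divergences = NA_integer_)

  bad <- !is.na(diag$rhat) & diag$rhat > rhat_max
  if (any(bad)) {
    msg <- sprintf(
      "MCMC did not converge: split-Rhat %s (threshold %g)",
      paste(sprintf("%s = %.4f", names(diag$rhat)[bad], diag$rhat[bad]),
            collapse = ", "), rhat_max)
    if (on_nonconvergence == "error") {
      stop(errorCondition(msg, diagnostics = diag,
                          class = c("postDCA_nonconvergence", "error",
                                    "condition")))
    }
    warning(msg, call. = FALSE)
  }

  structure(list(alpha = as.numeric(alpha_mat),
                 sigma = as.numeric(sigma_mat),
                 diagnostics = diag, prior_only = FALSE,
                 chains = chains, warmup = warmup, draws = draws),
            class = "weibull_posterior_draws")
}

#' @export
print.weibull_posterior_draws <- function(x, ...) {
  cat(sprintf(
    "<weibull_posterior_draws> %d draws%s; mean alpha %.3f, mean sigma %.3f\n",
    length(x$alpha), if (x$prior_only) " (prior only)" else "",
    mean(x$alpha), mean(x$sigma)))
  if (!x$prior_only) {
    cat(sprintf("  split-Rhat: alpha %.4f, sigma %.4f; ESS: %.0f / %.0f\n",
                x$diagnostics$rhat["alpha"], x$diagnostics$rhat["sigma"],
                x$diagnostics$ess["alpha"], x$diagnostics$ess["sigma"]))
  }
  invisible(x)
}

#' Posterior of the positivity probability
#'
#' The indicator of a positive prediction is Bernoulli with probability
#' `p`; under a conjugate Beta(a, b) prior the posterior is
#' `Beta(n_pos + a, n - n_pos + b)` in closed form, independent of the
#' Weibull component.
#'
#' @param n_pos Number of positive predictions, `0 <= n_pos <= n`.
#' @param n Cohort size.
#' @param prior A [beta_prior()] (default uniform).
#' @param M Number of draws.
#' @param seed Optional seed.
#' @return Numeric vector of `M` draws of the positivity probability.
#' @export
sample_positivity <- function(n_pos, n, prior = beta_prior(), M = 4000,
                              seed = NULL) {
  stopifnot(n_pos >= 0, n >= n_pos, inherits(prior, "beta_prior"), M >= 1)
  maybe_with_seed(seed,
    rbeta(M, n_pos + prior$shape1, n - n_pos + prior$shape2))
}

#' Weibull survival probability at the prediction horizon
#'
#' \eqn{S(\tau) = \exp\{-(\tau/\sigma)^{\alpha}\}}, evaluated per draw.
#'
#' @param alpha,sigma Numeric vectors of Weibull shape/scale draws.
#' @param tau Positive prediction horizon.
#' @return Numeric vector of survival probabilities in (0, 1).
#' @export
survival_at_horizon <- function(alpha, sigma, tau) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0,
            all(alpha > 0), all(sigma > 0))
  exp(-(tau / sigma)^alpha)
}

#' Posterior net benefit draws for a survival-outcome strategy
#'
#' \eqn{NB = (1 - S)\,p - S\,p\,w_t} per paired draw, where `S` is the
#' survival probability at the horizon among positive predictions and `p`
#' the positivity probability. A true positive is a treated patient who
#' experiences the event by the horizon; a treated survivor is a false
#' positive.
#'
#' @param s_draws,p_draws Equal-length draw vectors of `S` and `p`.
#' @param t Decision threshold in `[0, 1)`.
#' @return Numeric vector of net benefit draws.
#' @export
net_benefit_survival <- function(s_draws, p_draws, t) {
  stopifnot(length(s_draws) == length(p_draws), t >= 0, t < 1)
  (1 - s_draws) * p_draws - s_draws * p_draws * threshold_weight(t)
}

#' Treat-all net benefit draws for survival outcomes
#'
#' Treating everyone fixes the positivity probability at 1 and replaces
#' the conditional survival with the cohort-wide survival at the horizon,
#' estimated from a Weibull fit to all patients:
#' \eqn{NB_{all} = (1 - S) - S\,w_t}.
#'
#' @param alpha,sigma Cohort-level Weibull posterior draws.
#' @param tau Prediction horizon.
#' @param t Decision threshold in `[0, 1)`.
#' @return Numeric vector of net benefit draws.
#' @export
net_benefit_treat_all_survival <- function(alpha, sigma, tau, t) {
  s <- survival_at_horizon(alpha, sigma, tau)
  (1 - s) - s * threshold_weight(t)
}
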