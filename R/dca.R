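#' Assemble a set of posterior decision curves
#'
#' Low-level constructor bundling per-strategy net benefit draw matrices
#' into the container all interrogation statistics operate on. The
#' Treat-none strategy (net benefit identically zero) is appended
#' automatically; a `treat_all` entry must be supplied. Draw matrices must
#' be index-aligned: draw `m` at every strategy and threshold comes from
#' the same joint posterior draw, which preserves the correlation
#' structure (e.g. the shared prevalence parameter) that the comparison
#' statistics rely on.
#'
#' @param nb_draws Named list of numeric matrices, one per strategy, each
#'   of dimension `n_thresholds x M`. Must include `treat_all`.
#' @param grid A [threshold_grid()] whose length matches the matrix rows.
#' @param outcome_type `"binary"` or `"survival"`.
#' @param p_draws Optional shared prevalence draw vector (binary case).
#' @param flags Optional logical matrix (strategy x threshold) marking
#'   cells with no positive predictions.
#' @param meta Optional list of run metadata.
#' @return A `dca_set` object.
#' @export
decision_curve_set <- function(nb_draws, grid,
                               outcome_type = c("binary", "survival"),
                               p_draws = NULL, flags = NULL, meta = list()) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(inherits(grid, "threshold_grid"), is.list(nb_draws))
  if (!"treat_all" %in% names(nb_draws)) {
    stop("nb_draws must include a 'treat_all' entry", call. = FALSE)
  }
  nt <- nrow(grid)
  dims <- unique(lapply(nb_draws, dim))
  if (length(dims) != 1 || dims[[1]][1] != nt) {
    stop("all draw matrices must be n_thresholds x M with matching dims",
         call. = FALSE)
  }
  M <- dims[[1]][2]
  if (M < 1) stop("need at least one draw", call. = FALSE)
  if (!"treat_none" %in% names(nb_draws)) {
    nb_draws$treat_none <- matrix(0, nrow = nt, ncol = M)
  }
  models <- setdiff(names(nb_draws), c("treat_all", "treat_none"))
  strategies <- c(models, "treat_all", "treat_none")
  nb <- array(NA_real_, dim = c(length(strategies), nt, M),
              dimnames = list(strategy = strategies,
                              threshold = format(grid$threshold),
                              draw = NULL))
  for (s in strategies) nb[s, , ] <- nb_draws[[s]]
  if (is.null(flags)) {
    flags <- matrix(FALSE, length(strategies), nt,
                    dimnames = list(strategies, NULL))
  }
  structure(list(strategies = strategies, models = models, grid = grid,
                 M = M, nb = nb, outcome_type = outcome_type,
                 p_draws = p_draws, flags = flags, meta = meta),
            class = "dca_set")
}

#' @export
print.dca_set <- function(x, ...) {
  cat(sprintf(
    "<dca_set> %s outcomes; %d strategies (%s); %d thresholds in [%g, %g]; M = %d\n",
    x$outcome_type, length(x$strategies),
    paste(x$strategies, collapse = ", "),
    nrow(x$grid), min(x$grid$threshold), max(x$grid$threshold), x$M))
  if (any(x$flags)) {
    cat("  note: some (strategy, threshold) cells had no positive",
        "predictions\n")
  }
  invisible(x)
}

#' Extract net benefit draws for one strategy and threshold
#'
#' @param set A `dca_set`.
#' @param strategy Strategy name (including `treat_all`/`treat_none`).
#' @param t Threshold value present in the grid.
#' @return Numeric vector of `M` draws.
#' @export
nb_draws <- function(set, strategy, t) {
  stopifnot(inherits(set, "dca_set"))
  if (!strategy %in% set$strategies) {
    stop("unknown strategy: '", strategy, "'", call. = FALSE)
  }
  set$nb[strategy, match_threshold(set$grid, t), ]
}

#' Bayesian decision curve analysis for binary outcomes
#'
#' Runs the conjugate Beta-Bernoulli model at every threshold of the grid
#' for every strategy in the data, plus the Treat-all and Treat-none
#' defaults. A single prevalence draw vector is shared by all strategies
#' and thresholds (prevalence is a common parameter of the joint model),
#' which induces the strong cross-curve posterior correlation that makes
#' comparisons between curves far more precise than their marginal
#' intervals suggest.
#'
#' @param data A [binary_validation_data()] object.
#' @param thresholds A [threshold_grid()]; default 0 to 0.5 by 0.01.
#' @param priors Optional list with entries `p`, `se`, `sp`. `p` must be a
#'   single [beta_prior()]; `se`/`sp` may additionally be a per-threshold
#'   prior table (data frame with columns `threshold`, `shape1`,
#'   `shape2`) or a per-strategy named list of either form — the hook for
#'   threshold-dependent informative priors.
#' @param M Number of posterior draws per cell (default 4000).
#' @param seed Optional seed making the whole analysis reproducible.
#' @param external_prevalence Optional `c(cases, noncases)` from an
#'   external source; replaces the study-sample prevalence posterior
#'   (case-control adjustment).
#' @return A `dca_set` object.
#' @examples
#' set.seed(7)
#' y <- rbinom(200, 1, 0.3)
#' dat <- binary_validation_data(y, list(model = plogis(qlogis(0.3) +
#'   y * 0.9 + rnorm(200, 0, 0.8))))
#' fit <- dca_binary(dat, threshold_grid(max = 0.3, step = 0.1), seed = 1)
#' fit
#' @export
dca_binary <- function(data, thresholds = threshold_grid(), priors = NULL,
                       M = 4000, seed = NULL, external_prevalence = NULL) {
  stopifnot(inherits(data, "binary_validation_data"),
            inherits(thresholds, "threshold_grid"), M >= 1)
  p_prior <- priors$p %||% beta_prior()
  if (!inherits(p_prior, "beta_prior")) {
    stop("priors$p must be a single beta_prior (prevalence is shared ",
         "across thresholds)", call. = FALSE)
  }
  nt <- nrow(thresholds)
  maybe_with_seed(seed, {
    d <- sum(data$outcome)
    nd <- data$n - d
    p_draws <- if (is.null(external_prevalence)) {
      rbeta(M, d + p_prior$shape1, nd + p_prior$shape2)
    } else {
      stopifnot(length(external_prevalence) == 2,
                all(external_prevalence >= 0))
      rbeta(M, external_prevalence[1] + p_prior$shape1,
            external_prevalence[2] + p_prior$shape2)
    }

    nb_list <- list()
    flags <- matrix(FALSE, length(data$strategies) + 2, nt,
                    dimnames = list(c(data$strategies, "treat_all",
                                      "treat_none"), NULL))
    zero_cells <- character(0)
    for (s in data$strategies) {
      m <- matrix(NA_real_, nt, M)
      for (k in seq_len(nt)) {
        t_k <- thresholds$threshold[k]
        cts <- tabulate_counts(data, s, t_k)
        if (cts$tp + cts$fp == 0) {
          flags[s, k] <- TRUE
          zero_cells <- c(zero_cells, sprintf("%s @ %g", s, t_k))
        }
        se_prior <- resolve_beta_prior(priors$se, s, t_k)
        sp_prior <- resolve_beta_prior(priors$sp, s, t_k)
        se <- rbeta(M, cts$tp + se_prior$shape1, cts$fn + se_prior$shape2)
        sp <- rbeta(M, cts$tn + sp_prior$shape1, cts$fp + sp_prior$shape2)
        m[k, ] <- nb_binary(se, sp, p_draws, t_k)
      }
      nb_list[[s]] <- m
    }
    nb_list$treat_all <- t(vapply(thresholds$threshold, function(t_k) {
      net_benefit_treat_all_binary(p_draws, t_k)
    }, numeric(M)))
    if (length(zero_cells)) {
      warning("no positive predictions at: ",
              paste(head(zero_cells, 10), collapse = "; "),
              if (length(zero_cells) > 10) "; ...",
              " (posterior is prior-dominated there)", call. = FALSE)
    }
    decision_curve_set(nb_list, thresholds, "binary", p_draws = p_draws,
                       flags = flags,
                       meta = list(seed = seed, M = M, n = data$n,
                                   d = d,
                                   external_prevalence = external_prevalence))
  })
}

#' Bayesian decision curve analysis for survival outcomes
#'
#' At each threshold and for each strategy, the positivity probability is
#' sampled from its conjugate Beta posterior and the event-time
#' distribution among positive predictions from a censored Weibull
#' posterior via MCMC; their draws combine into net benefit at the
#' prediction horizon. The Treat-all curve uses a single cohort-wide
#' Weibull fit (positivity fixed at 1) shared across thresholds. Expect a
#' runtime of minutes rather than seconds: one MCMC run per strategy and
#' threshold.
#'
#' @param data A [survival_validation_data()] object.
#' @param thresholds A [threshold_grid()].
#' @param horizon Prediction horizon; defaults to the one stored in
#'   `data`. Must be explicit — there is no universal default.
#' @param priors Optional list with entries `positivity` (a
#'   [beta_prior()]) and `weibull` (a [weibull_prior()]).
#' @param mcmc List overriding `chains` (4), `warmup` (1000), `draws`
#'   (1000 per chain); the retained total `chains * draws` is the draw
#'   count `M` of the returned set.
#' @param seed Optional master seed; per-cell chain seeds are derived
#'   deterministically.
#' @param rhat_max,on_nonconvergence Passed to
#'   [sample_weibull_posterior()]. Note that split-\eqn{\hat R} is a
#'   noisy statistic for short chains; the default gate of 1.01 is
#'   calibrated to the default 4 x 1000 configuration.
#' @return A `dca_set` object; per-cell MCMC diagnostics are available
#'   via [mcmc_diagnostics()].
#' @export
dca_survival <- function(data, thresholds = threshold_grid(),
                         horizon = data$horizon, priors = NULL,
                         mcmc = list(), seed = NULL, rhat_max = 1.01,
                         on_nonconvergence = c("error", "warn")) {
  stopifnot(inherits(data, "survival_validation_data"),
            inherits(thresholds, "threshold_grid"))
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (is.null(horizon) || !is.numeric(horizon) || horizon <= 0) {
    stop("survival DCA requires a positive prediction horizon",
         call. = FALSE)
  }
  chains <- mcmc$chains %||% 4
  warmup <- mcmc$warmup %||% 1000
  draws <- mcmc$draws %||% 1000
  M <- chains * draws
  pos_prior <- priors$positivity %||% beta_prior()
  wb_prior <- priors$weibull %||% weibull_prior()
  nt <- nrow(thresholds)
  seed_counter <- 0
  next_seed <- function() {
    seed_counter <<- seed_counter + 1
    if (is.null(seed)) NULL else derive_seed(seed, seed_counter)
  }

  maybe_with_seed(seed, {
    cohort_fit <- sample_weibull_posterior(
      data$time, data$event, prior = wb_prior, chains = chains,
      warmup = warmup, draws = draws, seed = next_seed(),
      rhat_max = rhat_max, on_nonconvergence = on_nonconvergence)

    nb_list <- list()
    diagnostics <- list()
    flags <- matrix(FALSE, length(data$strategies) + 2, nt,
                    dimnames = list(c(data$strategies, "treat_all",
                                      "treat_none"), NULL))
    zero_cells <- character(0)
    for (s in data$strategies) {
      m <- matrix(NA_real_, nt, M)
      for (k in seq_len(nt)) {
        t_k <- thresholds$threshold[k]
        tab <- tabulate_survival(data, s, t_k)
        p <- sample_positivity(tab$n_pos, tab$n, pos_prior, M,
                               seed = next_seed())
        if (tab$zero_positives) {
          flags[s, k] <- TRUE
          zero_cells <- c(zero_cells, sprintf("%s @ %g", s, t_k))
          fit <- suppressWarnings(sample_weibull_posterior(
            numeric(0), numeric(0), prior = wb_prior, chains = chains,
            warmup = warmup, draws = draws, seed = next_seed()))
        } else {
          fit <- sample_weibull_posterior(
            tab$times, tab$events, prior = wb_prior, chains = chains,
            warmup = warmup, draws = draws, seed = next_seed(),
            rhat_max = rhat_max, on_nonconvergence = on_nonconvergence)
        }
        s_tau <- survival_at_horizon(fit$alpha, fit$sigma, horizon)
        m[k, ] <- net_benefit_survival(s_tau, p, t_k)
        diagnostics[[s]][[k]] <- c(list(threshold = t_k,
                                        prior_only = fit$prior_only),
                                   fit$diagnostics)
      }
      nb_list[[s]] <- m
    }
    s_cohort <- survival_at_horizon(cohort_fit$alpha, cohort_fit$sigma,
                                    horizon)
    nb_list$treat_all <- t(vapply(thresholds$threshold, function(t_k) {
      (1 - s_cohort) - s_cohort * threshold_weight(t_k)
    }, numeric(M)))
    if (length(zero_cells)) {
      warning("no positive predictions at: ",
              paste(head(zero_cells, 10), collapse = "; "),
              if (length(zero_cells) > 10) "; ...",
              " (prior-only Weibull draws used there)", call. = FALSE)
    }
    decision_curve_set(
      nb_list, thresholds, "survival", p_draws = NULL, flags = flags,
      meta = list(seed = seed, M = M, horizon = horizon, n = data$n,
                  mcmc = list(chains = chains, warmup = warmup,
                              draws = draws),
                  diagnostics = diagnostics,
                  cohort_diagnostics = cohort_fit$diagnostics))
  })
}

#' MCMC diagnostics of a survival decision curve set
#'
#' @param set A `dca_set` produced by [dca_survival()].
#' @return A data frame with one row per (strategy, threshold):
#'   split-\eqn{\hat R} and effective sample size for both Weibull
#'   parameters, the divergence field (`NA`: not applicable to the Gibbs
#'   sampler used), and whether the cell fell back to the prior.
#' @export
mcmc_diagnostics <- function(set) {
  stopifnot(inherits(set, "dca_set"))
  if (set$outcome_type != "survival") {
    stop("diagnostics are only available for survival decision curves",
         call. = FALSE)
  }
  rows <- list()
  for (s in names(set$meta$diagnostics)) {
    for (d in set$meta$diagnostics[[s]]) {
      rows[[length(rows) + 1]] <- data.frame(
        strategy = s, threshold = d$threshold,
        rhat_alpha = d$rhat[["alpha"]], rhat_sigma = d$rhat[["sigma"]],
        ess_alpha = d$ess[["alpha"]], ess_sigma = d$ess[["sigma"]],
        divergences = d$divergences, prior_only = d$prior_only)
    }
  }
  do.call(rbind, rows)
}
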