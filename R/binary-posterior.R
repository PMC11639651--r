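#' Closed-form posterior parameters for the binary model
#'
#' The joint model of disease status and positive predictions factorizes
#' into three independent Bernoulli likelihoods for prevalence,
#' sensitivity and specificity, so with independent Beta priors the joint
#' posterior is a product of Beta distributions:
#' \deqn{p \sim Beta(D + \alpha_0,\; ND + \beta_0)}
#' \deqn{Se \sim Beta(TP + \alpha_1,\; FN + \beta_1)}
#' \deqn{Sp \sim Beta(TN + \alpha_2,\; FP + \beta_2)}
#' Specificity is modeled directly (rather than its complement) so that
#' priors are stated in the terms users think in.
#'
#' @param counts A [tabulate_counts()] result.
#' @param priors Named list with optional entries `p`, `se`, `sp`, each a
#'   [beta_prior()]; missing entries default to `beta_prior(1, 1)`.
#' @return List of three `c(shape1, shape2)` pairs: `p`, `se`, `sp`.
#' @export
binary_posterior_params <- function(counts, priors = list()) {
  stopifnot(inherits(counts, "diagnostic_counts"))
  pp <- priors$p %||% beta_prior()
  pse <- priors$se %||% beta_prior()
  psp <- priors$sp %||% beta_prior()
  stopifnot(inherits(pp, "beta_prior"), inherits(pse, "beta_prior"),
            inherits(psp, "beta_prior"))
  list(p = c(counts$d + pp$shape1, counts$nd + pp$shape2),
       se = c(counts$tp + pse$shape1, counts$fn + pse$shape2),
       sp = c(counts$tn + psp$shape1, counts$fp + psp$shape2))
}

#' Sample the joint posterior of (prevalence, sensitivity, specificity)
#'
#' Draws are taken independently from the three marginal Beta posteriors;
#' posterior independence (a consequence of parameter orthogonality in the
#' likelihood) makes the combined draws valid samples of the joint
#' posterior, with no MCMC involved. When a threshold admits no positive
#' prediction (`TP + FP = 0`) the sensitivity and specificity posteriors
#' are prior-dominated but remain proper; nothing collapses to zero.
#'
#' @inheritParams binary_posterior_params
#' @param M Number of posterior draws (default 4000).
#' @param seed Optional seed; draws are reproducible given a seed.
#' @return A `binary_posterior_draws` object with vectors `p`, `se`, `sp`
#'   of length `M`, the originating `threshold` and `strategy`, and the
#'   closed-form `params`.
#' @examples
#' dat <- binary_validation_data(c(1, 1, 0, 0),
#'                               list(model = c(0.9, 0.2, 0.6, 0.1)))
#' cts <- tabulate_counts(dat, "model", 0.5)
#' draws <- sample_binary_posterior(cts, M = 1000, seed = 1)
#' mean(draws$p)
#' @export
sample_binary_posterior <- function(counts, priors = list(), M = 4000,
                                    seed = NULL) {
  stopifnot(M >= 1)
  par <- binary_posterior_params(counts, priors)
  draws <- maybe_with_seed(seed, {
    list(p = rbeta(M, par$p[1], par$p[2]),
         se = rbeta(M, par$se[1], par$se[2]),
         sp = rbeta(M, par$sp[1], par$sp[2]))
  })
  structure(c(draws,
              list(threshold = counts$threshold, strategy = counts$strategy,
                   params = par, M = M)),
            class = "binary_posterior_draws")
}

#' Prevalence posterior from external (population) data
#'
#' In case-control designs the sample case fraction is fixed by design and
#' cannot estimate prevalence. Instead, counts of cases and non-cases from
#' an external cross-sectional study or source cohort are combined with a
#' Beta prior, and the resulting draws replace the study-sample prevalence
#' draws in every downstream net benefit computation, propagating the
#' prevalence uncertainty instead of plugging in a point estimate.
#'
#' @param cases,noncases Non-negative integer counts from the external
#'   source. Both zero returns draws from the prior.
#' @param prior A [beta_prior()] (default uniform).
#' @param M Number of draws.
#' @param seed Optional seed.
#' @return Numeric vector of `M` prevalence draws.
#' @export
sample_prevalence_external <- function(cases, noncases,
                                       prior = beta_prior(), M = 4000,
                                       seed = NULL) {
  stopifnot(cases >= 0, noncases >= 0, inherits(prior, "beta_prior"),
            M >= 1)
  maybe_with_seed(seed,
    rbeta(M, cases + prior$shape1, noncases + prior$shape2))
}

# Net benefit per joint draw: NB = Se p - (1 - Sp)(1 - p) w_t.
nb_binary <- function(se, sp, p, t) {
  se * p - (1 - sp) * (1 - p) * threshold_weight(t)
}

#' Posterior net benefit draws for a binary-outcome strategy
#'
#' Applies \eqn{NB_t = Se_t\,p - (1 - Sp_t)(1 - p)\,w_t} to each joint
#' posterior draw, so the returned vector is index-aligned with the input
#' draws (draw \eqn{m} of the net benefit uses draw \eqn{m} of each
#' parameter).
#'
#' @param draws A [sample_binary_posterior()] result.
#' @param t Decision threshold in `[0, 1)`; defaults to the threshold the
#'   draws were tabulated at.
#' @return Numeric vector of net benefit draws.
#' @export
net_benefit_binary <- function(draws, t = draws$threshold) {
  stopifnot(inherits(draws, "binary_posterior_draws"), t >= 0, t < 1)
  nb_binary(draws$se, draws$sp, draws$p, t)
}

#' Net benefit draws for the Treat-all strategy (binary outcomes)
#'
#' Treating everyone turns every diseased patient into a true positive and
#' every non-diseased one into a false positive:
#' \eqn{NB_{all} = p - (1 - p) w_t}. Treat-none has net benefit 0 by
#' definition and needs no computation.
#'
#' @param p_draws Numeric vector of prevalence draws.
#' @param t Decision threshold in `[0, 1)`.
#' @return Numeric vector of net benefit draws, index-aligned with
#'   `p_draws`.
#' @export
net_benefit_treat_all_binary <- function(p_draws, t) {
  stopifnot(is.numeric(p_draws), t >= 0, t < 1)
  p_draws - (1 - p_draws) * threshold_weight(t)
}
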