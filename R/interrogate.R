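#' Posterior summaries of the decision curves
#'
#' Posterior means and percentile credible intervals of net benefit for
#' every strategy and threshold.
#'
#' @param set A `dca_set`.
#' @param level Credible level (default 0.95, reported as the 2.5\% and
#'   97.5\% posterior percentiles).
#' @return Data frame with columns `threshold`, `strategy`, `nb_mean`,
#'   `nb_lo`, `nb_hi`.
#' @export
summarize_curves <- function(set, level = 0.95) {
  stopifnot(inherits(set, "dca_set"), set$M >= 2, level > 0, level < 1)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- expand.grid(threshold = set$grid$threshold,
                     strategy = set$strategies,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats <- mapply(function(s, t) {
    x <- nb_draws(set, s, t)
    c(mean(x), quantile(x, probs, names = FALSE))
  }, out$strategy, out$threshold)
  out$nb_mean <- stats[1, ]
  out$nb_lo <- stats[2, ]
  out$nb_hi <- stats[3, ]
  out
}

#' Posterior probability that a strategy is clinically useful
#'
#' A strategy is useful at threshold `t` when its net benefit exceeds
#' both default strategies:
#' \eqn{P(\mathrm{useful}) = P(NB > \max\{NB_{all}, 0\})}, evaluated
#' draw-wise on index-aligned draws. Ties count as non-wins (the
#' posteriors are continuous, so ties are null events; strictness keeps
#' the degenerate identical-draws case well defined).
#'
#' @param set A `dca_set`.
#' @param strategy A model strategy (not `treat_all`/`treat_none`, whose
#'   usefulness is not defined by this statistic).
#' @param t Threshold present in the grid.
#' @return A probability in `[0, 1]`.
#' @export
p_useful <- function(set, strategy, t) {
  if (strategy %in% c("treat_all", "treat_none")) {
    stop("P(useful) is defined for model strategies only", call. = FALSE)
  }
  mean(nb_draws(set, strategy, t) >
         pmax(nb_draws(set, "treat_all", t), 0))
}

#' Posterior probability that a strategy is the best one available
#'
#' The fraction of joint posterior draws in which the strategy's net
#' benefit strictly exceeds the draw-wise maximum over every other
#' strategy under consideration, defaults included. With a single model
#' competing only against the defaults, `p_best` coincides with
#' [p_useful()].
#'
#' @param set A `dca_set`.
#' @param strategy Any strategy in the set.
#' @param t Threshold present in the grid.
#' @return A probability in `[0, 1]`.
#' @export
p_best <- function(set, strategy, t) {
  stopifnot(inherits(set, "dca_set"))
  if (!strategy %in% set$strategies) {
    stop("unknown strategy: '", strategy, "'", call. = FALSE)
  }
  k <- match_threshold(set$grid, t)
  m <- set$nb[, k, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                   dimnames = list(set$strategies))
  others <- setdiff(set$strategies, strategy)
  best_other <- apply(m[others, , drop = FALSE], 2, max)
  mean(m[strategy, ] > best_other)
}

#' Pairwise posterior superiority of one strategy over another
#'
#' Returns \eqn{P(NB_{s_1} - NB_{s_2} > c)} together with the full vector
#' of per-draw differences, suitable for density and interval displays.
#' The margin `c >= 0` (in net true positive units) accommodates, e.g.,
#' differential test harms.
#'
#' @param set A `dca_set`.
#' @param s1,s2 Distinct strategy names.
#' @param t Threshold present in the grid.
#' @param c Non-negative superiority margin (default 0).
#' @return List with `prob` and the `delta` draw vector.
#' @export
pairwise_superiority <- function(set, s1, s2, t, c = 0) {
  if (!is.numeric(c) || length(c) != 1 || c < 0) {
    stop("the superiority margin c must be a single number >= 0",
         call. = FALSE)
  }
  if (identical(s1, s2)) stop("s1 and s2 must differ", call. = FALSE)
  delta <- nb_draws(set, s1, t) - nb_draws(set, s2, t)
  list(prob = mean(delta > c), delta = delta)
}

#' Expected value of perfect information at a threshold
#'
#' \eqn{EVPI = E[\max_s NB_s] - \max_s E[NB_s]}: the expected net benefit
#' lost by committing to the apparently best strategy under current
#' parameter uncertainty instead of the actually best one. The inner
#' maximum is taken within each joint posterior draw (index-aligned
#' draws), the outer over posterior means. Always non-negative.
#'
#' @param set A `dca_set`.
#' @param t Threshold present in the grid.
#' @return A non-negative scalar, in net true positive units per patient.
#' @export
evpi <- function(set, t) {
  stopifnot(inherits(set, "dca_set"))
  k <- match_threshold(set$grid, t)
  m <- set$nb[, k, , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  e_max <- mean(apply(m, 2, max))
  max_e <- max(rowMeans(m))
  e_max - max_e
}

#' Full posterior interrogation of a decision curve set
#'
#' For every threshold and strategy: posterior mean and credible interval
#' of net benefit, P(useful) (models only), P(best), the difference
#' against the draw-wise best competitor (mean and interval), the
#' per-threshold EVPI, and the zero-positive-predictions flag.
#'
#' @param set A `dca_set`.
#' @param level Credible level for all intervals (default 0.95).
#' @return A `dca_interrogation` data frame with columns `threshold`,
#'   `strategy`, `nb_mean`, `nb_lo`, `nb_hi`, `p_useful`, `p_best`,
#'   `delta_mean`, `delta_lo`, `delta_hi`, `evpi`, `zero_positives`.
#' @export
interrogate <- function(set, level = 0.95) {
  stopifnot(inherits(set, "dca_set"), set$M >= 2)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  res <- list()
  for (k in seq_len(nrow(set$grid))) {
    t_k <- set$grid$threshold[k]
    m <- set$nb[, k, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                     dimnames = list(set$strategies))
    ev <- {
      e_max <- mean(apply(m, 2, max))
      e_max - max(rowMeans(m))
    }
    useful_ref <- pmax(m["treat_all", ], 0)
    for (s in set$strategies) {
      x <- m[s, ]
      others <- setdiff(set$strategies, s)
      delta <- x - apply(m[others, , drop = FALSE], 2, max)
      qs <- quantile(x, probs, names = FALSE)
      dq <- quantile(delta, probs, names = FALSE)
      res[[length(res) + 1]] <- data.frame(
        threshold = t_k, strategy = s,
        nb_mean = mean(x), nb_lo = qs[1], nb_hi = qs[2],
        p_useful = if (s %in% set$models) mean(x > useful_ref)
                   else NA_real_,
        p_best = mean(delta > 0),
        delta_mean = mean(delta), delta_lo = dq[1], delta_hi = dq[2],
        evpi = ev,
        zero_positives = unname(set$flags[s, k]))
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("dca_interrogation", "data.frame")
  attr(out, "M") <- set$M
  attr(out, "level") <- level
  out
}

#' Write interrogation results to CSV and/or JSON
#'
#' @param x A [interrogate()] result.
#' @param csv,json Optional output paths.
#' @return Invisibly, the written paths.
#' @export
write_interrogation <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "dca_interrogation"))
  if (!is.null(csv)) write.csv(x, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(as.data.frame(x), json, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(c(csv = csv, json = json))
}

#' Export net benefit draws in long format
#'
#' One row per (threshold, strategy, draw) for tool-agnostic downstream
#' use. Beware of size: the default grid with three strategies and 4000
#' draws is already over half a million rows.
#'
#' @param set A `dca_set`.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
export_nb_draws <- function(set, path) {
  stopifnot(inherits(set, "dca_set"))
  nt <- nrow(set$grid)
  long <- data.frame(
    threshold = rep(set$grid$threshold, times = length(set$strategies),
                    each = set$M),
    strategy = rep(set$strategies, each = nt * set$M),
    draw = rep(seq_len(set$M), times = length(set$strategies) * nt),
    nb = as.vector(aperm(set$nb, c(3, 2, 1))))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
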