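#' Per-threshold diagnostic counts for a binary strategy
#'
#' Classifies each patient as test-positive when their prediction strictly
#' exceeds the threshold (`prediction > t`; ties at the threshold count as
#' negative, which keeps a 0/1 binary test positive for every threshold in
#' (0, 1)) and cross-tabulates against the outcome. These counts are the
#' sufficient statistics of the conjugate Beta-Bernoulli posterior.
#'
#' @param data A [binary_validation_data()] object.
#' @param strategy Strategy name.
#' @param threshold Decision threshold in `[0, 1)`.
#' @return A `diagnostic_counts` object with fields `tp`, `fp`, `tn`,
#'   `fn`, `d`, `nd`, `n`, `threshold`, `strategy`. Always satisfies
#'   `tp + fn == d`, `fp + tn == nd`, `d + nd == n`.
#' @examples
#' dat <- binary_validation_data(c(1, 1, 0, 0),
#'                               list(model = c(0.9, 0.2, 0.6, 0.1)))
#' tabulate_counts(dat, "model", 0.5)
#' @export
tabulate_counts <- function(data, strategy, threshold) {
  stopifnot(inherits(data, "binary_validation_data"))
  if (!strategy %in% data$strategies) {
    stop("unknown strategy: '", strategy, "'", call. = FALSE)
  }
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  z <- data$predictions[[strategy]] > threshold
  d <- data$outcome == 1L
  out <- list(tp = sum(d & z), fp = sum(!d & z),
              tn = sum(!d & !z), fn = sum(d & !z),
              d = sum(d), nd = sum(!d), n = data$n,
              threshold = threshold, strategy = strategy)
  structure(out, class = "diagnostic_counts")
}

#' @export
print.diagnostic_counts <- function(x, ...) {
  cat(sprintf(
    "<diagnostic_counts> t = %g [%s]: TP %d FP %d TN %d FN %d (D %d, ND %d)\n",
    x$threshold, x$strategy, x$tp, x$fp, x$tn, x$fn, x$d, x$nd))
  invisible(x)
}

#' Positive-prediction subset for a survival strategy
#'
#' Splits the cohort at a decision threshold: patients whose predicted
#' event risk at the horizon strictly exceeds `t` form the positive set
#' whose follow-up feeds the censored Weibull model, while the positive
#' count feeds the Bernoulli positivity model. When no prediction exceeds
#' the threshold a non-fatal `zero_positives` flag is set; downstream
#' posteriors then fall back to the prior.
#'
#' @inheritParams tabulate_counts
#' @param data A [survival_validation_data()] object.
#' @return A list with `n_pos`, `n`, `times`, `events` (restricted to the
#'   positive set), `zero_positives`, `threshold`, `strategy`.
#' @export
tabulate_survival <- function(data, strategy, threshold) {
  stopifnot(inherits(data, "survival_validation_data"))
  if (!strategy %in% data$strategies) {
    stop("unknown strategy: '", strategy, "'", call. = FALSE)
  }
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  pos <- data$predictions[[strategy]] > threshold
  list(n_pos = sum(pos), n = data$n,
       times = data$time[pos], events = data$event[pos],
       zero_positives = !any(pos),
       threshold = threshold, strategy = strategy)
}
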