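#' Construct a grid of decision thresholds
#'
#' A decision threshold \eqn{t} is the predicted risk above which a patient
#' is treated. Each threshold carries the weight \eqn{w_t = t / (1 - t)}
#' that prices one false positive in units of true positives, so the grid
#' must stay strictly below 1 (at \eqn{t = 1} the weight is undefined).
#'
#' When `thresholds` is omitted the grid runs from `min` to `max` in steps
#' of `step`; the default 0 to 0.5 by 0.01 reflects the usual situation in
#' which false negatives are at least as costly as false positives, so
#' thresholds above 50\% are not of interest.
#'
#' @param thresholds Optional numeric vector of thresholds, each in
#'   `[0, 1)`. Overrides `min`/`max`/`step`.
#' @param min,max,step Range specification used when `thresholds` is
#'   `NULL`. `min <= max` and `step > 0`.
#' @return A `threshold_grid` data frame with columns `threshold` and
#'   `weight`, sorted, deduplicated.
#' @examples
#' threshold_grid(c(0, 0.25, 0.5))
#' threshold_grid(min = 0.05, max = 0.45, step = 0.05)
#' @export
threshold_grid <- function(thresholds = NULL, min = 0, max = 0.5,
                           step = 0.01) {
  if (is.null(thresholds)) {
    stopifnot(is.numeric(min), is.numeric(max), is.numeric(step),
              length(min) == 1, length(max) == 1, length(step) == 1)
    if (step <= 0) stop("step must be > 0", call. = FALSE)
    if (min > max) stop("min must be <= max", call. = FALSE)
    thresholds <- seq(min, max, by = step)
  }
  if (!is.numeric(thresholds) || length(thresholds) == 0 ||
      anyNA(thresholds)) {
    stop("thresholds must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(thresholds < 0 | thresholds >= 1)) {
    stop("all thresholds must lie in [0, 1): w_t = t/(1-t) is undefined ",
         "at t = 1", call. = FALSE)
  }
  t <- sort(unique(thresholds))
  out <- data.frame(threshold = t, weight = t / (1 - t))
  class(out) <- c("threshold_grid", "data.frame")
  out
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat(sprintf("<threshold_grid> %d thresholds in [%.3g, %.3g]\n",
              nrow(x), min(x$threshold), max(x$threshold)))
  NextMethod()
}

# Weight w_t = t/(1-t) for a bare threshold value.
threshold_weight <- function(t) {
  stopifnot(all(t >= 0 & t < 1))
  t / (1 - t)
}
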