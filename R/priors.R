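#' Beta prior
#'
#' Prior for any probability-scale parameter of the net benefit model:
#' prevalence, sensitivity, specificity, or the positivity probability in
#' the survival model. The default `beta_prior(1, 1)` is uniform on (0, 1).
#'
#' @param shape1,shape2 Strictly positive Beta shape parameters.
#' @return A `beta_prior` object.
#' @export
beta_prior <- function(shape1 = 1, shape2 = 1) {
  if (!is.numeric(shape1) || !is.numeric(shape2) ||
      length(shape1) != 1 || length(shape2) != 1 ||
      !is.finite(shape1) || !is.finite(shape2) ||
      shape1 <= 0 || shape2 <= 0) {
    stop("Beta prior shapes must be single positive numbers", call. = FALSE)
  }
  structure(list(shape1 = shape1, shape2 = shape2), class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("<beta_prior> Beta(%g, %g)\n", x$shape1, x$shape2))
  invisible(x)
}

#' Prior for the Weibull shape and scale parameters
#'
#' Defaults follow the half-Student-t choices
#' \eqn{\alpha_1 \sim} Half-t(df = 5, scale = 1.5) and
#' \eqn{\sigma_1 \sim} Half-t(df = 30, scale = 100): close to equal prior
#' mass on increasing (\eqn{\alpha > 1}) and decreasing hazards, and
#' largely vague about the time scale. A Gamma alternative is available;
#' it takes explicit `(shape, rate)` pairs and has no canonical default.
#'
#' @param family `"half_t"` (default) or `"gamma"`.
#' @param shape For `half_t`, `c(df, location, scale)` for the Weibull
#'   shape parameter (location must be 0); for `gamma`, `c(shape, rate)`.
#' @param scale Same structure, for the Weibull scale parameter.
#' @return A `weibull_prior` object.
#' @export
weibull_prior <- function(family = c("half_t", "gamma"),
                          shape = NULL, scale = NULL) {
  family <- match.arg(family)
  if (family == "half_t") {
    shape <- shape %||% c(df = 5, location = 0, scale = 1.5)
    scale <- scale %||% c(df = 30, location = 0, scale = 100)
    for (p in list(shape, scale)) {
      if (length(p) != 3 || p[[1]] <= 0 || p[[2]] != 0 || p[[3]] <= 0) {
        stop("half_t parameters must be c(df > 0, location = 0, scale > 0)",
             call. = FALSE)
      }
    }
  } else {
    if (is.null(shape) || is.null(scale)) {
      stop("the gamma family has no default; give c(shape, rate) for both ",
           "parameters", call. = FALSE)
    }
    for (p in list(shape, scale)) {
      if (length(p) != 2 || any(p <= 0)) {
        stop("gamma parameters must be c(shape > 0, rate > 0)",
             call. = FALSE)
      }
    }
  }
  structure(list(family = family, shape = unname(shape),
                 scale = unname(scale)),
            class = "weibull_prior")
}

#' @export
print.weibull_prior <- function(x, ...) {
  if (x$family == "half_t") {
    cat(sprintf(
      "<weibull_prior> alpha ~ Half-t(%g, 0, %g), sigma ~ Half-t(%g, 0, %g)\n",
      x$shape[1], x$shape[3], x$scale[1], x$scale[3]))
  } else {
    cat(sprintf(
      "<weibull_prior> alpha ~ Gamma(%g, %g), sigma ~ Gamma(%g, %g)\n",
      x$shape[1], x$shape[2], x$scale[1], x$scale[2]))
  }
  invisible(x)
}

# Resolve a prior specification to a single beta_prior for one
# (strategy, threshold) cell. Accepted forms:
#   * a beta_prior, used everywhere;
#   * a data frame with columns threshold/shape1/shape2 (per-threshold
#     prior table, the hook for threshold-dependent informative priors);
#   * a named list keyed by strategy, each element one of the above.
resolve_beta_prior <- function(prior, strategy = NULL, threshold = NULL) {
  if (is.null(prior)) return(beta_prior())
  if (inherits(prior, "beta_prior")) return(prior)
  if (is.data.frame(prior)) {
    need <- c("threshold", "shape1", "shape2")
    if (!all(need %in% names(prior))) {
      stop("a prior table needs columns threshold, shape1, shape2",
           call. = FALSE)
    }
    idx <- which(abs(prior$threshold - threshold) < 1e-9)
    if (length(idx) != 1) {
      stop("prior table has no row for threshold ", format(threshold),
           call. = FALSE)
    }
    return(beta_prior(prior$shape1[idx], prior$shape2[idx]))
  }
  if (is.list(prior) && !is.null(strategy) && strategy %in% names(prior)) {
    return(resolve_beta_prior(prior[[strategy]], strategy, threshold))
  }
  stop("cannot interpret prior specification", call. = FALSE)
}
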