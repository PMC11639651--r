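# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministic integer stream used to give each simulation replicate (or
#' each MCMC chain) its own reproducible seed. Two multiplicative
#' congruential steps modulo the Mersenne prime 2^31 - 1 keep every value a
#' valid 32-bit R seed while decorrelating consecutive indices.
#'
#' @param seed Master seed (single integer-valued number).
#' @param index Non-negative integer index of the child stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(index), length(index) == 1, index >= 0)
  m <- 2147483647
  h <- (abs(seed) %% m)
  h <- (h * 48271 + index + 1) %% m
  h <- (h * 69621) %% m
  as.integer(h + (h == 0))
}

# Run `expr` under `seed` when given, restoring the caller's RNG state;
# with seed = NULL the ambient RNG stream is consumed as usual.
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Index of `t` in a threshold grid, matching to numerical tolerance.
match_threshold <- function(grid, t) {
  stopifnot(inherits(grid, "threshold_grid"))
  idx <- which(abs(grid$threshold - t) < 1e-9)
  if (length(idx) != 1) {
    stop("threshold ", format(t), " is not in the grid", call. = FALSE)
  }
  idx
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
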