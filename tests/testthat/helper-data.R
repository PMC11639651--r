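# Small in-code fixtures.

toy_binary <- function() {
  binary_validation_data(c(1, 1, 0, 0),
                         list(model = c(0.9, 0.2, 0.6, 0.1)))
}

write_binary_csv <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(outcome = c(1, 1, 0, 0),
                     model = c(0.9, 0.2, 0.6, 0.1),
                     test = c(1, 0, 1, 0))
  }
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

write_survival_csv <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(time = c(3, 14, 7, 20, 1),
                     event = c(1, 0, 1, 0, 1),
                     model = c(0.8, 0.3, 0.9, 0.1, 0.7))
  }
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# A moderately informative simulated binary validation sample.
sim_binary_sample <- function(n = 500, prev = 0.2, seed = 42) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, prev)
    lp <- qlogis(prev) + 1.2 * y + rnorm(n, 0, 1)
    binary_validation_data(y, list(model = plogis(lp)))
  })
}
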