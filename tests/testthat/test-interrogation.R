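test_that("curve summaries reproduce means and order-statistic percentiles", {
  const <- tiny_set(list(model = rep(0.3, 100), treat_all = rep(0.1, 100)))
  s <- summarize_curves(const)
  row <- s[s$strategy == "model", ]
  expect_equal(c(row$nb_mean, row$nb_lo, row$nb_hi), c(0.3, 0.3, 0.3))
  none <- s[s$strategy == "treat_none", ]
  expect_equal(c(none$nb_mean, none$nb_lo, none$nb_hi), c(0, 0, 0))

  # sorted 1..10000 scaled to (0, 1]: type-7 order statistics by hand
  x <- (1:10000) / 10000
  s2 <- summarize_curves(tiny_set(list(model = x,
                                       treat_all = rep(-1, 10000))))
  row2 <- s2[s2$strategy == "model", ]
  h <- function(p) {
    j <- (10000 - 1) * p + 1
    lo <- floor(j)
    (x[lo] + (j - lo) * (x[lo + 1] - x[lo]))
  }
  expect_equal(row2$nb_lo, h(0.025))
  expect_equal(row2$nb_hi, h(0.975))
})

test_that("P(useful) counts draws beating both defaults, strictly", {
  s <- tiny_set(list(model = c(0.2, 0.3), treat_all = c(0.1, 0.35)))
  expect_equal(p_useful(s, "model", 0.1), 0.5)
  neg <- tiny_set(list(model = c(-0.2, -0.1), treat_all = c(-0.5, -0.4)))
  expect_equal(p_useful(neg, "model", 0.1), 0)
  tied <- tiny_set(list(model = c(0.1, 0.2), treat_all = c(0.1, 0.2)))
  expect_equal(p_useful(tied, "model", 0.1), 0)
  expect_error(p_useful(s, "treat_all", 0.1), "model strategies")
})

test_that("P(best) enumerates draw-wise wins over all competitors", {
  s <- tiny_set(list(A = c(0.3, 0.1), B = c(0.2, 0.2),
                     treat_all = c(0, 0)))
  expect_equal(p_best(s, "A", 0.1), 0.5)
  expect_equal(p_best(s, "B", 0.1), 0.5)
  dom <- tiny_set(list(A = c(0.5, 0.6), B = c(0.2, 0.2),
                       treat_all = c(0, 0)))
  expect_equal(p_best(dom, "A", 0.1), 1)
  # single model: P(best) reduces to P(useful)
  withr::with_seed(21, {
    one <- tiny_set(list(model = rnorm(500, 0.05, 0.1),
                         treat_all = rnorm(500, 0.02, 0.1)))
    expect_equal(p_best(one, "model", 0.1), p_useful(one, "model", 0.1))
  })
})

test_that("P(best) sums to one across strategies for continuous draws", {
  withr::with_seed(31, {
    s <- tiny_set(list(A = rnorm(2000, 0.05, 0.05),
                       B = rnorm(2000, 0.04, 0.05),
                       treat_all = rnorm(2000, 0.02, 0.05)))
    total <- sum(vapply(s$strategies, function(st) p_best(s, st, 0.1),
                        numeric(1)))
    expect_equal(total, 1)
  })
})

test_that("pairwise superiority enumerates margin exceedances", {
  deltas <- c(-0.1, 0.2, 0.3, 0.4)
  s <- tiny_set(list(A = deltas, B = rep(0, 4), treat_all = rep(-1, 4)))
  cmp <- pairwise_superiority(s, "A", "B", 0.1)
  expect_equal(cmp$prob, 0.75)
  expect_equal(cmp$delta, deltas)
  same <- tiny_set(list(A = c(0.1, 0.2), B = c(0.1, 0.2),
                        treat_all = c(0, 0)))
  expect_equal(pairwise_superiority(same, "A", "B", 0.1)$prob, 0)
  above <- tiny_set(list(A = c(0.10, 0.12), B = c(0.01, 0.02),
                         treat_all = c(-1, -1)))
  expect_equal(pairwise_superiority(above, "A", "B", 0.1, c = 0.05)$prob, 1)
  expect_error(pairwise_superiority(s, "A", "B", 0.1, c = -0.01), ">= 0")
  expect_error(pairwise_superiority(s, "A", "A", 0.1), "differ")
})

test_that("EVPI matches hand enumeration and is always non-negative", {
  same <- tiny_set(list(model = c(0.1, 0.4), treat_all = c(0.1, 0.4)))
  expect_equal(evpi(same, 0.1), 0)
  # model {-0.1, 0.3} against the defaults: Emax = 0.15, maxE = 0.1
  s <- tiny_set(list(model = c(-0.1, 0.3), treat_all = c(-5, -5)))
  expect_equal(evpi(s, 0.1), 0.05)
  withr::with_seed(41, {
    for (i in 1:20) {
      r <- tiny_set(list(A = rnorm(200), B = rnorm(200),
                         treat_all = rnorm(200)))
      expect_gte(evpi(r, 0.1), 0)
    }
  })
})

test_that("with two or more models, P(best) never exceeds P(useful)", {
  withr::with_seed(51, {
    for (i in 1:10) {
      s <- tiny_set(list(A = rnorm(500, 0.03, 0.05),
                         B = rnorm(500, 0.03, 0.05),
                         treat_all = rnorm(500, 0.01, 0.05)))
      for (st in c("A", "B")) {
        expect_lte(p_best(s, st, 0.1), p_useful(s, st, 0.1))
      }
    }
  })
})

test_that("interrogation output is invariant to strategy ordering", {
  withr::with_seed(61, {
    draws <- list(A = rnorm(300, 0.05, 0.04), B = rnorm(300, 0.04, 0.04),
                  treat_all = rnorm(300, 0.02, 0.04))
    r1 <- interrogate(tiny_set(draws))
    r2 <- interrogate(tiny_set(draws[c("B", "treat_all", "A")]))
    key <- function(r) r[order(r$strategy),
                         setdiff(names(r), "strategy")]
    expect_equal(key(r1), key(r2), ignore_attr = TRUE)
  })
})

test_that("interrogate reports a coherent table", {
  withr::with_seed(71, {
    dat <- sim_binary_sample(400)
    set <- dca_binary(dat, threshold_grid(c(0.05, 0.2, 0.35)), M = 2000,
                      seed = 7)
    res <- interrogate(set)
    expect_setequal(names(res),
                    c("threshold", "strategy", "nb_mean", "nb_lo", "nb_hi",
                      "p_useful", "p_best", "delta_mean", "delta_lo",
                      "delta_hi", "evpi", "zero_positives"))
    expect_equal(nrow(res), 3 * 3)
    none <- res[res$strategy == "treat_none", ]
    expect_true(all(none$nb_mean == 0 & none$nb_lo == 0 & none$nb_hi == 0))
    expect_true(all(is.na(res$p_useful[res$strategy != "model"])))
    expect_true(all(res$evpi >= 0))
    # per threshold the evpi column is a single value
    expect_equal(as.vector(tapply(res$evpi, res$threshold,
                                  function(x) length(unique(x)))),
                 rep(1L, 3))
    # p_useful/p_best recompute from the accessor functions
    for (t in c(0.05, 0.2, 0.35)) {
      row <- res[res$strategy == "model" & res$threshold == t, ]
      expect_equal(row$p_useful, p_useful(set, "model", t))
      expect_equal(row$p_best, p_best(set, "model", t))
      expect_equal(row$evpi, evpi(set, t))
    }
  })
})

test_that("draw exports round-trip through the long CSV", {
  withr::with_seed(81, {
    set <- dca_binary(sim_binary_sample(150), threshold_grid(c(0.1, 0.3)),
                      M = 50, seed = 3)
    path <- tempfile(fileext = ".csv")
    export_nb_draws(set, path)
    long <- read.csv(path)
    expect_equal(nrow(long), 2 * length(set$strategies) * 50)
    cell <- long[long$strategy == "model" & long$threshold == 0.3, ]
    expect_equal(cell$nb[order(cell$draw)], nb_draws(set, "model", 0.3))
    res <- interrogate(set)
    out <- tempfile(fileext = ".csv")
    write_interrogation(res, csv = out)
    back <- read.csv(out)
    expect_equal(back$nb_mean, res$nb_mean)
    expect_equal(back$p_best, res$p_best)
  })
})
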