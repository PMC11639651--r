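#' Plot posterior decision curves
#'
#' Posterior mean net benefit per strategy across thresholds with
#' credible-interval ribbons; Treat-none is the zero line.
#'
#' @param x A [interrogate()] result (or a data frame with the same
#'   columns, e.g. read back from `interrogation.csv`).
#' @return A ggplot object.
#' @export
plot_decision_curves <- function(x) {
  x <- check_interrogation_frame(x, c("threshold", "strategy", "nb_mean",
                                      "nb_lo", "nb_hi"))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$threshold, y = .data$nb_mean,
                                  colour = .data$strategy,
                                  fill = .data$strategy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$nb_lo,
                                      ymax = .data$nb_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Decision threshold", y = "Net benefit",
                  colour = "Strategy", fill = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot P(useful) and P(best) across thresholds
#'
#' @inheritParams plot_decision_curves
#' @return A ggplot object with one panel per statistic.
#' @export
plot_probabilities <- function(x) {
  x <- check_interrogation_frame(x, c("threshold", "strategy",
                                      "p_useful", "p_best"))
  long <- rbind(
    data.frame(threshold = x$threshold, strategy = x$strategy,
               statistic = "P(useful)", value = x$p_useful),
    data.frame(threshold = x$threshold, strategy = x$strategy,
               statistic = "P(best)", value = x$p_best))
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~statistic) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Decision threshold", y = "Posterior probability",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot the posterior density of a pairwise net benefit difference
#'
#' Density of \eqn{NB_{s_1} - NB_{s_2}} at one threshold, with the
#' posterior mean and central 66\% and 95\% intervals drawn under the
#' curve.
#'
#' @param set A `dca_set`.
#' @param s1,s2 Strategies to compare.
#' @param t Threshold present in the grid.
#' @param levels Interval levels (default `c(0.66, 0.95)`).
#' @return A ggplot object.
#' @export
plot_pairwise <- function(set, s1, s2, t, levels = c(0.66, 0.95)) {
  cmp <- pairwise_superiority(set, s1, s2, t)
  delta <- cmp$delta
  qs <- lapply(levels, function(l) {
    quantile(delta, c((1 - l) / 2, 1 - (1 - l) / 2), names = FALSE)
  })
  df <- data.frame(delta = delta)
  bars <- data.frame(level = factor(levels),
                     lo = vapply(qs, `[`, numeric(1), 1),
                     hi = vapply(qs, `[`, numeric(1), 2),
                     size = rev(seq_along(levels)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_segment(data = bars,
                          ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       linewidth = .data$size),
                          y = 0, yend = 0, show.legend = FALSE) +
    ggplot2::geom_point(x = mean(delta), y = 0, size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("NB(%s) - NB(%s) at t = %g  [P(>0) = %.3f]",
                              s1, s2, t, cmp$prob),
                  y = "Posterior density") +
    ggplot2::theme_minimal()
}

#' Plot the validation EVPI across thresholds
#'
#' @inheritParams plot_decision_curves
#' @return A ggplot object.
#' @export
plot_evpi <- function(x) {
  x <- check_interrogation_frame(x, c("threshold", "evpi"))
  ev <- unique(x[, c("threshold", "evpi")])
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$threshold, y = .data$evpi)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::expand_limits(y = 0) +
    ggplot2::labs(x = "Decision threshold",
                  y = "EVPI (net true positives per patient)") +
    ggplot2::theme_minimal()
}

check_interrogation_frame <- function(x, needed) {
  if (is.character(x)) {
    path <- x
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    x <- read.csv(path)
    missing <- setdiff(needed, names(x))
    if (length(missing)) {
      stop("file '", path, "' is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Write the standard figure set for an interrogation result
#'
#' Renders decision curves with credible bands, the P(useful)/P(best)
#' panels and the EVPI-by-threshold line to image files.
#'
#' @param x An [interrogate()] result, or the path to an
#'   `interrogation.csv` written by [run_dca()].
#' @param dir Output directory.
#' @param format Image format understood by [ggplot2::ggsave()]
#'   (default `"png"`).
#' @return Invisibly, the written file paths.
#' @export
export_plots <- function(x, dir = ".", format = "png") {
  x <- check_interrogation_frame(x, c("threshold", "strategy", "nb_mean",
                                      "nb_lo", "nb_hi", "p_useful",
                                      "p_best", "evpi"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    decision_curves = file.path(dir, paste0("decision_curves.", format)),
    probabilities = file.path(dir, paste0("probabilities.", format)),
    evpi = file.path(dir, paste0("evpi.", format)))
  ggplot2::ggsave(paths[["decision_curves"]], plot_decision_curves(x),
                  width = 7, height = 4.5, dpi = 150)
  ggplot2::ggsave(paths[["probabilities"]], plot_probabilities(x),
                  width = 7, height = 4, dpi = 150)
  ggplot2::ggsave(paths[["evpi"]], plot_evpi(x),
                  width = 7, height = 4, dpi = 150)
  invisible(paths)
}
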