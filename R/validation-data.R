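#' Validation data for binary outcomes
#'
#' Bundles the disease indicator of each patient with the risk predictions
#' (or 0/1 binary test results) of one or more decision strategies, after
#' validating ranges and lengths. Data must be complete-case: the
#' per-threshold counts that feed the conjugate posterior are only well
#' defined when every patient contributes an outcome and a prediction.
#'
#' @param outcome Integer/numeric vector of 0/1 disease indicators.
#' @param predictions Named list or data frame, one element per strategy,
#'   each a numeric vector of predictions in `[0, 1]` (probabilities for a
#'   model, 0/1 for a binary test).
#' @return A `binary_validation_data` object with fields `outcome`,
#'   `predictions` (data frame), `n`, `strategies`.
#' @seealso [read_validation_csv()], [tabulate_counts()]
#' @examples
#' binary_validation_data(c(1, 1, 0, 0),
#'                        list(model = c(0.9, 0.2, 0.6, 0.1)))
#' @export
binary_validation_data <- function(outcome, predictions) {
  predictions <- as.data.frame(predictions)
  check_strategy_names(names(predictions))
  n <- length(outcome)
  if (n == 0) stop("outcome must be non-empty", call. = FALSE)
  if (anyNA(outcome) || !all(outcome %in% c(0, 1))) {
    bad <- which(is.na(outcome) | !(outcome %in% c(0, 1)))
    stop("column 'outcome', row(s) ", paste(head(bad, 5), collapse = ", "),
         ": outcome must be 0 or 1", call. = FALSE)
  }
  for (s in names(predictions)) {
    check_prediction_column(predictions[[s]], s, n)
  }
  structure(list(outcome = as.integer(outcome),
                 predictions = predictions,
                 n = n,
                 strategies = names(predictions)),
            class = "binary_validation_data")
}

#' Validation data for survival outcomes
#'
#' Stores observed follow-up times, event indicators and per-strategy
#' predicted event risks at a prediction horizon \eqn{\tau}. The event
#' indicator is 1 when the event was observed and 0 when the patient was
#' censored (note this is the complement of a censoring indicator; convert
#' before calling if your data code censoring as 1). Times must be
#' strictly positive (Weibull support) and in the same unit as `horizon`.
#'
#' @param time Positive numeric vector of observed times.
#' @param event Integer/numeric 0/1 vector; 1 = event observed.
#' @param predictions Named list/data frame of predicted event risks at
#'   `horizon`, each in `[0, 1]`.
#' @param horizon Positive scalar prediction horizon \eqn{\tau}.
#' @return A `survival_validation_data` object with fields `time`,
#'   `event`, `predictions`, `horizon`, `n`, `strategies`.
#' @examples
#' survival_validation_data(time = c(3, 14, 7), event = c(1, 0, 1),
#'                          predictions = list(model = c(0.8, 0.3, 0.9)),
#'                          horizon = 12)
#' @export
survival_validation_data <- function(time, event, predictions, horizon) {
  predictions <- as.data.frame(predictions)
  check_strategy_names(names(predictions))
  n <- length(time)
  if (n == 0) stop("time must be non-empty", call. = FALSE)
  if (anyNA(time) || !all(time > 0)) {
    bad <- which(is.na(time) | time <= 0)
    stop("column 'time', row(s) ", paste(head(bad, 5), collapse = ", "),
         ": times must be positive", call. = FALSE)
  }
  if (length(event) != n || anyNA(event) || !all(event %in% c(0, 1))) {
    stop("column 'event': must be 0/1 and match the length of 'time'",
         call. = FALSE)
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || !is.finite(horizon) ||
      horizon <= 0) {
    stop("horizon must be a single positive number (same time unit as ",
         "'time')", call. = FALSE)
  }
  for (s in names(predictions)) {
    check_prediction_column(predictions[[s]], s, n)
  }
  structure(list(time = as.numeric(time),
                 event = as.integer(event),
                 predictions = predictions,
                 horizon = horizon,
                 n = n,
                 strategies = names(predictions)),
            class = "survival_validation_data")
}

check_strategy_names <- function(nms) {
  if (length(nms) == 0 || anyNA(nms) || any(!nzchar(nms))) {
    stop("predictions must be a named list with at least one strategy",
         call. = FALSE)
  }
  reserved <- intersect(nms, c("treat_all", "treat_none"))
  if (length(reserved)) {
    stop("strategy names 'treat_all'/'treat_none' are reserved",
         call. = FALSE)
  }
  invisible(nms)
}

check_prediction_column <- function(x, name, n) {
  if (length(x) != n) {
    stop("column '", name, "': length differs from the outcome column",
         call. = FALSE)
  }
  bad <- which(is.na(x) | x < 0 | x > 1)
  if (length(bad)) {
    stop(sprintf("column '%s', row %d: prediction %s outside [0, 1]",
                 name, bad[1], format(x[bad[1]])), call. = FALSE)
  }
  invisible(x)
}

#' Read validation data from a CSV file
#'
#' Expects a header row. The binary schema has an `outcome` column (0/1)
#' plus one column per strategy; the survival schema has `time` and
#' `event` columns (event = 1 observed, 0 censored) plus one risk column
#' per strategy. Rows with missing values are rejected and reported by row
#' index; out-of-range values raise an error naming the offending column
#' and row.
#'
#' @param path Path to a CSV file (UTF-8, decimal point).
#' @param schema `"binary"` or `"survival"`.
#' @param horizon Prediction horizon, required for the survival schema.
#' @param on_missing `"error"` (default) refuses files containing missing
#'   values; `"drop"` removes the offending rows with a warning listing
#'   their indices.
#' @return A [binary_validation_data()] or [survival_validation_data()]
#'   object.
#' @export
read_validation_csv <- function(path, schema = c("binary", "survival"),
                                horizon = NULL,
                                on_missing = c("error", "drop")) {
  schema <- match.arg(schema)
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- if (schema == "binary") "outcome" else c("time", "event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  strat_cols <- setdiff(names(df), required)
  if (length(strat_cols) == 0) {
    stop("no strategy columns found in ", path, call. = FALSE)
  }
  bad_rows <- which(!complete.cases(df))
  if (length(bad_rows)) {
    msg <- paste0("rows with missing values: ",
                  paste(head(bad_rows, 10), collapse = ", "),
                  if (length(bad_rows) > 10) ", ...")
    if (on_missing == "error") {
      stop(msg, " (validation data must be complete-case)", call. = FALSE)
    }
    warning("dropped ", msg, call. = FALSE)
    df <- df[-bad_rows, , drop = FALSE]
  }
  if (schema == "binary") {
    binary_validation_data(df$outcome, df[strat_cols])
  } else {
    if (is.null(horizon)) {
      stop("the survival schema requires an explicit prediction horizon",
           call. = FALSE)
    }
    survival_validation_data(df$time, df$event, df[strat_cols], horizon)
  }
}

#' @export
print.binary_validation_data <- function(x, ...) {
  cat(sprintf("<binary_validation_data> n = %d, %d event(s), strategies: %s\n",
              x$n, sum(x$outcome), paste(x$strategies, collapse = ", ")))
  invisible(x)
}

#' @export
print.survival_validation_data <- function(x, ...) {
  cat(sprintf(
    "<survival_validation_data> n = %d, %d event(s), horizon = %g, strategies: %s\n",
    x$n, sum(x$event), x$horizon, paste(x$strategies, collapse = ", ")))
  invisible(x)
}
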