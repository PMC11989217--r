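#' Root mean square error of prediction (RMSEP)
#'
#' `sqrt(mean((truth - estimate)^2))` over a prediction set.
#'
#' @param truth,estimate Numeric vectors of equal, non-zero length.
#' @return A non-negative scalar; zero iff every prediction is exact.
#' @export
#' @examples
#' rmsep(0.6, 0.7)  # 0.1
rmsep <- function(truth, estimate) {
  check_pairs(truth, estimate)
  sqrt(mean((truth - estimate)^2))
}

#' Standard deviation of the reference labels (SD)
#'
#' Sample standard deviation (N - 1 denominator) of the reference moisture
#' labels. In the chemometric RPD convention the spread is taken over the
#' reference (training-label) values, not over the evaluation truths.
#'
#' @param reference_labels Numeric vector of at least two reference values.
#' @return A non-negative scalar.
#' @export
reference_sd <- function(reference_labels) {
  reference_labels <- as.numeric(reference_labels)
  if (length(reference_labels) < 2L || anyNA(reference_labels)) {
    abort("Need at least two non-missing reference labels.")
  }
  sd(reference_labels)
}

#' Relative predictive deviation (RPD)
#'
#' The ratio SD / RMSEP of the reference-label standard deviation to the
#' prediction error. Chemometric convention: RPD > 2 indicates a model that
#' judges the quantity well, 1-2 average ability, < 1 unusable.
#'
#' @inheritParams rmsep
#' @param reference_labels Reference values whose spread defines SD.
#' @return A scalar with attribute `band` (one of `"good"`, `"average"`,
#'   `"unusable"`). A perfect prediction set (RMSEP = 0) yields `Inf` with
#'   attribute `degenerate = TRUE` rather than an error.
#' @export
rpd <- function(truth, estimate, reference_labels) {
  s <- reference_sd(reference_labels)
  r <- rmsep(truth, estimate)
  if (r == 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    attr(out, "band") <- "good"
    return(out)
  }
  out <- s / r
  attr(out, "band") <- if (out > 2) "good" else if (out >= 1) "average" else "unusable"
  out
}

#' Correlation-type goodness statistic Rp
#'
#' The printed convention is `1 - sum((estimate - truth)^2) /
#' sum((estimate - ybar)^2)` with `ybar` the mean of the reference labels —
#' note the denominator is spread of the *estimates* about the reference mean.
#' `convention = "textbook"` instead uses the familiar coefficient-of-
#' determination denominator `sum((truth - ybar)^2)`. Both equal 1 exactly
#' when every prediction is exact.
#'
#' @inheritParams rpd
#' @param convention `"printed"` (default) or `"textbook"`.
#' @return A scalar (1 for perfect prediction).
#' @export
rp <- function(truth, estimate, reference_labels = truth,
               convention = c("printed", "textbook")) {
  convention <- match.arg(convention)
  check_pairs(truth, estimate)
  if (length(truth) < 2L) abort("Rp needs at least two prediction pairs.")
  ybar <- mean(as.numeric(reference_labels))
  num <- sum((estimate - truth)^2)
  den <- switch(convention,
                printed  = sum((estimate - ybar)^2),
                textbook = sum((truth - ybar)^2))
  if (den == 0) {
    abort(paste0("Rp denominator is zero (no spread about the reference mean",
                 " under the '", convention, "' convention)."))
  }
  1 - num / den
}

check_pairs <- function(truth, estimate) {
  if (length(truth) == 0L || length(estimate) == 0L) {
    abort("Prediction set is empty.")
  }
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  if (anyNA(truth) || anyNA(estimate)) abort("Missing values in prediction set.")
  invisible(TRUE)
}

#' Evaluation report for moisture predictions
#'
#' Computes the full evaluation suite — Rp, RMSEP, RPD and SD — for a set of
#' (true, predicted) moisture pairs, optionally grouped (e.g. per held-out
#' category).
#'
#' @param data A data frame of predictions.
#' @param truth,estimate Column names (tidy-eval) holding true and predicted
#'   moisture.
#' @param reference_labels Numeric vector of reference moisture labels used
#'   for `ybar` and SD; defaults to [reference_moisture_labels()]'s ten values.
#' @param group Optional column name to group by before computing metrics.
#' @param convention Rp convention, see [rp()].
#' @return A tibble with columns `n`, `Rp`, `RMSEP`, `RPD`, `SD` (plus the
#'   grouping column if requested), of class `tea_metric_report`.
#' @export
#' @examples
#' d <- tibble::tibble(truth = c(0.78, 0.72, 0.60), est = c(0.783, 0.721, 0.604))
#' moisture_metrics(d, truth, est)
moisture_metrics <- function(data, truth, estimate,
                             reference_labels = reference_moisture_labels()$moisture,
                             group = NULL,
                             convention = c("printed", "textbook")) {
  convention <- match.arg(convention)
  truth_q <- rlang::enquo(truth)
  est_q <- rlang::enquo(estimate)
  group_q <- rlang::enquo(group)
  one <- function(df) {
    y <- rlang::eval_tidy(truth_q, df)
    e <- rlang::eval_tidy(est_q, df)
    tibble(
      n = length(y),
      Rp = rp(y, e, reference_labels, convention = convention),
      RMSEP = rmsep(y, e),
      RPD = as.numeric(rpd(y, e, reference_labels)),
      SD = reference_sd(reference_labels)
    )
  }
  if (rlang::quo_is_null(group_q)) {
    out <- one(data)
  } else {
    out <- data |>
      dplyr::group_by(!!group_q) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  }
  class(out) <- c("tea_metric_report", class(out))
  out
}
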