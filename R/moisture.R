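#' Confidence-weighted moisture prediction
#'
#' Converts a vector of per-class softmax confidences into a continuous
#' moisture estimate as the expected value of the class moisture labels under
#' the confidence distribution: Y = sum_i Y_i * N_i, where Y_i is the moisture
#' label of withering class i and N_i the classifier's confidence for it.
#' Because a held-out withering stage lies between trained stages, its
#' moisture is representable as a convex combination of the trained labels —
#' the mechanism that lets a categorical classifier interpolate a continuous
#' quantity.
#'
#' Confidences are first rounded to `decimals` places and are deliberately
#' *not* renormalized afterwards; published confidence tables are typically
#' retained to eight decimals, so their sums deviate from 1 by rounding and
#' the reported estimates reflect that.
#'
#' @param conf Numeric vector of non-negative per-class confidences, same
#'   length as the label table. Must sum to 1 within `sum_tol` *before*
#'   rounding.
#' @param labels A moisture label table: either a numeric vector of strictly
#'   decreasing fractions in (0,1), or a data frame with columns `class_index`
#'   and `moisture` (as returned by [reference_moisture_labels()]).
#' @param decimals Number of decimal places confidences (and the reported
#'   estimate) are rounded to. Default 8, the published reporting convention.
#'   Use `NULL` for full double precision.
#' @param sum_tol Tolerance on `sum(conf)` before rounding (default 1e-6).
#' @return A single moisture fraction.
#' @seealso [assess_withering()], [assess_samples()]
#' @export
#' @examples
#' lab <- reference_moisture_labels()
#' ex <- example_confidences()
#' predict_moisture(ex$confidences$cat1, lab)  # 0.78325333
predict_moisture <- function(conf, labels, decimals = 8L, sum_tol = 1e-6) {
  y <- as_label_vector(labels)
  conf <- as.numeric(conf)
  if (length(conf) != length(y)) {
    abort(sprintf("`conf` has %d classes but the label table has %d.",
                  length(conf), length(y)))
  }
  if (anyNA(conf)) abort("`conf` contains missing values.")
  if (any(conf < 0)) abort("Confidences must be non-negative.")
  if (abs(sum(conf) - 1) > sum_tol) {
    abort(sprintf("Confidences sum to %.8f; expected 1 within %g before rounding.",
                  sum(conf), sum_tol))
  }
  if (!is.null(decimals)) {
    conf <- round(conf, decimals)
    return(round(sum(y * conf), decimals))
  }
  sum(y * conf)
}

as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("class_index", "moisture") %in% names(labels))) {
      abort("A label table data frame needs columns `class_index` and `moisture`.")
    }
    labels <- labels[order(labels$class_index), , drop = FALSE]
    idx <- as.integer(labels$class_index)
    if (anyDuplicated(idx)) {
      abort("Label table class indices must be unique.")
    }
    y <- as.numeric(labels$moisture)
  } else {
    y <- as.numeric(labels)
  }
  if (length(y) < 2L) abort("Need at least two moisture labels.")
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1)) {
    abort("Moisture labels must be fractions in (0, 1).")
  }
  if (any(diff(y) >= 0)) {
    abort("Moisture labels must be strictly decreasing with class index (withering loses water).")
  }
  y
}

#' Classify the degree of withering from moisture content
#'
#' Applies the industry moderate-withering band for fresh tea leaves:
#' moisture between 58% and 66% (inclusive at both ends) is `moderate`,
#' above 66% is `insufficient` (the leaf is still too wet), below 58% is
#' `excessive`.
#'
#' @param moisture Numeric vector of moisture fractions in \[0, 1\].
#' @param lower,upper Band edges as fractions (defaults 0.58 and 0.66).
#' @return A factor with levels `insufficient`, `moderate`, `excessive`.
#' @export
#' @examples
#' assess_withering(c(0.70, 0.62, 0.50))
assess_withering <- function(moisture, lower = 0.58, upper = 0.66) {
  moisture <- as.numeric(moisture)
  if (anyNA(moisture) || any(moisture < 0) || any(moisture > 1)) {
    abort("`moisture` must lie in [0, 1].")
  }
  out <- ifelse(moisture > upper, "insufficient",
                ifelse(moisture < lower, "excessive", "moderate"))
  factor(out, levels = c("insufficient", "moderate", "excessive"))
}

#' Predict moisture and withering degree for images
#'
#' Runs the classifier on each image, converts the softmax confidences into a
#' continuous moisture estimate via [predict_moisture()], and classifies the
#' withering degree via [assess_withering()]. Row order is preserved.
#'
#' @param data A leaf-sample tibble with a `pixels` list-column (H x W x 3
#'   integer arrays, 0-255), e.g. from [generate_leaf_images()] or
#'   [read_leaf_dataset()].
#' @param model A fitted classifier from [train_classifier()] (or a freshly
#'   built one from [build_classifier()]).
#' @param labels Moisture label table for the model's classes; defaults to the
#'   label table stored in the model at training time.
#' @param decimals Reporting precision passed to [predict_moisture()].
#' @return The input tibble (minus `pixels`) with added columns
#'   `predicted_moisture`, `degree`, and a `confidences` list-column.
#' @export
assess_samples <- function(data, model, labels = NULL, decimals = 8L) {
  stopifnot(is.data.frame(data), "pixels" %in% names(data))
  labels <- labels %||% model$label_table
  if (is.null(labels)) {
    abort("No label table: supply `labels` or train the model with one.")
  }
  y <- as_label_vector(labels)
  if (length(y) != model$plan$n_classes) {
    abort(sprintf("Model predicts %d classes but the label table has %d.",
                  model$plan$n_classes, length(y)))
  }
  conf <- predict(model, data)
  moist <- vapply(seq_len(nrow(conf)), function(i) {
    predict_moisture(as.numeric(conf[i, ]), y, decimals = decimals)
  }, numeric(1))
  out <- data[setdiff(names(data), "pixels")]
  out$predicted_moisture <- moist
  out$degree <- assess_withering(moist)
  out$confidences <- lapply(seq_len(nrow(conf)), function(i) as.numeric(conf[i, ]))
  as_tibble(out)
}
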