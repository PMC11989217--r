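#' Reference moisture labels for ten hourly withering time points
#'
#' Moisture content (wet basis, fraction of fresh mass) measured for ten
#' consecutive hourly withering time points of Jin Guan Yin fresh leaves,
#' indexed 0 (freshest, 78.43%) to 9 (most withered, 48.63%). These are the
#' class labels the confidence-weighted moisture model is trained against.
#'
#' @return A tibble with columns `class_index` (integer, 0-9) and `moisture`
#'   (double, strictly decreasing).
#' @seealso [default_moisture_labels()] for the 13-class extension used by the
#'   synthetic generator, [example_confidences()] for the worked example.
#' @export
#' @examples
#' reference_moisture_labels()
reference_moisture_labels <- function() {
  path <- system.file("extdata", "withering_reference_labels.csv",
                      package = "teawither", mustWork = TRUE)
  df <- read.csv(path)
  tibble(class_index = as.integer(df$class_index), moisture = df$moisture)
}

#' Worked-example confidence vectors for three held-out withering categories
#'
#' Softmax confidence vectors (retained to eight decimal places, hence summing
#' to 1 only up to rounding) produced by the trained classifier for single
#' images of three withering time points that were excluded from training
#' (external categories 1, 5 and 9), together with the measured moisture of
#' those categories. Feeding these through [predict_moisture()] with the
#' [reference_moisture_labels()] table reproduces the published continuous
#' moisture estimates.
#'
#' @return A list with elements `confidences` (tibble: `class_index`, `cat1`,
#'   `cat5`, `cat9`) and `truth` (tibble: `category`, `true_moisture`).
#' @export
#' @examples
#' ex <- example_confidences()
#' predict_moisture(ex$confidences$cat1, reference_moisture_labels())
example_confidences <- function() {
  conf <- read.csv(system.file("extdata", "external_category_confidences.csv",
                               package = "teawither", mustWork = TRUE))
  truth <- read.csv(system.file("extdata", "external_category_truth.csv",
                                package = "teawither", mustWork = TRUE))
  list(
    confidences = tibble(
      class_index = as.integer(conf$class_index),
      cat1 = conf$cat1, cat5 = conf$cat5, cat9 = conf$cat9
    ),
    truth = tibble(category = as.integer(truth$category),
                   true_moisture = truth$true_moisture)
  )
}

#' Default moisture labels for a synthetic withering series
#'
#' Builds a strictly decreasing moisture-label sequence for `n_classes`
#' withering time points. For 10 classes this is exactly the reference label
#' table; for 13 classes the three additional time points are inserted at
#' positions 1, 5 and 9 as midpoints of their neighbours (0.77785, 0.72455,
#' 0.60215), so that holding out classes 1/5/9 leaves precisely the ten
#' reference labels for training. Other class counts interpolate linearly
#' along the reference range.
#'
#' @param n_classes Number of withering time points (default 13).
#' @return Numeric vector of length `n_classes`, strictly decreasing, in (0,1).
#' @export
#' @examples
#' default_moisture_labels(13)
default_moisture_labels <- function(n_classes = 13L) {
  stopifnot(is.numeric(n_classes), length(n_classes) == 1L, n_classes >= 2)
  n_classes <- as.integer(n_classes)
  ref <- reference_moisture_labels()$moisture
  if (n_classes == 10L) return(ref)
  if (n_classes == 13L) {
    full <- numeric(13L)
    train_pos <- setdiff(0:12, c(1L, 5L, 9L)) + 1L
    full[train_pos] <- ref
    for (h in c(2L, 6L, 10L)) full[h] <- (full[h - 1L] + full[h + 1L]) / 2
    return(full)
  }
  stats::approx(seq(0, 1, length.out = 10L), ref,
                xout = seq(0, 1, length.out = n_classes))$y
}
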