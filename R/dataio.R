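#' Write a leaf dataset as a class-per-directory PNG tree
#'
#' Writes `root/<class_index>/<name>.png` for every sample plus a `labels.csv`
#' (`class_index`, `moisture`) at the root, so synthetic and externally
#' collected data are consumed identically downstream.
#'
#' @param data Sample tibble with `pixels`, `class_index`, `moisture`.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_leaf_dataset <- function(data, root) {
  stopifnot(is.data.frame(data),
            all(c("pixels", "class_index", "moisture") %in% names(data)))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  counter <- integer(0)
  for (i in seq_len(nrow(data))) {
    ci <- data$class_index[i]
    key <- as.character(ci)
    counter[key] <- (if (is.na(counter[key])) 0L else counter[key]) + 1L
    d <- file.path(root, key)
    dir.create(d, showWarnings = FALSE)
    png::writePNG(pixels_to_unit(data$pixels[[i]]),
                  file.path(d, sprintf("img_%04d.png", counter[key])))
  }
  lab <- unique(data.frame(class_index = data$class_index,
                           moisture = data$moisture))
  lab <- lab[order(lab$class_index), ]
  write.csv(lab, file.path(root, "labels.csv"), row.names = FALSE)
  invisible(root)
}

pixels_to_unit <- function(px) {
  if (is.double(px) && max(px) <= 1) return(px)
  px <- px / 255
  px
}

unit_to_pixels <- function(arr) {
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE] # drop alpha
  px <- round(arr * 255)
  storage.mode(px) <- "integer"
  px
}

#' List a class-per-directory image tree
#'
#' Scans `root/<class_index>/*.png` and joins each file with its class's
#' moisture label from `root/labels.csv`. Images are not decoded; use
#' [read_leaf_dataset()] for pixels.
#'
#' @param root Dataset directory containing class subdirectories and
#'   `labels.csv`.
#' @return A tibble with `path`, `class_index`, `moisture`, one row per image.
#' @export
dataset_manifest <- function(root) {
  if (!dir.exists(root)) abort(sprintf("No such dataset directory: %s", root))
  lab_path <- file.path(root, "labels.csv")
  if (!file.exists(lab_path)) abort("Dataset is missing labels.csv.")
  lab <- read.csv(lab_path)
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[grepl("^[0-9]+$", basename(dirs))]
  if (length(dirs) == 0L) abort("Dataset has no class directories.")
  rows <- lapply(dirs, function(d) {
    files <- list.files(d, pattern = "\\.(png|PNG)$", full.names = TRUE)
    if (length(files) == 0L) {
      abort(sprintf("Class directory %s contains no PNG images.", d))
    }
    ci <- as.integer(basename(d))
    m <- lab$moisture[match(ci, lab$class_index)]
    if (is.na(m)) abort(sprintf("Class %d has no entry in labels.csv.", ci))
    tibble(path = files, class_index = ci, moisture = m)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$class_index, .data$path)
}

#' Read a leaf dataset from disk
#'
#' Decodes every image in a [dataset_manifest()] tree into the in-memory
#' sample format used throughout the package.
#'
#' @inheritParams dataset_manifest
#' @return A sample tibble with `class_index`, `moisture`,
#'   `provenance = "external"`, `pixels` and `path` columns.
#' @export
read_leaf_dataset <- function(root) {
  man <- dataset_manifest(root)
  px <- lapply(man$path, function(p) unit_to_pixels(png::readPNG(p)))
  tibble(class_index = man$class_index, moisture = man$moisture,
         provenance = "external", pixels = px, path = man$path)
}

#' Split a pool of samples into training and validation sets
#'
#' Shuffles the pool with a fixed seed and assigns `floor((1 - ratio_train) *
#' N)` samples to validation and the remainder to training — the floor rule on
#' the validation share (so a pool of 556 at 9:1 gives 501 training and 55
#' validation samples). With `stratify = TRUE` the floor rule is applied
#' within each class instead of to the whole pool.
#'
#' @param data Sample or manifest tibble (any columns; `class_index` required
#'   only when `stratify = TRUE`).
#' @param ratio_train Training share in (0, 1), default 0.9.
#' @param seed Integer seed for the shuffle.
#' @param stratify Apply the split per class (default `FALSE`).
#' @return A list with tibbles `train` and `validation`: a disjoint,
#'   exhaustive partition of `data`'s rows.
#' @export
#' @examples
#' d <- tibble::tibble(id = 1:10)
#' split_train_validation(d, 0.9, seed = 1)
split_train_validation <- function(data, ratio_train = 0.9, seed = 1L,
                                   stratify = FALSE) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) abort("Cannot split an empty sample pool.")
  if (!(ratio_train > 0 && ratio_train < 1)) {
    abort("`ratio_train` must be strictly between 0 and 1.")
  }
  pick_validation <- function(n) {
    # tiny epsilon guards the floor against binary representation of the
    # ratio (0.1 * 10 must give 1 validation sample, not 0)
    n_val <- floor((1 - ratio_train) * n + 1e-9)
    idx <- sample.int(n)
    idx[seq_len(n_val)]
  }
  with_seed(seed, {
    if (stratify) {
      if (!"class_index" %in% names(data)) {
        abort("`stratify = TRUE` needs a `class_index` column.")
      }
      val_rows <- unlist(lapply(split(seq_len(nrow(data)), data$class_index),
                                function(rows) rows[pick_validation(length(rows))]),
                         use.names = FALSE)
    } else {
      val_rows <- pick_validation(nrow(data))
    }
    val <- sort(val_rows)
    list(train = as_tibble(data[setdiff(seq_len(nrow(data)), val), , drop = FALSE]),
         validation = as_tibble(data[val, , drop = FALSE]))
  })
}
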