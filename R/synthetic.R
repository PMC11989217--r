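#' Configuration for the synthetic withering-leaf generator
#'
#' Describes a synthetic dataset of leaf-like RGB images whose appearance
#' responds deterministically (plus noise) to moisture content: as moisture
#' falls the leaf interior darkens from fresh green toward dark olive, the
#' leaf mask shrinks, and the interior mottling coarsens — the qualitative
#' changes a withering fresh leaf shows over consecutive hourly time points.
#'
#' @param n_classes Number of withering time-point classes (default 13).
#' @param moisture_labels Strictly decreasing moisture fractions in (0,1), one
#'   per class. Default [default_moisture_labels()] for `n_classes`.
#' @param images_per_class Images generated per class (>= 1).
#' @param image_size Square image side in pixels (>= 32, default 64).
#' @param seed Integer seed; one seed drives every stochastic draw so a given
#'   config is byte-reproducible.
#' @param noise_sd Additive Gaussian pixel noise, in 0-255 intensity units.
#' @param darkening_gain Unitless gain on how strongly the interior green
#'   channel darkens over the full moisture range (1 = about 70 intensity
#'   units from wettest to driest class).
#' @param shrink_gain Unitless gain on leaf-mask shrinkage over the full
#'   moisture range (0.25 = the driest leaf's axes are 25% shorter).
#' @return A `tea_synth_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, images_per_class = 2)
synthetic_config <- function(n_classes = 13L,
                             moisture_labels = NULL,
                             images_per_class = 10L,
                             image_size = 64L,
                             seed = 1L,
                             noise_sd = 8,
                             darkening_gain = 1,
                             shrink_gain = 0.25) {
  n_classes <- as.integer(n_classes)
  images_per_class <- as.integer(images_per_class)
  image_size <- as.integer(image_size)
  if (is.na(n_classes) || n_classes < 2L) abort("`n_classes` must be >= 2.")
  if (is.na(images_per_class) || images_per_class < 1L) {
    abort("`images_per_class` must be >= 1.")
  }
  if (is.na(image_size) || image_size < 32L) abort("`image_size` must be >= 32.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (darkening_gain <= 0 || shrink_gain < 0 || shrink_gain >= 1) {
    abort("`darkening_gain` must be positive and `shrink_gain` in [0, 1).")
  }
  moisture_labels <- moisture_labels %||% default_moisture_labels(n_classes)
  moisture_labels <- as.numeric(moisture_labels)
  if (length(moisture_labels) != n_classes) {
    abort("`moisture_labels` must have one entry per class.")
  }
  if (any(!is.finite(moisture_labels)) ||
      any(moisture_labels <= 0) || any(moisture_labels >= 1)) {
    abort("Moisture labels must be fractions in (0, 1).")
  }
  if (any(diff(moisture_labels) >= 0)) {
    abort("Moisture labels must be strictly decreasing with class index.")
  }
  structure(
    list(n_classes = n_classes, moisture_labels = moisture_labels,
         images_per_class = images_per_class, image_size = image_size,
         seed = as.integer(seed), noise_sd = noise_sd,
         darkening_gain = darkening_gain, shrink_gain = shrink_gain),
    class = "tea_synth_config"
  )
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic withering-leaf dataset
#'
#' Renders `images_per_class` leaf images for each withering class in the
#' config. Each image is a superellipse leaf mask with a ragged edge on a
#' dark neutral background (an acquisition tray darker than any leaf, so both
#' darkening and shrinkage lower the whole-image brightness monotonically);
#' the interior base colour interpolates from fresh
#' green toward dark olive as moisture falls, low-frequency mottling grows
#' with withering (texture coarsening), and additive Gaussian pixel noise is
#' clipped to \[0, 255\]. Class-mean interior green intensity is strictly
#' decreasing, and class-mean mask area non-increasing, with class index.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with one row per image: `class_index` (0-based),
#'   `moisture`, `provenance` (`"synthetic"`), `pixels` (H x W x 3 integer
#'   array list-column, 0-255) and `mask` (logical matrix list-column marking
#'   leaf-interior pixels).
#' @export
#' @examples
#' d <- generate_leaf_images(synthetic_config(seed = 1, images_per_class = 1))
#' dplyr::count(d, class_index)
generate_leaf_images <- function(cfg) {
  if (!inherits(cfg, "tea_synth_config")) {
    abort("`cfg` must come from synthetic_config().")
  }
  m <- cfg$moisture_labels
  wither <- (max(m) - m) / (max(m) - min(m)) # 0 = wettest class, 1 = driest
  with_seed(cfg$seed, {
    rows <- vector("list", cfg$n_classes * cfg$images_per_class)
    k <- 0L
    for (ci in seq_len(cfg$n_classes)) {
      for (j in seq_len(cfg$images_per_class)) {
        img <- render_leaf(cfg$image_size, wither[ci], cfg$noise_sd,
                           cfg$darkening_gain, cfg$shrink_gain)
        k <- k + 1L
        rows[[k]] <- tibble(
          class_index = ci - 1L, moisture = m[ci], provenance = "synthetic",
          pixels = list(img$pixels), mask = list(img$mask)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

# Render one leaf image at withering level w in [0, 1].
render_leaf <- function(size, w, noise_sd, darkening_gain, shrink_gain) {
  # centred coordinates in [-1, 1]
  u <- seq(-1, 1, length.out = size)
  X <- matrix(rep(u, each = size), nrow = size)   # column coordinate
  Y <- matrix(rep(u, times = size), nrow = size)  # row coordinate
  theta <- runif(1, -pi / 6, pi / 6)              # leaf orientation
  Xr <- cos(theta) * X + sin(theta) * Y
  Yr <- -sin(theta) * X + cos(theta) * Y
  s <- 1 - shrink_gain * w
  a <- 0.72 * s
  b <- 0.42 * s
  p <- 2.5                                        # superellipse exponent
  r <- (abs(Xr / a))^p + (abs(Yr / b))^p
  # ragged edge: smooth zero-mean jitter on the boundary radius, small enough
  # that the deterministic shrinkage dominates class-mean areas
  edge <- upsample_field(matrix(rnorm(64, sd = 0.02), 8, 8), size)
  edge <- edge - mean(edge)
  mask <- r <= 1 + edge

  # interior base colour: fresh green -> dark olive as w rises
  g_drop <- 70 * darkening_gain * w
  base <- c(72 + 20 * w, 165 - g_drop, 58 - 10 * w)
  # mottling: low-frequency multiplicative field, coarser/stronger when drier;
  # demeaned inside the mask so it never shifts the interior mean colour
  amp <- 0.04 + 0.10 * w
  grid_n <- max(3L, 9L - as.integer(round(5 * w)))
  mottle <- upsample_field(matrix(rnorm(grid_n^2), grid_n, grid_n), size)
  mottle <- 1 + amp * (mottle - mean(mottle[mask]))

  px <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) {
    plane <- matrix(25, size, size)  # dark neutral tray, darker than any leaf
    plane[mask] <- (base[ch] * mottle)[mask]
    plane <- plane + matrix(rnorm(size * size, sd = noise_sd), size, size)
    px[, , ch] <- pmin(pmax(round(plane), 0), 255)
  }
  storage.mode(px) <- "integer"
  list(pixels = px, mask = mask)
}

# Bilinear upsampling of a small square field to size x size (internal).
upsample_field <- function(f, size) {
  n <- nrow(f)
  xi <- seq(1, n, length.out = size)
  i0 <- pmin(floor(xi), n - 1L)
  t <- xi - i0
  # interpolate rows then columns
  fr <- f[i0, , drop = FALSE] * (1 - t) + f[i0 + 1L, , drop = FALSE] * t
  fr[, i0, drop = FALSE] * rep(1 - t, each = size) +
    fr[, i0 + 1L, drop = FALSE] * rep(t, each = size)
}

#' Hold out whole withering classes as an external test set
#'
#' Splits a sample table into training classes and external (held-out)
#' classes. Holding out whole time points — rather than random images — tests
#' whether the confidence-weighted model can interpolate moisture values it
#' never saw as labels.
#'
#' @param data A sample tibble with a `class_index` column.
#' @param held_classes Integer class indices to hold out (may be empty).
#' @return A list with tibbles `train` and `external`; every row of `data`
#'   appears in exactly one of them.
#' @export
#' @examples
#' d <- generate_leaf_images(synthetic_config(seed = 1, images_per_class = 1))
#' sp <- holdout_split(d, c(1, 5, 9))
holdout_split <- function(data, held_classes) {
  stopifnot(is.data.frame(data), "class_index" %in% names(data))
  held_classes <- as.integer(held_classes)
  unknown <- setdiff(held_classes, unique(data$class_index))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown class index: %s", paste(unknown, collapse = ", ")))
  }
  ext <- data$class_index %in% held_classes
  list(train = as_tibble(data[!ext, , drop = FALSE]),
       external = as_tibble(data[ext, , drop = FALSE]))
}
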