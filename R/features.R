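#' Classical colour and texture features of a leaf image
#'
#' Computes the nine colour metrics and six first-order grayscale texture
#' features used by chemometric moisture baselines (PLS / shallow CNN on
#' tabular features):
#'
#' Colour (on 0-255 RGB): `mean_R`, `mean_G`, `mean_B`; `color_angle` — the
#' hue angle (degrees) of the *mean* RGB vector; `mean_saturation` and
#' `mean_luminance` — per-pixel HSV saturation and value averaged over the
#' image (\[0, 1\]); `super_green` — the vegetation index 2G - R - B of the
#' channel means; `rg_ratio` — mean R over mean G (`NA` when mean G is 0);
#' `mean_hue` — per-pixel HSV hue averaged in degrees (hue of achromatic
#' pixels taken as 0).
#'
#' Texture (first-order statistics of the ITU-R BT.601 luma `0.299 R +
#' 0.587 G + 0.114 B`, quantized to 256 bins): `gray_mean`, `gray_sd`
#' (population SD, 0-255 units); `smoothness` `1 - 1/(1 + sigma^2)` with sigma
#' on \[0, 1\]-normalized gray; `third_moment` — the skewness-like third
#' central moment on normalized gray; `uniformity` — histogram energy
#' `sum(p^2)`; `entropy` — Shannon entropy `-sum(p log2 p)` in bits (0 to 8
#' for 256 bins).
#'
#' All 15 are orderless statistics, hence invariant to flips and other pixel
#' permutations.
#'
#' @param px H x W x 3 integer pixel array (0-255).
#' @return A named list of 15 numeric features.
#' @seealso [image_features()] for the table-level interface.
#' @export
#' @examples
#' px <- array(128L, dim = c(8, 8, 3))
#' extract_features(px)$uniformity  # 1: constant image
extract_features <- function(px) {
  check_pixels(px)
  r <- as.numeric(px[, , 1]); g <- as.numeric(px[, , 2]); b <- as.numeric(px[, , 3])
  mean_r <- mean(r); mean_g <- mean(g); mean_b <- mean(b)

  hsv <- rgb_to_hsv01(r / 255, g / 255, b / 255)

  gray <- 0.299 * r + 0.587 * g + 0.114 * b
  bins <- pmin(pmax(round(gray), 0), 255)
  p <- tabulate(bins + 1L, nbins = 256L) / length(bins)
  z <- (0:255) / 255
  m1 <- sum(z * p)
  sigma2 <- sum((z - m1)^2 * p)
  nz <- p > 0

  list(
    mean_R = mean_r, mean_G = mean_g, mean_B = mean_b,
    color_angle = hue_angle(mean_r, mean_g, mean_b),
    mean_saturation = mean(hsv$s),
    mean_luminance = mean(hsv$v),
    super_green = 2 * mean_g - mean_r - mean_b,
    rg_ratio = if (mean_g > 0) mean_r / mean_g else NA_real_,
    mean_hue = mean(hsv$h),
    gray_mean = mean(gray),
    gray_sd = sqrt(mean((gray - mean(gray))^2)),
    smoothness = 1 - 1 / (1 + sigma2),
    third_moment = sum((z - m1)^3 * p),
    uniformity = sum(p^2),
    entropy = -sum(p[nz] * log2(p[nz]))
  )
}

# Vectorized RGB (in [0,1]) -> HSV with hue in degrees; achromatic hue = 0.
rgb_to_hsv01 <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  i <- d > 0 & mx == r
  h[i] <- 60 * (((g[i] - b[i]) / d[i]) %% 6)
  i <- d > 0 & mx == g & !(mx == r)
  h[i] <- 60 * ((b[i] - r[i]) / d[i] + 2)
  i <- d > 0 & mx == b & !(mx == r) & !(mx == g)
  h[i] <- 60 * ((r[i] - g[i]) / d[i] + 4)
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, v = mx)
}

hue_angle <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  if (d == 0) return(0)
  h <- if (mx == r) ((g - b) / d) %% 6
       else if (mx == g) (b - r) / d + 2
       else (r - g) / d + 4
  60 * h
}

#' Feature table for a set of leaf samples
#'
#' Applies [extract_features()] to every image in a sample tibble and returns
#' one row per image with the 15 feature columns appended to the sample
#' metadata — the tabular input the classical baseline regressions consume.
#'
#' @param data Sample tibble with a `pixels` list-column.
#' @return A tibble: the non-pixel sample columns plus 15 feature columns.
#' @export
#' @examples
#' d <- generate_leaf_images(synthetic_config(seed = 1, images_per_class = 1))
#' image_features(d)
image_features <- function(data) {
  stopifnot(is.data.frame(data), "pixels" %in% names(data))
  feats <- purrr::map(data$pixels, extract_features)
  meta <- data[setdiff(names(data), c("pixels", "mask"))]
  dplyr::bind_cols(as_tibble(meta),
                   dplyr::bind_rows(lapply(feats, as_tibble)))
}
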