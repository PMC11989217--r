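#' @name image-ops
#' @title Elementary image transforms
#'
#' @description Deterministic single-image transforms used by
#' [augment_images()]. All operate on H x W x 3 integer arrays (0-255) and
#' clip results back to that range.
#'
#' * `img_flip()` mirrors the image horizontally (left-right) or vertically.
#' * `img_rotate()` rotates counter-clockwise; exact multiples of 90 degrees
#'   are pure index permutations (a 90 degree turn of a H x W image yields
#'   W x H content), other angles use bilinear interpolation on an enlarged
#'   canvas.
#' * `img_crop()` extracts a window; it errors if the window exceeds the
#'   image.
#' * `img_brightness()` multiplies intensities by `factor` and clips.
#' * `img_resize()` resizes to a square side with bilinear interpolation.
#'
#' @param px H x W x 3 integer pixel array (0-255).
#' @param direction `"horizontal"` or `"vertical"`.
#' @param degrees Rotation angle, counter-clockwise.
#' @param top,left 1-based corner of the crop window.
#' @param height,width Crop window size in pixels.
#' @param factor Multiplicative brightness factor (> 0).
#' @param size Output side length in pixels.
#' @param fill Background intensity (0-255) revealed by rotation.
#' @return A pixel array of the same kind.
NULL

#' @rdname image-ops
#' @export
img_flip <- function(px, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  check_pixels(px)
  if (direction == "horizontal") px[, dim(px)[2]:1, , drop = FALSE]
  else px[dim(px)[1]:1, , , drop = FALSE]
}

#' @rdname image-ops
#' @export
img_rotate <- function(px, degrees, fill = 0L) {
  check_pixels(px)
  degrees <- degrees %% 360
  if (degrees %% 90 == 0) {
    k <- (degrees / 90) %% 4
    out <- px
    for (i in seq_len(k)) out <- rot90_ccw(out)
    return(out)
  }
  img <- EBImage::Image(aperm(px, c(2, 1, 3)) / 255, colormode = "Color")
  rot <- EBImage::rotate(img, angle = -degrees, filter = "bilinear",
                         bg.col = fill / 255)
  arr <- pmin(pmax(as.array(rot), 0), 1)
  unit_to_pixels(aperm(arr, c(2, 1, 3)))
}

# 90 degree counter-clockwise index permutation: out[W+1-j, i] = in[i, j]
rot90_ccw <- function(px) {
  w <- dim(px)[2]
  out <- aperm(px, c(2, 1, 3))
  out[w:1, , , drop = FALSE]
}

#' @rdname image-ops
#' @export
img_crop <- function(px, top, left, height, width) {
  check_pixels(px)
  d <- dim(px)
  if (top < 1 || left < 1 || height < 1 || width < 1 ||
      top + height - 1 > d[1] || left + width - 1 > d[2]) {
    abort(sprintf("Crop window %dx%d at (%d, %d) exceeds a %dx%d image.",
                  height, width, top, left, d[1], d[2]))
  }
  px[top:(top + height - 1), left:(left + width - 1), , drop = FALSE]
}

#' @rdname image-ops
#' @export
img_brightness <- function(px, factor) {
  check_pixels(px)
  if (!is.finite(factor) || factor <= 0) abort("`factor` must be positive.")
  out <- pmin(pmax(round(px * factor), 0), 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname image-ops
#' @export
img_resize <- function(px, size) {
  check_pixels(px)
  if (dim(px)[1] == size && dim(px)[2] == size) return(px)
  img <- EBImage::Image(aperm(px, c(2, 1, 3)) / 255, colormode = "Color")
  res <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
  arr <- pmin(pmax(as.array(res), 0), 1)
  unit_to_pixels(aperm(arr, c(2, 1, 3)))
}

check_pixels <- function(px) {
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] != 3L) {
    abort("Pixels must be an H x W x 3 array.")
  }
  if (dim(px)[1] < 1L || dim(px)[2] < 1L) abort("Zero-sized image.")
  invisible(TRUE)
}

#' Augment a sample table with crop / rotate / flip / brightness variants
#'
#' For every input image and every requested operation, draws the operation's
#' parameters at random (under a fixed seed), applies it, and resizes the
#' result back to `out_size`. Class index and moisture label are inherited
#' unchanged; provenance becomes `"augmented"`. With `per_image = k` each
#' image receives `k` independent draws of every operation, so the output has
#' `nrow(data) * k * length(ops)` rows.
#'
#' @param data Sample tibble with `pixels`, `class_index`, `moisture`.
#' @param ops Character subset of `c("crop", "rotate", "flip", "brightness")`;
#'   at least one.
#' @param per_image Augmented copies per image per operation.
#' @param seed Integer seed.
#' @param out_size Output side length; default the input image's height.
#' @param crop_range Crop side as a fraction of the original, drawn uniformly.
#' @param angle_range Rotation angle bounds in degrees.
#' @param brightness_range Brightness factor bounds.
#' @return A sample tibble of augmented images.
#' @export
augment_images <- function(data,
                           ops = c("crop", "rotate", "flip", "brightness"),
                           per_image = 1L, seed = 1L, out_size = NULL,
                           crop_range = c(0.7, 1), angle_range = c(-30, 30),
                           brightness_range = c(0.8, 1.2)) {
  stopifnot(is.data.frame(data),
            all(c("pixels", "class_index", "moisture") %in% names(data)))
  ops <- match.arg(ops, several.ok = TRUE)
  if (length(ops) == 0L) abort("Request at least one augmentation op.")
  if (any(crop_range <= 0) || any(crop_range > 1) || crop_range[1] > crop_range[2]) {
    abort("`crop_range` must be increasing fractions in (0, 1].")
  }
  if (any(brightness_range <= 0)) abort("`brightness_range` must be positive.")
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(data))) {
      px <- data$pixels[[i]]
      size <- out_size %||% dim(px)[1]
      for (rep in seq_len(per_image)) {
        for (op in ops) {
          aug <- switch(op,
            crop = {
              f <- runif(1, crop_range[1], crop_range[2])
              h <- max(1L, as.integer(round(f * dim(px)[1])))
              w <- max(1L, as.integer(round(f * dim(px)[2])))
              top <- sample.int(dim(px)[1] - h + 1L, 1L)
              left <- sample.int(dim(px)[2] - w + 1L, 1L)
              img_crop(px, top, left, h, w)
            },
            rotate = img_rotate(px, runif(1, angle_range[1], angle_range[2])),
            flip = img_flip(px, sample(c("horizontal", "vertical"), 1L)),
            brightness = img_brightness(
              px, runif(1, brightness_range[1], brightness_range[2]))
          )
          rows[[length(rows) + 1L]] <- tibble(
            class_index = data$class_index[i], moisture = data$moisture[i],
            provenance = "augmented", pixels = list(img_resize(aug, size))
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
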