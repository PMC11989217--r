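test_that("flips are involutions and identity parameters leave pixels untouched", {
  px <- random_pixels(7, 5, seed = 2)
  expect_identical(img_flip(img_flip(px, "horizontal"), "horizontal"), px)
  expect_identical(img_flip(img_flip(px, "vertical"), "vertical"), px)
  expect_identical(img_brightness(px, 1.0), px)
  expect_identical(img_rotate(px, 0), px)
  expect_identical(img_rotate(px, 360), px)
  expect_identical(img_crop(px, 1, 1, 7, 5), px)
})

test_that("90-degree rotation is the expected index permutation", {
  px <- random_pixels(6, 4, seed = 3)
  r <- img_rotate(px, 90)
  expect_equal(dim(r), c(4L, 6L, 3L))
  # coordinate-permutation oracle: out[W+1-j, i] = in[i, j]
  for (i in seq_len(6)) for (j in seq_len(4)) for (ch in 1:3) {
    expect_identical(r[4 + 1 - j, i, ch], px[i, j, ch])
  }
  # four quarter turns restore the original
  expect_identical(img_rotate(img_rotate(img_rotate(img_rotate(px, 90), 90), 90), 90),
                   px)
  expect_identical(img_rotate(px, -90), img_rotate(px, 270))
})

test_that("arbitrary-angle rotation stays in range and roughly agrees with the permutation path", {
  px <- random_pixels(16, 16, seed = 4)
  r <- img_rotate(px, 33)
  expect_true(min(r) >= 0 && max(r) <= 255)
  expect_true(is.integer(r))
  # bilinear path at 90 degrees must match the exact permutation orientation
  rb <- img_rotate(px, 90.000001)
  rp <- img_rotate(px, 90)
  # compare central crop (interpolated canvas can differ by a border pixel)
  cb <- img_crop(rb, 5, 5, 8, 8)
  cp <- img_crop(rp, 5, 5, 8, 8)
  expect_lt(mean(abs(cb - cp)), 3)
})

test_that("crop validates its window", {
  px <- random_pixels(6, 6)
  expect_error(img_crop(px, 1, 1, 7, 3), "exceeds")
  expect_error(img_crop(px, 4, 4, 4, 4), "exceeds")
  expect_equal(dim(img_crop(px, 2, 3, 4, 2)), c(4L, 2L, 3L))
})

test_that("brightness is multiplicative with clipping", {
  px <- random_pixels(5, 5, seed = 6)
  b <- img_brightness(px, 2)
  expect_identical(b, {
    e <- pmin(pmax(round(px * 2), 0), 255); storage.mode(e) <- "integer"; e
  })
  expect_true(max(img_brightness(px, 100)) == 255)
  expect_error(img_brightness(px, 0), "positive")
})

test_that("augment_images inherits labels, marks provenance, and is seed-deterministic", {
  d <- tiny_dataset()[c(1, 9), ]
  aug <- augment_images(d, ops = c("crop", "rotate", "flip", "brightness"),
                        per_image = 2, seed = 5)
  expect_equal(nrow(aug), 2 * 2 * 4)
  expect_true(all(aug$provenance == "augmented"))
  expect_setequal(unique(aug$class_index), d$class_index)
  # labels ride along unchanged
  for (ci in unique(aug$class_index)) {
    expect_equal(unique(aug$moisture[aug$class_index == ci]),
                 d$moisture[d$class_index == ci])
  }
  # resized back to the input resolution, clipped to [0, 255]
  for (px in aug$pixels) {
    expect_equal(dim(px), dim(d$pixels[[1]]))
    expect_true(min(px) >= 0 && max(px) <= 255)
  }
  aug2 <- augment_images(d, ops = c("crop", "rotate", "flip", "brightness"),
                         per_image = 2, seed = 5)
  expect_identical(aug$pixels, aug2$pixels)
  expect_error(augment_images(d, ops = character(0)), "arg")
})
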