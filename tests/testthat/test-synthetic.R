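test_that("generator produces the configured number of samples with exact labels", {
  cfg <- synthetic_config(seed = 1, n_classes = 13, images_per_class = 3,
                          image_size = 32)
  d <- generate_leaf_images(cfg)
  expect_equal(nrow(d), 13 * 3)
  expect_equal(as.integer(table(d$class_index)), rep(3L, 13))
  # label fidelity: every sample's moisture equals its class's table entry
  expect_identical(d$moisture, cfg$moisture_labels[d$class_index + 1L])
  expect_true(all(d$provenance == "synthetic"))
  for (px in d$pixels) {
    expect_true(is.integer(px) && min(px) >= 0 && max(px) <= 255)
    expect_equal(dim(px), c(32L, 32L, 3L))
  }
})

test_that("identical configs produce byte-identical datasets", {
  cfg <- synthetic_config(seed = 42, n_classes = 5,
                          moisture_labels = c(0.78, 0.7, 0.65, 0.6, 0.5),
                          images_per_class = 2, image_size = 32)
  d1 <- generate_leaf_images(cfg)
  d2 <- generate_leaf_images(cfg)
  expect_identical(d1$pixels, d2$pixels)
  expect_identical(d1$mask, d2$mask)
  # and the generator does not disturb the caller's RNG stream
  set.seed(5); a <- rnorm(3)
  set.seed(5); invisible(generate_leaf_images(cfg)); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("class-mean interior green darkens and mask area shrinks with withering", {
  d <- generate_leaf_images(synthetic_config(seed = 1, images_per_class = 8,
                                             image_size = 48))
  # independent pixel-loop oracle for the interior channel mean
  green_loop <- function(px, mask) {
    tot <- 0; n <- 0
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) { tot <- tot + px[i, j, 2]; n <- n + 1 }
    }
    tot / n
  }
  g <- class_mean_loop(d, green_loop)
  expect_true(all(diff(g) < 0))
  area <- class_mean_loop(d, function(px, mask) sum(mask))
  expect_true(all(diff(area) <= 0))
})

test_that("invalid generator configs are rejected", {
  expect_error(synthetic_config(image_size = 16), "image_size")
  expect_error(synthetic_config(images_per_class = 0), "images_per_class")
  expect_error(synthetic_config(n_classes = 3,
                                moisture_labels = c(0.7, 0.75, 0.6)),
               "decreasing")
  expect_error(synthetic_config(n_classes = 2, moisture_labels = c(1.2, 0.5)),
               "fraction")
  expect_error(synthetic_config(n_classes = 3, moisture_labels = c(0.7, 0.6)),
               "one entry per class")
  expect_error(generate_leaf_images(list()), "synthetic_config")
})

test_that("13-class default labels embed the 10 reference labels at the 1/5/9 holdout", {
  full <- default_moisture_labels(13)
  expect_true(all(diff(full) < 0))
  expect_equal(full[-c(2, 6, 10)], reference_moisture_labels()$moisture)
  # the held-out labels are the midpoints of their neighbours
  expect_equal(full[2], (full[1] + full[3]) / 2)
  expect_equal(full[6], (full[5] + full[7]) / 2)
  expect_equal(full[10], (full[9] + full[11]) / 2)
  expect_equal(default_moisture_labels(10),
               reference_moisture_labels()$moisture)
})

test_that("holdout_split partitions by class exactly", {
  d <- generate_leaf_images(synthetic_config(seed = 3, n_classes = 13,
                                             images_per_class = 2,
                                             image_size = 32))
  sp <- holdout_split(d, c(1, 5, 9))
  expect_setequal(unique(sp$external$class_index), c(1, 5, 9))
  expect_equal(length(unique(sp$train$class_index)), 10)
  expect_equal(nrow(sp$train) + nrow(sp$external), nrow(d))

  # empty holdout: everything trains
  sp0 <- holdout_split(d, integer(0))
  expect_equal(nrow(sp0$external), 0)
  expect_equal(nrow(sp0$train), nrow(d))

  # set-difference oracle on a small pool: 3 classes x 5 images, hold {0}
  d3 <- tibble::tibble(class_index = rep(0:2, each = 5), id = 1:15)
  sp3 <- holdout_split(d3, 0L)
  expect_equal(nrow(sp3$external), 5)
  expect_equal(nrow(sp3$train), 10)
  expect_setequal(c(sp3$train$id, sp3$external$id), d3$id)
  expect_length(intersect(sp3$train$id, sp3$external$id), 0)

  expect_error(holdout_split(d3, 7L), "Unknown class")
})
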