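ref_labels <- function() reference_moisture_labels()$moisture

test_that("confidence weighting reduces to the label for one-hot and the mean for uniform confidence", {
  y <- ref_labels()
  onehot <- replace(numeric(10), 4, 1)
  expect_equal(predict_moisture(onehot, y), 0.7501)

  unif <- rep(0.1, 10)
  # independent dot-product oracle
  acc <- 0
  for (i in 1:10) acc <- acc + y[i] * 0.1
  expect_equal(predict_moisture(unif, y, decimals = NULL), acc,
               tolerance = 1e-15)
  expect_equal(predict_moisture(unif, y), round(mean(y), 8))

  # a data-frame label table works identically
  expect_equal(predict_moisture(onehot, reference_moisture_labels()), 0.7501)
})

test_that("rounding convention: confidences are rounded, never renormalized", {
  y <- ref_labels()
  conf <- c(0.918881421, 0.081092349, 0.000026191, 0.000000011, rep(0, 6))
  # decimals = 8 rounds each confidence first
  expect_equal(predict_moisture(conf, y, decimals = 8),
               round(sum(y * round(conf, 8)), 8))
  # full precision keeps the raw dot product
  expect_equal(predict_moisture(conf, y, decimals = NULL), sum(y * conf))
})

test_that("predictions are convex combinations of the labels", {
  y <- ref_labels()
  set.seed(41)
  for (i in 1:25) {
    w <- rexp(10); w <- w / sum(w)
    p <- predict_moisture(w, y, decimals = NULL)
    expect_gte(p, min(y))
    expect_lte(p, max(y))
  }
})

test_that("shifting confidence mass toward a wetter class never lowers the prediction", {
  y <- ref_labels()
  set.seed(42)
  for (i in 1:25) {
    w <- rexp(10); w <- w / sum(w)
    from <- sample(2:10, 1)        # drier class
    to <- sample(seq_len(from - 1), 1)  # wetter class (lower index)
    eps <- runif(1, 0, w[from])
    w2 <- w
    w2[from] <- w2[from] - eps
    w2[to] <- w2[to] + eps
    expect_gte(predict_moisture(w2, y, decimals = NULL),
               predict_moisture(w, y, decimals = NULL))
  }
})

test_that("malformed confidence vectors and label tables are rejected", {
  y <- ref_labels()
  expect_error(predict_moisture(rep(0.2, 5), y), "5 classes")
  expect_error(predict_moisture(c(-0.1, 1.1, rep(0, 8)), y), "non-negative")
  expect_error(predict_moisture(rep(0.2, 10), y), "sum")
  expect_error(predict_moisture(rep(0.1, 10), c(rev(y))), "decreasing")
  expect_error(predict_moisture(rep(0.1, 10), c(y[-10], 1.5)), "fraction")
})

test_that("withering degree follows the 58-66% band with inclusive edges", {
  expect_equal(as.character(assess_withering(0.62)), "moderate")
  expect_equal(as.character(assess_withering(0.66)), "moderate")
  expect_equal(as.character(assess_withering(0.6600001)), "insufficient")
  expect_equal(as.character(assess_withering(0.58)), "moderate")
  expect_equal(as.character(assess_withering(0.5799999)), "excessive")
  # the category-9 true value sits inside the band
  expect_equal(as.character(assess_withering(0.597)), "moderate")
  expect_equal(as.character(assess_withering(0.7843)), "insufficient")
  expect_error(assess_withering(1.2), "0, 1")
  expect_error(assess_withering(-0.1), "0, 1")
})

test_that("assess_samples preserves row order and echoes softmax confidences", {
  d <- tiny_dataset()[c(1, 9, 17, 25, 2, 10), ]
  plan <- architecture_plan(4, width_multiplier = 1 / 16,
                            depth_multiplier = 1 / 3, image_size = 64)
  model <- build_classifier(plan, seed = 8)
  labs <- c(0.78, 0.70, 0.62, 0.50)
  a <- assess_samples(d, model, labels = labs)
  expect_equal(nrow(a), 6)
  expect_identical(a$class_index, d$class_index)
  for (cv in a$confidences) {
    expect_equal(sum(cv), 1, tolerance = 1e-6)
    expect_true(all(cv >= 0))
  }
  expect_true(all(a$predicted_moisture >= min(labs) &
                    a$predicted_moisture <= max(labs)))
  expect_identical(a$degree, assess_withering(a$predicted_moisture))

  # permutation oracle: shuffling input rows shuffles outputs identically
  perm <- c(4, 1, 6, 2, 5, 3)
  a_perm <- assess_samples(d[perm, ], model, labels = labs)
  expect_equal(a_perm$predicted_moisture, a$predicted_moisture[perm])
})
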