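test_that("RFAConv attention is a softmax over receptive-field positions", {
  set.seed(31)
  m <- rfaconv_block(8, 8, k = 3, stride = 1)
  x <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  out <- nn_forward(m, x, training = TRUE)
  expect_equal(dim(out), c(16L, 16L, 8L, 2L))

  # independent exponent-and-normalize oracle from the cached logits
  logits <- m$cache$logits          # (Ho, Wo, k2, C, N)
  attn <- m$cache$attn
  e <- exp(logits)
  sums <- apply(e, c(1, 2, 4, 5), sum)
  for (j in 1:9) {
    expect_equal(attn[, , j, , ], e[, , j, , ] / sums, tolerance = 1e-9)
  }
  per_pos <- apply(attn, c(1, 2, 4, 5), sum)
  expect_true(max(abs(per_pos - 1)) < 1e-6)
  expect_true(all(attn >= 0))
})

test_that("a spatially constant input receives uniform 1/k^2 attention", {
  set.seed(32)
  m <- rfaconv_block(4, 4, k = 3)
  x <- array(rep(c(0.3, -1, 2, 0), each = 8 * 8), c(8, 8, 4, 1))
  invisible(nn_forward(m, x, training = TRUE))
  # interior positions see a constant pooled field (borders are zero-padded)
  attn_int <- m$cache$attn[3:6, 3:6, , , ]
  expect_equal(max(abs(attn_int - 1 / 9)), 0, tolerance = 1e-12)
})

test_that("blocks satisfy their spatial shape contracts on randomized shapes", {
  set.seed(33)
  for (rep in 1:5) {
    H <- sample(7:14, 1); W <- sample(7:14, 1)
    cin <- sample(2:5, 1); cout <- sample(2:6, 1)
    stride <- sample(1:2, 1)
    m <- rfaconv_block(cin, cout, k = 3, stride = stride)
    out <- nn_forward(m, array(rnorm(H * W * cin * 2), c(H, W, cin, 2)),
                      training = TRUE)
    expect_equal(dim(out),
                 c((H + 2L - 3L) %/% stride + 1L, (W + 2L - 3L) %/% stride + 1L,
                   cout, 2L))

    C <- sample(c(4L, 6L, 8L), 1)
    ca <- coord_attention_block(C)
    xin <- array(rnorm(H * W * C * 2), c(H, W, C, 2))
    expect_equal(dim(nn_forward(ca, xin, training = TRUE)), dim(xin))

    ch2 <- 2L * sample(2:4, 1)
    c2 <- c2f_ca_block(C, ch2, repeats = sample(1:2, 1))
    expect_equal(dim(nn_forward(c2, xin, training = TRUE)),
                 c(H, W, ch2, 2L))
  }
  expect_error(c2f_ca_block(4, 7), "even")
})

test_that("coordinate attention gates behave at their analytic limits", {
  set.seed(34)
  C <- 6
  x <- array(rnorm(5 * 4 * C * 2), c(5, 4, C, 2))
  m <- coord_attention_block(C, reduction = 2)

  # directional pooled descriptors equal per-element loop means
  invisible(nn_forward(m, x, training = TRUE))
  mh <- m$cache$mh
  for (h in 1:5) for (c in 1:C) for (n in 1:2) {
    s <- 0
    for (w in 1:4) s <- s + x[h, w, c, n]
    expect_equal(mh[h, c, n], s / 4, tolerance = 1e-12)
  }

  # zeroed gate convolutions -> sigmoid(0) = 0.5 gates -> x / 4
  m$children$conv_h$params$W[] <- 0
  m$children$conv_h$params$b[] <- 0
  m$children$conv_w$params$W[] <- 0
  m$children$conv_w$params$b[] <- 0
  expect_equal(nn_forward(m, x, training = TRUE), x / 4, tolerance = 1e-12)

  # saturated biases -> gates -> 1 -> identity map
  m$children$conv_h$params$b[] <- 40
  m$children$conv_w$params$b[] <- 40
  expect_equal(nn_forward(m, x, training = TRUE), x, tolerance = 1e-6)
})

test_that("C2f parameter count grows strictly with repeats and stays finite on zero input", {
  p1 <- n_parameters(c2f_ca_block(8, 16, repeats = 1))
  p3 <- n_parameters(c2f_ca_block(8, 16, repeats = 3))
  expect_gt(p3, p1)
  m <- c2f_ca_block(8, 16, repeats = 2)
  out <- nn_forward(m, array(0, c(8, 8, 8, 2)), training = TRUE)
  expect_true(all(is.finite(out)))
})

test_that("block backward passes agree with finite differences", {
  expect_lt(gradcheck_module(function() rfaconv_block(3, 4, 3, stride = 2),
                             c(8, 8, 3, 2), nparam = 3), 1e-4)
  expect_lt(gradcheck_module(function() coord_attention_block(6, 2),
                             c(5, 4, 6, 2), nparam = 4), 1e-4)
  expect_lt(gradcheck_module(function() c2f_ca_block(6, 8, repeats = 1),
                             c(6, 6, 6, 2), nparam = 3), 1e-4)
})

test_that("the default plan mirrors the published backbone and the head softmax normalizes", {
  plan <- architecture_plan()
  expect_equal(nrow(plan$stages), 9)
  expect_equal(plan$stages$kind,
               c("RFAConv", "RFAConv", "C2f_CA", "RFAConv", "C2f_CA",
                 "RFAConv", "C2f_CA", "RFAConv", "C2f_CA"))
  expect_equal(plan$stages$channels, c(64, 128, 128, 256, 256, 512, 512, 1024, 1024))
  expect_equal(plan$stages$repeats_scaled[plan$stages$kind == "C2f_CA"],
               c(3L, 6L, 6L, 3L))
  expect_equal(plan$n_classes, 10L)

  mini <- mini_profile_plan(10)
  expect_equal(mini$stages$channels, c(4, 8, 8, 16, 16, 32, 32, 64, 64))
  model <- build_classifier(mini, seed = 5)
  d <- tiny_dataset()[c(1, 9, 17, 25), ]
  # head contract: softmax confidences, non-negative, unit sum
  conf <- predict(model, d)
  expect_equal(dim(conf), c(4L, 10L))
  expect_true(all(conf >= 0))
  expect_true(max(abs(rowSums(conf) - 1)) < 1e-6)

  # deterministic: same seed, same input, same confidences
  model2 <- build_classifier(mini, seed = 5)
  conf2 <- predict(model2, d)
  expect_identical(conf, conf2)
})
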