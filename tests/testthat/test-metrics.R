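test_that("rmsep matches its closed forms and a summation oracle", {
  expect_equal(rmsep(c(0.6, 0.7), c(0.6, 0.7)), 0)
  expect_equal(rmsep(0.6, 0.7), 0.1)

  set.seed(51)
  y <- runif(5); e <- runif(5)
  acc <- 0
  for (i in 1:5) acc <- acc + (y[i] - e[i])^2
  expect_equal(rmsep(y, e), sqrt(acc / 5), tolerance = 1e-12)

  # permutation invariance and scale covariance
  p <- sample(5)
  expect_equal(rmsep(y[p], e[p]), rmsep(y, e), tolerance = 1e-15)
  expect_equal(rmsep(3 * y, 3 * e), 3 * rmsep(y, e), tolerance = 1e-12)

  expect_error(rmsep(numeric(0), numeric(0)), "empty")
  expect_error(rmsep(c(1, 2), 1), "equal length")
})

test_that("reference SD is the sample standard deviation of the label list", {
  expect_equal(reference_sd(c(0.5, 0.5, 0.5)), 0)
  expect_equal(reference_sd(c(0, 1)), sqrt(0.5))

  # two-pass oracle on the ten reference labels
  y <- reference_moisture_labels()$moisture
  m <- sum(y) / 10
  ss <- 0
  for (v in y) ss <- ss + (v - m)^2
  expect_equal(reference_sd(y), sqrt(ss / 9), tolerance = 1e-14)
  expect_error(reference_sd(0.5), "two")
})

test_that("RPD is SD over RMSEP with the chemometric quality bands", {
  # construct SD = 0.2 (two-point reference) and RMSEP = 0.1
  ref <- c(0.5 - 0.2 / sqrt(2), 0.5 + 0.2 / sqrt(2))
  r <- rpd(0.6, 0.7, ref)
  expect_equal(as.numeric(r), 2, tolerance = 1e-12)
  # halving the error doubles RPD
  r2 <- rpd(0.6, 0.65, ref)
  expect_equal(as.numeric(r2), 4, tolerance = 1e-12)
  expect_equal(attr(r2, "band"), "good")
  expect_equal(attr(rpd(0.6, 0.75, ref), "band"), "average")
  expect_equal(attr(rpd(0.6, 0.95, ref), "band"), "unusable")
  # exact predictions: flagged infinite, not an error
  r0 <- rpd(c(0.6, 0.7), c(0.6, 0.7), ref)
  expect_true(is.infinite(r0))
  expect_true(attr(r0, "degenerate"))
})

test_that("Rp equals 1 exactly for perfect prediction and matches a term-by-term oracle", {
  y <- reference_moisture_labels()$moisture
  expect_equal(rp(y, y, y), 1)

  set.seed(52)
  truth <- runif(10, 0.4, 0.8)
  est <- truth + rnorm(10, sd = 0.02)
  ybar <- mean(y)
  num <- 0; den_printed <- 0; den_text <- 0
  for (i in 1:10) {
    num <- num + (est[i] - truth[i])^2
    den_printed <- den_printed + (est[i] - ybar)^2
    den_text <- den_text + (truth[i] - ybar)^2
  }
  expect_equal(rp(truth, est, y), 1 - num / den_printed, tolerance = 1e-12)
  expect_equal(rp(truth, est, y, convention = "textbook"),
               1 - num / den_text, tolerance = 1e-12)
  # imperfect predictions always sit strictly below 1
  expect_lt(rp(truth, est, y), 1)

  # degenerate: estimates constant at the reference mean
  expect_error(rp(truth, rep(ybar, 10), y), "zero")
})

test_that("the report ties the metrics together: RPD x RMSEP = SD", {
  set.seed(53)
  d <- tibble::tibble(
    truth = runif(12, 0.45, 0.8),
    est = runif(12, 0.45, 0.8),
    grp = rep(1:3, each = 4)
  )
  rep_all <- moisture_metrics(d, truth, est)
  expect_equal(rep_all$RPD * rep_all$RMSEP, rep_all$SD, tolerance = 1e-10)
  expect_equal(rep_all$SD, reference_sd(reference_moisture_labels()$moisture))
  expect_equal(rep_all$n, 12L)

  by_grp <- moisture_metrics(d, truth, est, group = grp)
  expect_equal(nrow(by_grp), 3)
  expect_equal(by_grp$n, rep(4L, 3))
  expect_equal(by_grp$RPD * by_grp$RMSEP, by_grp$SD, tolerance = 1e-10)

  # custom reference labels flow through to ybar and SD
  ref <- c(0.9, 0.7, 0.5)
  rep_ref <- moisture_metrics(d, truth, est, reference_labels = ref)
  expect_equal(rep_ref$SD, sd(ref))
})
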