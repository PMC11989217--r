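# Shared fixtures and oracles, built in code at test time.

# small 4-class synthetic dataset, memoised per session
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_classes = 4,
                              moisture_labels = c(0.78, 0.70, 0.62, 0.50),
                              images_per_class = 8, image_size = 64, seed = 7)
      cache <<- generate_leaf_images(cfg)
    }
    cache
  }
})

random_pixels <- function(h = 6, w = 5, seed = 1) {
  set.seed(seed)
  px <- array(sample.int(256, h * w * 3, replace = TRUE) - 1L, c(h, w, 3))
  storage.mode(px) <- "integer"
  px
}

# brute-force 2-D convolution oracle (zero padding), one (cout, position)
# at a time; W rows follow the package layout: c * k^2 + kc * k + kr.
naive_conv2d <- function(x, W, b, k, stride, pad, groups = 1L) {
  d <- dim(x)
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  cout <- nrow(W)
  cing <- d[3] %/% groups
  coutg <- cout %/% groups
  out <- array(0, c(Ho, Wo, cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(cout)) {
    g <- (co - 1) %/% coutg
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- b[co]
      for (ci in seq_len(cing)) {
        c_abs <- g * cing + ci
        for (kc in seq_len(k)) for (kr in seq_len(k)) {
          h <- (ho - 1) * stride - pad + kr
          w <- (wo - 1) * stride - pad + kc
          if (h >= 1 && h <= d[1] && w >= 1 && w <= d[2]) {
            acc <- acc + x[h, w, c_abs, n] *
              W[co, (ci - 1) * k * k + (kc - 1) * k + kr]
          }
        }
      }
      out[ho, wo, co, n] <- acc
    }
  }
  out
}

# finite-difference gradient check of a module; returns max relative error
# over a few sampled input coordinates and the first `nparam` parameters
gradcheck_module <- function(make, dims, nparam = 2, eps = 1e-5, seed = 11) {
  set.seed(seed)
  m <- make()
  x <- array(rnorm(prod(dims)), dims)
  out <- m$fwd(x, train = TRUE)
  R <- array(rnorm(length(out)), dim = dim(out))
  loss <- function(xx) sum(m$fwd(xx, train = TRUE) * R)
  invisible(m$fwd(x, TRUE))
  teawither:::zero_grads(m)
  dx <- m$bwd(R)
  worst <- 0
  idx <- sample(length(x), min(6, length(x)))
  num <- vapply(idx, function(i) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    (loss(x1) - loss(x2)) / (2 * eps)
  }, numeric(1))
  worst <- max(worst, abs(num - dx[idx]) / pmax(abs(num), 1e-3))
  ps <- utils::head(teawither:::collect_params(m), nparam)
  for (p in ps) {
    invisible(m$fwd(x, TRUE))
    teawither:::zero_grads(m)
    m$bwd(R)
    g <- p$env$grads[[p$name]]
    w <- p$env$params[[p$name]]
    i <- sample(length(w), min(4, length(w)))
    num <- vapply(i, function(j) {
      w1 <- w
      w1[j] <- w1[j] + eps; p$env$params[[p$name]] <- w1
      l1 <- loss(x)
      w1[j] <- w1[j] - 2 * eps; p$env$params[[p$name]] <- w1
      l2 <- loss(x)
      p$env$params[[p$name]] <- w
      (l1 - l2) / (2 * eps)
    }, numeric(1))
    worst <- max(worst, abs(num - g[i]) / pmax(abs(num), 1e-3))
  }
  worst
}

# class means of a per-image statistic, via an explicit pixel loop (oracle)
class_mean_loop <- function(data, stat) {
  vapply(split(seq_len(nrow(data)), data$class_index), function(ix) {
    mean(vapply(ix, function(i) stat(data$pixels[[i]], data$mask[[i]]),
                numeric(1)))
  }, numeric(1))
}
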