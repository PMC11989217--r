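# Minimal reverse-mode module system for the network blocks.
#
# A module is an environment with:
#   $params / $grads  named lists of numeric arrays (leaf modules)
#   $decay            named logical: which params receive weight decay
#   $children         sub-modules (walked recursively for parameters)
#   $fwd(x, train)    forward pass, caching what backward needs
#   $bwd(dout)        backward pass: accumulates $grads, returns d(input)
# Tensors are (H, W, C, N) double arrays; classifier outputs are (K, N)
# matrices. All randomness in initialization comes from the caller's RNG.

new_module <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- list()
  e$grads <- list()
  e$decay <- logical(0)
  e$children <- list()
  e$cache <- NULL
  class(e) <- "tea_module"
  e
}

#' @export
print.tea_module <- function(x, ...) {
  cat("<tea_module:", x$kind, "- ", n_parameters(x), "parameters>\n")
  invisible(x)
}

out_hw <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# channel-major matrix view (C x H*W*N) and back
to_cmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])
}
from_cmat <- function(m, H, W, N) {
  aperm(array(m, c(nrow(m), H, W, N)), c(2, 3, 1, 4))
}

## ---- convolution -----------------------------------------------------------

# weight layout: (cout) x (k*k*cin_per_group); rows blocked by group.
# init = "he" (ReLU-family fan-in) or "shared" (identical weights across the
# k*k receptive-field positions of each group -- used by the RFA attention
# branch so an untrained layer attends uniformly).
mod_conv2d <- function(cin, cout, k, stride = 1L, pad = k %/% 2L,
                       groups = 1L, bias = TRUE, init = "he") {
  if (cin %% groups != 0L || cout %% groups != 0L) {
    abort("Channel counts must be divisible by `groups`.")
  }
  m <- new_module(sprintf("conv%dx%d", k, k))
  m$cin <- cin; m$cout <- cout; m$k <- as.integer(k)
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$groups <- as.integer(groups)
  cing <- cin %/% groups
  fanin <- k * k * cing
  W <- matrix(rnorm(cout * fanin, sd = sqrt(2 / fanin)), cout, fanin)
  if (init == "shared") {
    coutg <- cout %/% groups
    for (g in seq_len(groups)) {
      v <- rnorm(fanin, sd = 0.1)
      for (r in seq_len(coutg)) W[(g - 1L) * coutg + r, ] <- v
    }
  }
  m$params <- list(W = W)
  m$decay <- c(W = TRUE)
  if (bias) {
    m$params$b <- numeric(cout)
    m$decay <- c(m$decay, b = FALSE)
  }
  m$grads <- lapply(m$params, function(p) array(0, dim = dim(p) %||% length(p)))

  m$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    stopifnot(d[3] == cin)
    if (m$k == 1L && m$groups == 1L && m$stride == 1L) {
      xm <- to_cmat(x)
      m$cache <- list(xm = xm, d = d, fast = TRUE)
      om <- m$params$W %*% xm
      if (bias) om <- om + m$params$b
      return(from_cmat(om, d[1], d[2], d[4]))
    }
    cols <- cpp_im2col(as.numeric(x), as.integer(d), m$k, m$stride, m$pad)
    Ho <- out_hw(d[1], m$k, m$stride, m$pad)
    Wo <- out_hw(d[2], m$k, m$stride, m$pad)
    m$cache <- list(cols = cols, d = d, Ho = Ho, Wo = Wo, fast = FALSE)
    om <- matrix(0, cout, ncol(cols))
    k2g <- m$k * m$k * cing
    coutg <- cout %/% m$groups
    for (g in seq_len(m$groups)) {
      ri <- ((g - 1L) * k2g + 1L):(g * k2g)
      ro <- ((g - 1L) * coutg + 1L):(g * coutg)
      om[ro, ] <- m$params$W[ro, , drop = FALSE] %*% cols[ri, , drop = FALSE]
    }
    if (bias) om <- om + m$params$b
    aperm(array(om, c(cout, Ho, Wo, d[4])), c(2, 3, 1, 4))
  }

  m$bwd <- function(dout) {
    cc <- m$cache
    dm <- to_cmat(dout)
    if (bias) m$grads$b <- m$grads$b + rowSums(dm)
    if (isTRUE(cc$fast)) {
      m$grads$W <- m$grads$W + dm %*% t(cc$xm)
      dxm <- t(m$params$W) %*% dm
      return(from_cmat(dxm, cc$d[1], cc$d[2], cc$d[4]))
    }
    dcols <- matrix(0, nrow(cc$cols), ncol(cc$cols))
    k2g <- m$k * m$k * cing
    coutg <- cout %/% m$groups
    for (g in seq_len(m$groups)) {
      ri <- ((g - 1L) * k2g + 1L):(g * k2g)
      ro <- ((g - 1L) * coutg + 1L):(g * coutg)
      dg <- dm[ro, , drop = FALSE]
      m$grads$W[ro, ] <- m$grads$W[ro, , drop = FALSE] +
        dg %*% t(cc$cols[ri, , drop = FALSE])
      dcols[ri, ] <- t(m$params$W[ro, , drop = FALSE]) %*% dg
    }
    array(cpp_col2im(dcols, as.integer(cc$d), m$k, m$stride, m$pad),
          dim = cc$d)
  }
  m
}

## ---- batch normalization ---------------------------------------------------

mod_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  m <- new_module("batchnorm")
  m$params <- list(gamma = rep(1, C), beta = rep(0, C))
  m$decay <- c(gamma = FALSE, beta = FALSE)
  m$grads <- list(gamma = numeric(C), beta = numeric(C))
  m$running_mean <- numeric(C)
  m$running_var <- rep(1, C)

  # reshape to (H*W) x (C*N) so no aperm is needed; column j belongs to
  # channel (j - 1) %% C + 1
  m$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    HW <- d[1] * d[2]; N <- d[4]
    xm <- matrix(x, nrow = HW)
    if (train) {
      mu_cn <- .colMeans(xm, HW, C * N)
      mu <- .rowMeans(matrix(mu_cn, C, N), C, N)
      xc <- xm - rep(rep(mu, N), each = HW)
      v_cn <- .colMeans(xc * xc, HW, C * N)
      v <- .rowMeans(matrix(v_cn, C, N), C, N)
      m$running_mean <- (1 - momentum) * m$running_mean + momentum * mu
      m$running_var <- (1 - momentum) * m$running_var + momentum * v
    } else {
      mu <- m$running_mean
      v <- m$running_var
      xc <- xm - rep(rep(mu, N), each = HW)
    }
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * rep(rep(invstd, N), each = HW)
    om <- xhat * rep(rep(m$params$gamma, N), each = HW) +
      rep(rep(m$params$beta, N), each = HW)
    m$cache <- list(xhat = xhat, invstd = invstd, d = d, train = train)
    array(om, d)
  }

  m$bwd <- function(dout) {
    cc <- m$cache
    d <- cc$d
    HW <- d[1] * d[2]; N <- d[4]
    dm <- matrix(dout, nrow = HW)
    per_ch <- function(mat) {  # sum over H, W and N for each channel
      .rowSums(matrix(.colSums(mat, HW, C * N), C, N), C, N)
    }
    m$grads$beta <- m$grads$beta + per_ch(dm)
    m$grads$gamma <- m$grads$gamma + per_ch(dm * cc$xhat)
    dxhat <- dm * rep(rep(m$params$gamma, N), each = HW)
    if (cc$train) {
      M <- HW * N
      s1 <- per_ch(dxhat)
      s2 <- per_ch(dxhat * cc$xhat)
      dxm <- (dxhat - rep(rep(s1 / M, N), each = HW) -
                cc$xhat * rep(rep(s2 / M, N), each = HW)) *
        rep(rep(cc$invstd, N), each = HW)
    } else {
      dxm <- dxhat * rep(rep(cc$invstd, N), each = HW)
    }
    array(dxm, d)
  }
  m
}

## ---- activations -----------------------------------------------------------

mod_act <- function(type = c("silu", "relu", "sigmoid")) {
  type <- match.arg(type)
  m <- new_module(type)
  m$fwd <- function(x, train = FALSE) {
    out <- switch(type,
      silu = { s <- 1 / (1 + exp(-x)); x * s },
      relu = pmax(x, 0),
      sigmoid = 1 / (1 + exp(-x))
    )
    m$cache <- list(x = if (type != "sigmoid") x else NULL,
                    out = if (type == "sigmoid") out else NULL)
    out
  }
  m$bwd <- function(dout) {
    switch(type,
      silu = {
        s <- 1 / (1 + exp(-m$cache$x))
        dout * (s * (1 + m$cache$x * (1 - s)))
      },
      relu = dout * (m$cache$x > 0),
      sigmoid = dout * m$cache$out * (1 - m$cache$out)
    )
  }
  m
}

## ---- pooling ---------------------------------------------------------------

# k x k average pooling (stride / pad as in the attention branch of RFAConv)
mod_avgpool <- function(k, stride = 1L, pad = k %/% 2L) {
  m <- new_module("avgpool")
  k <- as.integer(k); stride <- as.integer(stride); pad <- as.integer(pad)
  m$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    cols <- cpp_im2col(as.numeric(x), as.integer(d), k, stride, pad)
    k2 <- k * k
    a <- array(cols, c(k2, d[3] * ncol(cols)))  # (k2, C*M)
    pooled <- colMeans(a)                       # length C * M
    Ho <- out_hw(d[1], k, stride, pad)
    Wo <- out_hw(d[2], k, stride, pad)
    m$cache <- list(d = d, M = ncol(cols))
    pm <- matrix(pooled, d[3], ncol(cols))
    aperm(array(pm, c(d[3], Ho, Wo, d[4])), c(2, 3, 1, 4))
  }
  m$bwd <- function(dout) {
    cc <- m$cache
    dpm <- to_cmat(dout)                        # C x M
    k2 <- k * k
    dcols <- dpm[rep(seq_len(cc$d[3]), each = k2), , drop = FALSE] / k2
    array(cpp_col2im(dcols, as.integer(cc$d), k, stride, pad), dim = cc$d)
  }
  m
}

# global average pooling (H,W,C,N) -> (C,N)
mod_gap <- function() {
  m <- new_module("gap")
  m$fwd <- function(x, train = FALSE) {
    m$cache <- list(d = dim(x))
    colMeans(x, dims = 2)
  }
  m$bwd <- function(dout) {
    d <- m$cache$d
    array(rep(as.numeric(dout) / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  }
  m
}

## ---- linear ----------------------------------------------------------------

mod_linear <- function(nin, nout) {
  m <- new_module("linear")
  m$params <- list(W = matrix(rnorm(nout * nin, sd = sqrt(1 / nin)), nout, nin),
                   b = numeric(nout))
  m$decay <- c(W = TRUE, b = FALSE)
  m$grads <- list(W = matrix(0, nout, nin), b = numeric(nout))
  m$fwd <- function(x, train = FALSE) {   # x: (nin, N)
    m$cache <- list(x = x)
    m$params$W %*% x + m$params$b
  }
  m$bwd <- function(dout) {
    m$grads$W <- m$grads$W + dout %*% t(m$cache$x)
    m$grads$b <- m$grads$b + rowSums(dout)
    t(m$params$W) %*% dout
  }
  m
}

## ---- composition -----------------------------------------------------------

mod_sequential <- function(..., kind = "sequential") {
  m <- new_module(kind)
  m$children <- list(...)
  m$fwd <- function(x, train = FALSE) {
    for (ch in m$children) x <- ch$fwd(x, train)
    x
  }
  m$bwd <- function(dout) {
    for (ch in rev(m$children)) dout <- ch$bwd(dout)
    dout
  }
  m
}

# Conv + BN + SiLU, the standard composite block
mod_cbs <- function(cin, cout, k, stride = 1L) {
  mod_sequential(mod_conv2d(cin, cout, k, stride, bias = FALSE),
                 mod_bn(cout), mod_act("silu"), kind = "conv_bn_silu")
}

## ---- parameter walking -----------------------------------------------------

# list of list(env = module, name = param name, decay = flag)
collect_params <- function(mod) {
  out <- list()
  if (length(mod$params) > 0) {
    for (nm in names(mod$params)) {
      out[[length(out) + 1L]] <- list(env = mod, name = nm,
                                      decay = isTRUE(mod$decay[[nm]]))
    }
  }
  for (ch in mod$children) out <- c(out, collect_params(ch))
  out
}

zero_grads <- function(mod) {
  for (nm in names(mod$grads)) mod$grads[[nm]][] <- 0
  for (ch in mod$children) zero_grads(ch)
  invisible(NULL)
}

#' Number of trainable parameters in a module or classifier
#'
#' @param x A network module or a classifier from [build_classifier()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(x) {
  if (inherits(x, "tea_classifier")) x <- x$net
  sum(vapply(collect_params(x),
             function(p) length(p$env$params[[p$name]]), numeric(1)))
}
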