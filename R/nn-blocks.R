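# The model's building blocks. Shapes follow the (H, W, C, N) convention of
# nn-core.R; every block preserves the spatial contract documented on its
# constructor.

# softmax over the k2 receptive-field positions; a5 has dims (Ho,Wo,k2,C,N)
softmax_k2 <- function(a5) {
  d <- dim(a5)
  b <- aperm(a5, c(3, 1, 2, 4, 5))
  bm <- matrix(b, nrow = d[3])
  mx <- do.call(pmax, lapply(seq_len(d[3]), function(j) bm[j, ]))
  e <- exp(bm - rep(mx, each = d[3]))
  s <- colSums(e)
  am <- e / rep(s, each = d[3])
  aperm(array(am, dim(b)), c(2, 3, 1, 4, 5))
}

softmax_k2_bwd <- function(attn5, dattn5) {
  d <- dim(attn5)
  a <- matrix(aperm(attn5, c(3, 1, 2, 4, 5)), nrow = d[3])
  g <- matrix(aperm(dattn5, c(3, 1, 2, 4, 5)), nrow = d[3])
  dl <- a * (g - rep(colSums(a * g), each = d[3]))
  aperm(array(dl, c(d[3], d[1], d[2], d[4], d[5])), c(2, 3, 1, 4, 5))
}

#' Receptive-field attention convolution (RFAConv)
#'
#' A convolution whose k x k receptive-field positions are re-weighted by a
#' learned softmax attention before the spatial reduction, relieving the
#' parameter sharing of a plain convolution. The forward pass computes
#' `softmax(g1x1(avgpool(X)))` — k^2 non-negative weights per output location
#' and channel that sum to 1 — times `relu(batchnorm(gkxk(X)))`, the grouped
#' (per-channel) receptive-field expansion; the weighted features are
#' rearranged into non-overlapping k x k tiles and reduced by a stride-k
#' convolution (+ BN + SiLU), so the output spatial size equals that of a
#' standard stride-`stride` convolution.
#'
#' The attention 1 x 1 grouped convolution is initialized with identical
#' weights across the k^2 positions, so an untrained block attends uniformly
#' (1/k^2 everywhere); training breaks the symmetry.
#'
#' @param cin,cout Input/output channel counts.
#' @param k Receptive-field (kernel) size.
#' @param stride Output stride (1 or 2 in the backbone).
#' @return A network module; run it with [nn_forward()]. After a forward pass
#'   `module$cache$attn` holds the attention map with dims
#'   `(Ho, Wo, k^2, cin, N)`.
#' @export
rfaconv_block <- function(cin, cout, k = 3L, stride = 1L) {
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be >= 1.")
  m <- new_module("rfaconv")
  m$k <- k; m$cin <- cin; m$cout <- cout; m$stride <- as.integer(stride)
  k2 <- k * k
  pool <- mod_avgpool(k, stride, k %/% 2L)
  attn_conv <- mod_conv2d(cin, cin * k2, 1L, stride = 1L, pad = 0L,
                          groups = cin, bias = FALSE, init = "shared")
  feat_conv <- mod_conv2d(cin, cin * k2, k, stride = stride, pad = k %/% 2L,
                          groups = cin, bias = FALSE)
  feat_bn <- mod_bn(cin * k2)
  feat_act <- mod_act("relu")
  reduce <- mod_cbs(cin, cout, k, stride = k)
  m$children <- list(pool = pool, attn_conv = attn_conv, feat_conv = feat_conv,
                     feat_bn = feat_bn, feat_act = feat_act, reduce = reduce)

  m$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    if (d[1] < k || d[2] < k) abort("Input spatial dims must be >= k.")
    logits <- attn_conv$fwd(pool$fwd(x, train), train)      # (Ho,Wo,C*k2,N)
    do <- dim(logits)
    l5 <- array(logits, c(do[1], do[2], k2, cin, do[4]))
    attn <- softmax_k2(l5)
    feats <- feat_act$fwd(feat_bn$fwd(feat_conv$fwd(x, train), train), train)
    f5 <- array(feats, c(do[1], do[2], k2, cin, do[4]))
    wf <- attn * f5
    # (Ho,Wo,k2,C,N) -> (k*Ho, k*Wo, C, N): j = (kc)*k + kr, kr fastest
    w6 <- array(wf, c(do[1], do[2], k, k, cin, do[4]))
    tiles <- array(aperm(w6, c(3, 1, 4, 2, 5, 6)),
                   c(k * do[1], k * do[2], cin, do[4]))
    m$cache <- list(attn = attn, logits = l5, f5 = f5, do = do)
    reduce$fwd(tiles, train)
  }

  m$bwd <- function(dout) {
    cc <- m$cache
    do <- cc$do
    dtiles <- reduce$bwd(dout)
    d6 <- array(dtiles, c(k, do[1], k, do[2], cin, do[4]))
    dwf <- array(aperm(d6, c(2, 4, 1, 3, 5, 6)),
                 c(do[1], do[2], k2, cin, do[4]))
    dattn <- dwf * cc$f5
    dfeats <- dwf * cc$attn
    dlog5 <- softmax_k2_bwd(cc$attn, dattn)
    dx1 <- pool$bwd(attn_conv$bwd(array(dlog5, do)))
    df <- feat_conv$bwd(feat_bn$bwd(feat_act$bwd(array(dfeats, do))))
    dx1 + df
  }
  m
}

#' Coordinate attention block
#'
#' Channel attention factorized along the two spatial directions: the input is
#' average-pooled along width (one descriptor per row) and along height (one
#' per column); the concatenated descriptors pass through a shared 1 x 1
#' bottleneck (BN + SiLU) and two direction-specific 1 x 1 convolutions with
#' sigmoid gates in (0, 1). The output is `x * g_h * g_w`, broadcast over the
#' opposite direction, so shape is preserved; with both final convolutions
#' zeroed the gates are 0.5 and the block returns `x / 4`, and in the
#' saturated-bias limit it is the identity.
#'
#' @param C Channel count.
#' @param reduction Integer channel-reduction divisor for the bottleneck
#'   (intermediate channels `max(2, C %/% reduction)`).
#' @return A network module for [nn_forward()]. After a forward pass
#'   `module$cache$gh` / `$gw` hold the directional gates.
#' @export
coord_attention_block <- function(C, reduction = 8L) {
  cm <- max(2L, C %/% as.integer(reduction))
  m <- new_module("coord_attention")
  conv1 <- mod_conv2d(C, cm, 1L, bias = TRUE)
  bn1 <- mod_bn(cm)
  act1 <- mod_act("silu")
  conv_h <- mod_conv2d(cm, C, 1L, bias = TRUE)
  conv_w <- mod_conv2d(cm, C, 1L, bias = TRUE)
  sig_h <- mod_act("sigmoid")
  sig_w <- mod_act("sigmoid")
  m$children <- list(conv1 = conv1, bn1 = bn1, act1 = act1,
                     conv_h = conv_h, conv_w = conv_w,
                     sig_h = sig_h, sig_w = sig_w)

  bc_h <- function(x, gh) {                 # multiply by (H,1,C,N) along W
    aperm(aperm(x, c(1, 3, 4, 2)) * as.numeric(gh), c(1, 4, 2, 3))
  }
  bc_w <- function(x, gw) {                 # multiply by (1,W,C,N) along H
    aperm(aperm(x, c(2, 3, 4, 1)) * as.numeric(gw), c(4, 1, 2, 3))
  }

  m$fwd <- function(x, train = FALSE) {
    d <- dim(x)
    H <- d[1]; W <- d[2]
    mh <- colMeans(aperm(x, c(2, 1, 3, 4)))  # (H,C,N): mean over width
    mw <- colMeans(x)                        # (W,C,N): mean over height
    y <- array(0, c(H + W, 1L, d[3], d[4]))
    y[seq_len(H), 1L, , ] <- mh
    y[H + seq_len(W), 1L, , ] <- mw
    t0 <- act1$fwd(bn1$fwd(conv1$fwd(y, train), train), train)
    th <- t0[seq_len(H), , , , drop = FALSE]
    tw <- t0[H + seq_len(W), , , , drop = FALSE]
    gh <- sig_h$fwd(conv_h$fwd(th, train), train)   # (H,1,C,N)
    gw <- sig_w$fwd(conv_w$fwd(tw, train), train)   # (W,1,C,N)
    xh <- bc_h(x, gh)
    out <- bc_w(xh, gw)
    m$cache <- list(x = x, gh = gh, gw = gw, d = d, mh = mh, mw = mw)
    out
  }

  m$bwd <- function(dout) {
    cc <- m$cache
    d <- cc$d
    H <- d[1]; W <- d[2]
    gh <- cc$gh; gw <- cc$gw
    x_gh <- bc_h(cc$x, gh)
    dx <- bc_w(bc_h(dout, gh), gw)
    # gate gradients: sum the product rule over the broadcast direction
    dgw <- colSums(dout * x_gh)                       # (W,C,N)
    x_gw <- bc_w(cc$x, gw)
    dgh <- colSums(aperm(dout * x_gw, c(2, 1, 3, 4))) # (H,C,N)
    dth <- conv_h$bwd(sig_h$bwd(array(dgh, c(H, 1L, d[3], d[4]))))
    dtw <- conv_w$bwd(sig_w$bwd(array(dgw, c(W, 1L, d[3], d[4]))))
    dt0 <- array(0, c(H + W, 1L, dim(dth)[3], d[4]))
    dt0[seq_len(H), , , ] <- dth
    dt0[H + seq_len(W), , , ] <- dtw
    dy <- conv1$bwd(bn1$bwd(act1$bwd(dt0)))
    dmh <- array(dy[seq_len(H), 1L, , ], c(H, d[3], d[4]))
    dmw <- array(dy[H + seq_len(W), 1L, , ], c(W, d[3], d[4]))
    # spread the directional means back over the pooled axis
    dx + aperm(array(rep(as.numeric(dmh) / W, times = W),
                     c(H, d[3], d[4], W)), c(1, 4, 2, 3)) +
      aperm(array(rep(as.numeric(dmw) / H, times = H),
                  c(W, d[3], d[4], H)), c(4, 1, 2, 3))
  }
  m
}

# C2f bottleneck: two 3x3 conv+BN+SiLU with residual add
mod_bottleneck <- function(C) {
  m <- new_module("bottleneck")
  cv1 <- mod_cbs(C, C, 3L)
  cv2 <- mod_cbs(C, C, 3L)
  m$children <- list(cv1 = cv1, cv2 = cv2)
  m$fwd <- function(x, train = FALSE) x + cv2$fwd(cv1$fwd(x, train), train)
  m$bwd <- function(dout) dout + cv1$bwd(cv2$bwd(dout))
  m
}

#' Cross-stage fusion block with coordinate attention (C2f_CA)
#'
#' Standard cross-stage-partial topology: a 1 x 1 convolution expands to
#' `channels`, the result is split into two halves, `repeats` bottleneck
#' blocks are chained on the second half with every intermediate output
#' retained, all `2 + repeats` branches are concatenated and fused by a 1 x 1
#' convolution — then a [coord_attention_block()] gates the fused map.
#' Spatial dims are preserved; `channels` must be even (the split).
#'
#' @param cin Input channels.
#' @param channels Output channels (even).
#' @param repeats Number of bottleneck repeats (>= 1).
#' @param use_ca Apply the coordinate-attention gate (default `TRUE`; `FALSE`
#'   gives the plain C2f block).
#' @return A network module for [nn_forward()].
#' @export
c2f_ca_block <- function(cin, channels, repeats = 1L, use_ca = TRUE) {
  if (channels %% 2L != 0L) abort("`channels` must be even (split branch).")
  repeats <- as.integer(repeats)
  if (repeats < 1L) abort("`repeats` must be >= 1.")
  ch <- channels %/% 2L
  m <- new_module(if (use_ca) "c2f_ca" else "c2f")
  cv1 <- mod_cbs(cin, channels, 1L)
  bns <- lapply(seq_len(repeats), function(i) mod_bottleneck(ch))
  cv2 <- mod_cbs((2L + repeats) * ch, channels, 1L)
  m$children <- c(list(cv1 = cv1, cv2 = cv2), setNames(bns, paste0("b", seq_len(repeats))))
  if (use_ca) {
    ca <- coord_attention_block(channels)
    m$children$ca <- ca
  }
  m$repeats <- repeats

  m$fwd <- function(x, train = FALSE) {
    y <- cv1$fwd(x, train)
    parts <- list(y[, , seq_len(ch), , drop = FALSE],
                  y[, , ch + seq_len(ch), , drop = FALSE])
    for (i in seq_len(repeats)) {
      parts[[i + 2L]] <- bns[[i]]$fwd(parts[[i + 1L]], train)
    }
    cat_in <- array(0, c(dim(y)[1], dim(y)[2], (2L + repeats) * ch, dim(y)[4]))
    for (i in seq_along(parts)) {
      cat_in[, , (i - 1L) * ch + seq_len(ch), ] <- parts[[i]]
    }
    out <- cv2$fwd(cat_in, train)
    if (use_ca) out <- m$children$ca$fwd(out, train)
    m$cache <- list(dy = dim(y))
    out
  }

  m$bwd <- function(dout) {
    if (use_ca) dout <- m$children$ca$bwd(dout)
    dcat <- cv2$bwd(dout)
    dparts <- lapply(seq_len(2L + repeats), function(i) {
      dcat[, , (i - 1L) * ch + seq_len(ch), , drop = FALSE]
    })
    for (i in rev(seq_len(repeats))) {
      dparts[[i + 1L]] <- dparts[[i + 1L]] + bns[[i]]$bwd(dparts[[i + 2L]])
    }
    dy <- array(0, m$cache$dy)
    dy[, , seq_len(ch), ] <- dparts[[1L]]
    dy[, , ch + seq_len(ch), ] <- dparts[[2L]]
    cv1$bwd(dy)
  }
  m
}

# classification head: 1x1 conv+BN+SiLU -> global average pool -> linear
mod_classify <- function(cin, n_classes, embed) {
  m <- new_module("classify")
  conv <- mod_cbs(cin, embed, 1L)
  gap <- mod_gap()
  fc <- mod_linear(embed, n_classes)
  m$children <- list(conv = conv, gap = gap, fc = fc)
  m$fwd <- function(x, train = FALSE) {
    fc$fwd(gap$fwd(conv$fwd(x, train), train), train)
  }
  m$bwd <- function(dout) conv$bwd(gap$bwd(fc$bwd(dout)))
  m
}

#' Run a network module forward
#'
#' @param module A module from [rfaconv_block()], [coord_attention_block()],
#'   [c2f_ca_block()] or an internal composite.
#' @param x Input array with dims `(H, W, C, N)` (a single image may be
#'   supplied as `(H, W, C)` and is promoted to `N = 1`).
#' @param training Use batch statistics in the normalization layers (`TRUE`)
#'   or the running averages (`FALSE`, default).
#' @return The module output (an array, or a matrix for the classify head).
#' @export
nn_forward <- function(module, x, training = FALSE) {
  stopifnot(inherits(module, "tea_module"))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  module$fwd(x, training)
}
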