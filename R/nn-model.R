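#' Backbone/head architecture plan
#'
#' The default plan mirrors the improved classification backbone: five
#' stride-2 RFAConv stages at base widths 64/128/256/512/1024 interleaved with
#' C2f_CA fusion stages (repeats 3/6/6/3), followed by a classify head
#' (1 x 1 conv to an embedding, global average pooling, linear + softmax).
#' `width_multiplier` scales every channel count (rounded to even),
#' `depth_multiplier` scales the bottleneck repeats — how the family's small
#' variants are derived from the base plan.
#'
#' @param n_classes Output classes (default 10, the trained withering stages).
#' @param width_multiplier Channel scale factor (1 = base plan).
#' @param depth_multiplier Repeat scale factor (1 = base plan).
#' @param image_size Expected square input resolution (the base plan is
#'   trained at 224; the mini profile at 64).
#' @param k Convolution kernel size (3).
#' @return A `tea_plan` list with a `stages` tibble and scalar settings.
#' @seealso [mini_profile_plan()], [build_classifier()]
#' @export
architecture_plan <- function(n_classes = 10L, width_multiplier = 1,
                              depth_multiplier = 1, image_size = 224L,
                              k = 3L) {
  if (n_classes < 2L) abort("`n_classes` must be >= 2.")
  if (width_multiplier <= 0 || depth_multiplier <= 0) {
    abort("Multipliers must be positive.")
  }
  base <- tibble(
    stage = 1:9,
    kind = c("RFAConv", "RFAConv", "C2f_CA", "RFAConv", "C2f_CA",
             "RFAConv", "C2f_CA", "RFAConv", "C2f_CA"),
    width = c(64, 128, 128, 256, 256, 512, 512, 1024, 1024),
    repeats = c(1L, 1L, 3L, 1L, 6L, 1L, 6L, 1L, 3L),
    stride = c(2L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L)
  )
  scale_ch <- function(w) max(2L, 2L * as.integer(round(w * width_multiplier / 2)))
  base$channels <- vapply(base$width, scale_ch, integer(1))
  base$repeats_scaled <- ifelse(
    base$kind == "C2f_CA",
    pmax(1L, as.integer(round(base$repeats * depth_multiplier))), 1L)
  structure(
    list(stages = base, n_classes = as.integer(n_classes),
         width_multiplier = width_multiplier,
         depth_multiplier = depth_multiplier,
         image_size = as.integer(image_size), k = as.integer(k),
         embed = max(8L, as.integer(round(1280 * width_multiplier)))),
    class = "tea_plan"
  )
}

#' @export
print.tea_plan <- function(x, ...) {
  cat(sprintf("<tea_plan: %d backbone stages + classify head (%d classes), width x%.3g, depth x%.3g, %dpx>\n",
              nrow(x$stages), x$n_classes, x$width_multiplier,
              x$depth_multiplier, x$image_size))
  print(x$stages[, c("stage", "kind", "channels", "repeats_scaled", "stride")])
  invisible(x)
}

#' Mini training profile
#'
#' The CPU-sized variant of the base plan: width multiplier 1/16, depth
#' multiplier 1/3, 64 x 64 inputs.
#'
#' @inheritParams architecture_plan
#' @return A `tea_plan`.
#' @export
mini_profile_plan <- function(n_classes = 10L) {
  architecture_plan(n_classes, width_multiplier = 1 / 16,
                    depth_multiplier = 1 / 3, image_size = 64L)
}

#' Build the withering classifier
#'
#' Instantiates the network described by a [architecture_plan()]: the RFAConv /
#' C2f_CA backbone plus the classify head. Predictions pass through a softmax,
#' so each per-image confidence vector is non-negative and sums to 1.
#'
#' @param plan A `tea_plan`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `tea_classifier`.
#' @export
#' @examples
#' model <- build_classifier(mini_profile_plan(4), seed = 1)
#' n_parameters(model)
build_classifier <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "tea_plan"))
  with_seed(seed, {
    mods <- list()
    cin <- 3L
    for (i in seq_len(nrow(plan$stages))) {
      st <- plan$stages[i, ]
      mods[[i]] <- if (st$kind == "RFAConv") {
        rfaconv_block(cin, st$channels, k = plan$k, stride = st$stride)
      } else {
        c2f_ca_block(cin, st$channels, repeats = st$repeats_scaled)
      }
      cin <- st$channels
    }
    mods[[length(mods) + 1L]] <- mod_classify(cin, plan$n_classes, plan$embed)
    net <- mod_sequential(kind = "classifier")
    net$children <- mods
    structure(list(net = net, plan = plan, label_table = NULL,
                   class_levels = NULL, history = NULL, seed = seed),
              class = "tea_classifier")
  })
}

#' @export
print.tea_classifier <- function(x, ...) {
  cat(sprintf("<tea_classifier: %d classes, %d parameters%s>\n",
              x$plan$n_classes, n_parameters(x),
              if (is.null(x$history)) ", untrained" else
                sprintf(", trained %d epochs (final loss %.4f)",
                        nrow(x$history), x$history$loss[nrow(x$history)])))
  invisible(x)
}

# stack a list of (H,W,3) integer pixel arrays into a (H,W,3,N) [0,1] batch
stack_pixels <- function(pixels) {
  d <- dim(pixels[[1]])
  x <- array(0, c(d, length(pixels)))
  for (i in seq_along(pixels)) x[, , , i] <- pixels[[i]] / 255
  x
}

softmax_rows <- function(logits) {       # logits: (K, N) -> (K, N)
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  sweep(e, 2, colSums(e), "/")
}

#' Train the withering classifier
#'
#' Cross-entropy training with the Adam optimizer; the conventional momentum
#' setting is mapped to Adam's first-moment decay. Weight decay is applied as
#' L2 on convolution/linear weights only. One integer seed drives shuffling,
#' so a fixed (model seed, training seed) pair reproduces the run exactly.
#'
#' @param model A `tea_classifier` from [build_classifier()].
#' @param data Sample tibble with `pixels`, `class_index` and `moisture`
#'   columns; class indices need not be contiguous (held-out classes may be
#'   missing) but their count must equal the plan's `n_classes`.
#' @param epochs Training epochs (default 30, the mini profile; the base
#'   profile uses 200).
#' @param lr Learning rate (default 0.01).
#' @param batch_size Minibatch size (default 16).
#' @param momentum First-moment decay (default 0.937).
#' @param weight_decay L2 penalty on weights (default 5e-4).
#' @param seed Shuffling seed.
#' @param verbose Print per-epoch loss.
#' @return The fitted model (invisibly modified copy): `$history` holds the
#'   per-epoch mean loss and training accuracy, `$label_table` the
#'   class-index/moisture table observed in `data`.
#' @export
train_classifier <- function(model, data, epochs = 30L, lr = 0.01,
                             batch_size = 16L, momentum = 0.937,
                             weight_decay = 5e-4, seed = 1L,
                             verbose = FALSE) {
  stopifnot(inherits(model, "tea_classifier"), is.data.frame(data),
            all(c("pixels", "class_index", "moisture") %in% names(data)))
  lev <- sort(unique(data$class_index))
  K <- model$plan$n_classes
  if (length(lev) != K) {
    abort(sprintf("Data has %d classes but the plan expects %d.",
                  length(lev), K))
  }
  lab <- unique(data.frame(class_index = data$class_index,
                           moisture = data$moisture))
  lab <- lab[order(lab$class_index), ]
  if (nrow(lab) != K) abort("Each class must map to a single moisture label.")
  y <- match(data$class_index, lev)              # 1..K
  pix <- data$pixels
  n <- nrow(data)
  ps <- collect_params(model$net)
  opt <- lapply(ps, function(p) {
    w <- p$env$params[[p$name]]
    list(m = array(0, dim = dim(w) %||% length(w)),
         v = array(0, dim = dim(w) %||% length(w)))
  })
  beta1 <- momentum; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  history <- tibble(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hit <- 0L
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, n)]
        x <- stack_pixels(pix[idx])
        yb <- y[idx]
        logits <- model$net$fwd(x, train = TRUE)
        p <- softmax_rows(logits)
        B <- length(idx)
        picked <- p[cbind(yb, seq_len(B))]
        ep_loss <- ep_loss - sum(log(pmax(picked, 1e-12)))
        ep_hit <- ep_hit + sum(max.col(t(logits), ties.method = "first") == yb)
        dlogits <- p
        dlogits[cbind(yb, seq_len(B))] <- dlogits[cbind(yb, seq_len(B))] - 1
        dlogits <- dlogits / B
        zero_grads(model$net)
        model$net$bwd(dlogits)
        t_step <- t_step + 1L
        bc1 <- 1 - beta1^t_step
        bc2 <- 1 - beta2^t_step
        for (j in seq_along(ps)) {
          p_j <- ps[[j]]
          g <- p_j$env$grads[[p_j$name]]
          if (p_j$decay) g <- g + weight_decay * p_j$env$params[[p_j$name]]
          opt[[j]]$m <- beta1 * opt[[j]]$m + (1 - beta1) * g
          opt[[j]]$v <- beta2 * opt[[j]]$v + (1 - beta2) * g * g
          w_old <- p_j$env$params[[p_j$name]]
          w_new <- w_old - lr * (opt[[j]]$m / bc1) / (sqrt(opt[[j]]$v / bc2) + eps)
          attributes(w_new) <- attributes(w_old)  # keep vector params vectors
          p_j$env$params[[p_j$name]] <- w_new
        }
      }
      history <- dplyr::bind_rows(history, tibble(
        epoch = ep, loss = ep_loss / n, accuracy = ep_hit / n))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                        ep, ep_loss / n, ep_hit / n))
      }
    }
  })
  model$history <- history
  model$class_levels <- lev
  model$label_table <- tibble(class_index = lab$class_index,
                              moisture = lab$moisture)
  model
}

#' Predict class confidences for images
#'
#' @param object A `tea_classifier`.
#' @param newdata Sample tibble with a `pixels` list-column (or a single
#'   H x W x 3 array).
#' @param batch_size Forward batch size.
#' @param ... Unused.
#' @return A numeric matrix (rows = images, columns = classes, in
#'   `class_levels` order when trained) of softmax confidences; each row sums
#'   to 1 within 1e-6.
#' @export
predict.tea_classifier <- function(object, newdata, batch_size = 32L, ...) {
  pixels <- if (is.data.frame(newdata)) newdata$pixels else list(newdata)
  n <- length(pixels)
  out <- matrix(0, n, object$plan$n_classes)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    x <- stack_pixels(pixels[idx])
    out[idx, ] <- t(softmax_rows(object$net$fwd(x, train = FALSE)))
  }
  if (!is.null(object$class_levels)) {
    colnames(out) <- paste0("class_", object$class_levels)
  }
  out
}

#' Most likely class for each image (lowest index wins ties)
#'
#' @inheritParams predict.tea_classifier
#' @return Integer vector of class indices (on the training `class_index`
#'   scale when the model is trained).
#' @export
predict_class <- function(object, newdata, batch_size = 32L) {
  conf <- predict(object, newdata, batch_size = batch_size)
  pos <- max.col(conf, ties.method = "first")
  if (!is.null(object$class_levels)) object$class_levels[pos] else pos - 1L
}

#' @rdname tidy_tea
#' @export
tidy.tea_classifier <- function(x, ...) {
  if (is.null(x$history)) abort("Model is untrained; nothing to tidy.")
  x$history
}

#' Tidiers for fitted withering classifiers
#'
#' `tidy()` returns the per-epoch training trace (`epoch`, `loss`,
#' `accuracy`); `glance()` a one-row summary.
#'
#' @param x A trained `tea_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_tea
#' @export
glance.tea_classifier <- function(x, ...) {
  h <- x$history
  tibble(
    epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_accuracy = if (is.null(h)) NA_real_ else h$accuracy[nrow(h)],
    n_parameters = n_parameters(x),
    n_classes = x$plan$n_classes,
    width_multiplier = x$plan$width_multiplier
  )
}

#' Save / load a classifier checkpoint
#'
#' Checkpoints carry the architecture plan, all parameters and normalization
#' statistics, the class levels and the moisture label table, so a reloaded
#' model reproduces predictions exactly.
#'
#' @param model A `tea_classifier`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint()`: `path`, invisibly. `load_checkpoint()`: the
#'   restored `tea_classifier`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tea_classifier"))
  state <- list(plan = model$plan, params = extract_state(model$net),
                label_table = model$label_table,
                class_levels = model$class_levels,
                history = model$history, seed = model$seed)
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  model <- build_classifier(state$plan, seed = state$seed %||% 1L)
  restore_state(model$net, state$params)
  model$label_table <- state$label_table
  model$class_levels <- state$class_levels
  model$history <- state$history
  model
}

extract_state <- function(mod) {
  st <- list(params = mod$params)
  if (mod$kind == "batchnorm") {
    st$running_mean <- mod$running_mean
    st$running_var <- mod$running_var
  }
  st$children <- lapply(mod$children, extract_state)
  st
}

restore_state <- function(mod, st) {
  if (length(st$params) > 0) mod$params <- st$params
  if (!is.null(st$running_mean)) {
    mod$running_mean <- st$running_mean
    mod$running_var <- st$running_var
  }
  for (nm in seq_along(mod$children)) {
    restore_state(mod$children[[nm]], st$children[[nm]])
  }
  invisible(NULL)
}
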