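#' Depthwise-separable residual network with feature grafting
#'
#' A compact CNN for histology tiles built from residual blocks of
#' depthwise-separable convolutions (a per-channel k x k spatial
#' convolution followed by a 1 x 1 pointwise channel mix, `k*k*C + C*Ct`
#' weights instead of `k*k*C*Ct`), plus a custom *grafting* layer that
#' broadcasts a handcrafted feature vector (the GLPP descriptor) to every
#' spatial location and appends it along the channel axis. During
#' backpropagation the grafted branch is treated as a constant input: the
#' upstream gradient restricted to the convolutional channels flows on,
#' the handcrafted branch receives none. Forward/backward passes are
#' vectorised base-R array math; everything is seeded and deterministic.
#'
#' @name network
NULL

#' Network architecture specification
#'
#' @param input_size `c(H, W, channels)` of the network input (tiles are
#'   resized to this on the way in).
#' @param blocks data frame with columns `k`, `c_in`, `c_out`, `stride`;
#'   channel counts must chain (`c_in[1]` equals the input channels,
#'   `c_in[i+1] == c_out[i]`, plus `glpp_dim` after the graft point).
#' @param graft_after_block index of the block after which the handcrafted
#'   vector is grafted (0 = before the first block); default after the
#'   final block, just before pooling.
#' @param glpp_dim length of the grafted vector (0 disables grafting).
#' @param n_classes number of output classes.
#' @return a list of class `network_spec`.
#' @export
network_spec <- function(input_size = c(128, 128, 3),
                         blocks = default_blocks(input_size[3]),
                         graft_after_block = nrow(blocks),
                         glpp_dim = 0L,
                         n_classes = 5L) {
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("k", "c_in", "c_out", "stride") %in% names(blocks)),
            n_classes >= 2L, glpp_dim >= 0L,
            graft_after_block >= 0L, graft_after_block <= nrow(blocks))
  expected <- input_size[3]
  for (i in seq_len(nrow(blocks))) {
    if (i - 1L == graft_after_block) expected <- expected + glpp_dim
    if (blocks$c_in[i] != expected) {
      abort(sprintf("block %d: c_in = %d but the incoming map has %d channels",
                    i, blocks$c_in[i], expected))
    }
    expected <- blocks$c_out[i]
  }
  structure(list(input_size = input_size, blocks = blocks,
                 graft_after_block = as.integer(graft_after_block),
                 glpp_dim = as.integer(glpp_dim),
                 n_classes = as.integer(n_classes)),
            class = "network_spec")
}

#' Default desk-scale block layout
#' @param c_in input channel count.
#' @return tibble of four stride-2 blocks, channels 16, 32, 64, 128.
#' @export
default_blocks <- function(c_in = 3L) {
  tibble::tibble(k = 3L,
                 c_in = c(c_in, 16L, 32L, 64L),
                 c_out = c(16L, 32L, 64L, 128L),
                 stride = 2L)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> input %s, %d blocks, graft after block %d (d = %d), %d classes\n",
              paste(x$input_size, collapse = "x"), nrow(x$blocks),
              x$graft_after_block, x$glpp_dim, x$n_classes))
  print(x$blocks)
  invisible(x)
}

#' Learnable-parameter counts
#'
#' Per block: depthwise `k*k*C`, pointwise `C*Ct`, their sum (the
#' separable count `k*k*C + C*Ct`), biases (reported separately), the 1x1
#' skip projection when the block changes shape, and the standard-convolution
#' comparison `k*k*C*Ct`. A final `head` row counts the dense classifier.
#'
#' @param spec a [network_spec()].
#' @return tibble with one row per block plus the head; the `separable`
#'   column for block rows obeys `k*k*c_in + c_in*c_out`.
#' @export
param_count <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  b <- spec$blocks
  rows <- tibble::tibble(
    layer = sprintf("block%d", seq_len(nrow(b))),
    k = b$k, c_in = b$c_in, c_out = b$c_out,
    depthwise = b$k * b$k * b$c_in,
    pointwise = b$c_in * b$c_out,
    separable = b$k * b$k * b$c_in + b$c_in * b$c_out,
    bias = b$c_out,
    skip = ifelse(b$stride != 1L | b$c_in != b$c_out, b$c_in * b$c_out, 0L),
    standard_equiv = b$k * b$k * b$c_in * b$c_out
  )
  head_in <- b$c_out[nrow(b)] +
    if (spec$graft_after_block == nrow(b)) spec$glpp_dim else 0L
  head_row <- tibble::tibble(
    layer = "head", k = NA_integer_, c_in = head_in, c_out = spec$n_classes,
    depthwise = 0L, pointwise = head_in * spec$n_classes,
    separable = head_in * spec$n_classes, bias = spec$n_classes,
    skip = 0L, standard_equiv = head_in * spec$n_classes
  )
  out <- dplyr::bind_rows(rows, head_row)
  attr(out, "total") <- sum(out$separable + out$bias + out$skip)
  out
}

## ---- weight initialisation -------------------------------------------------

#' Initialise network weights
#'
#' He-style initialisation, fully determined by `seed`.
#'
#' @param spec a [network_spec()]; @param seed integer.
#' @return a `histofuse_model` (untrained).
#' @export
init_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  with_seed_(seed, {
    blocks <- purrr::pmap(spec$blocks, function(k, c_in, c_out, stride) {
      list(
        dw = array(rnorm(k * k * c_in, sd = sqrt(2 / (k * k))), c(k, k, c_in)),
        pw = matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
        b = numeric(c_out),
        skip = if (stride != 1L || c_in != c_out) {
          matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out)
        } else NULL,
        stride = stride, k = k
      )
    })
    head_in <- tail(spec$blocks$c_out, 1) +
      if (spec$graft_after_block == nrow(spec$blocks)) spec$glpp_dim else 0L
    head <- list(
      W = matrix(rnorm(head_in * spec$n_classes, sd = sqrt(1 / head_in)),
                 head_in, spec$n_classes),
      b = numeric(spec$n_classes)
    )
    structure(list(spec = spec, blocks = blocks, head = head,
                   trained = FALSE, history = NULL),
              class = "histofuse_model")
  })
}

#' @export
print.histofuse_model <- function(x, ...) {
  cat(sprintf("<histofuse_model> %s, %s\n",
              if (x$trained) "trained" else "untrained",
              sprintf("%d parameters", attr(param_count(x$spec), "total")))
  )
  invisible(x)
}

## ---- layer primitives ------------------------------------------------------

same_pad <- function(n, k, s) {
  n_out <- ceiling(n / s)
  total <- max((n_out - 1) * s + k - n, 0)
  c(before = floor(total / 2), after = total - floor(total / 2), n_out = n_out)
}

pad_input <- function(x, k, s) {
  d <- dim(x)
  py <- same_pad(d[1], k, s); px <- same_pad(d[2], k, s)
  xp <- array(0, c(d[1] + py[1] + py[2], d[2] + px[1] + px[2], d[3]))
  xp[py[1] + seq_len(d[1]), px[1] + seq_len(d[2]), ] <- x
  list(xp = xp, py = py, px = px)
}

depthwise_conv <- function(x, w, stride) {
  k <- dim(w)[1]
  p <- pad_input(x, k, stride)
  h_out <- p$py[["n_out"]]; w_out <- p$px[["n_out"]]
  C <- dim(x)[3]
  out <- array(0, c(h_out, w_out, C))
  plane <- h_out * w_out
  for (u in seq_len(k)) {
    rows <- seq(u, by = stride, length.out = h_out)
    for (v in seq_len(k)) {
      cols <- seq(v, by = stride, length.out = w_out)
      out <- out + p$xp[rows, cols, , drop = FALSE] *
        rep(w[u, v, ], each = plane)
    }
  }
  out
}

pointwise_conv <- function(x, W, b = NULL) {
  d <- dim(x)
  y <- matrix(x, ncol = d[3]) %*% W
  if (!is.null(b)) y <- sweep(y, 2, b, `+`)
  array(y, c(d[1], d[2], ncol(W)))
}

strided_subsample <- function(x, stride) {
  if (stride == 1L) return(x)
  d <- dim(x)
  rows <- seq(1, d[1], by = stride); cols <- seq(1, d[2], by = stride)
  x[rows, cols, , drop = FALSE]
}

#' Depthwise-separable convolution, forward
#'
#' Per-channel `k x k` spatial convolution ('same' padding, given stride)
#' followed by a `1 x 1` pointwise channel mix with bias.
#'
#' @param x `H x W x C` input map.
#' @param weights list with `dw` (`k x k x C`), `pw` (`C x Ct`), `b`
#'   (length `Ct`).
#' @param stride spatial stride.
#' @return `ceil(H/stride) x ceil(W/stride) x Ct` map.
#' @export
depthwise_separable_forward <- function(x, weights, stride = 1L) {
  if (dim(x)[3] != dim(weights$dw)[3]) {
    abort(sprintf("input has %d channels but depthwise kernel expects %d",
                  dim(x)[3], dim(weights$dw)[3]))
  }
  mid <- depthwise_conv(x, weights$dw, stride)
  pointwise_conv(mid, weights$pw, weights$b)
}

#' Residual block, forward
#'
#' `activation(separable(x) + skip(x))` with ReLU activation; the skip path
#' is the identity when shapes match and a strided 1 x 1 projection
#' otherwise.
#'
#' @param x `H x W x C` input map.
#' @param weights block weight list as created by [init_network()]
#'   (`dw`, `pw`, `b`, optional `skip`, `stride`).
#' @return the activated output map.
#' @export
residual_block_forward <- function(x, weights) {
  f <- block_forward(x, weights)
  f$out
}

# forward with cached intermediates for backprop
block_forward <- function(x, wts) {
  mid <- depthwise_conv(x, wts$dw, wts$stride)
  main <- pointwise_conv(mid, wts$pw, wts$b)
  skip <- if (is.null(wts$skip)) {
    x
  } else {
    pointwise_conv(strided_subsample(x, wts$stride), wts$skip)
  }
  if (!all(dim(main) == dim(skip))) {
    abort(sprintf("residual block shape mismatch: main %s vs skip %s",
                  paste(dim(main), collapse = "x"),
                  paste(dim(skip), collapse = "x")))
  }
  pre <- main + skip
  list(out = pmax(pre, 0), pre = pre, mid = mid, x = x)
}

# backward through one residual block; returns dx and weight gradients
block_backward <- function(cache, wts, dout) {
  dpre <- dout * (cache$pre > 0)
  d <- dim(cache$mid)
  dpre_m <- matrix(dpre, ncol = dim(dpre)[3])
  # pointwise main path
  mid_m <- matrix(cache$mid, ncol = d[3])
  g_pw <- t(mid_m) %*% dpre_m
  g_b <- colSums(dpre_m)
  dmid <- array(dpre_m %*% t(wts$pw), d)
  # depthwise
  k <- wts$k; stride <- wts$stride
  p <- pad_input(cache$x, k, stride)
  dxp <- array(0, dim(p$xp))
  g_dw <- array(0, dim(wts$dw))
  h_out <- d[1]; w_out <- d[2]; C <- dim(cache$x)[3]
  plane <- h_out * w_out
  for (u in seq_len(k)) {
    rows <- seq(u, by = stride, length.out = h_out)
    for (v in seq_len(k)) {
      cols <- seq(v, by = stride, length.out = w_out)
      slice <- p$xp[rows, cols, , drop = FALSE]
      g_dw[u, v, ] <- colSums(matrix(slice * dmid, ncol = C))
      dxp[rows, cols, ] <- dxp[rows, cols, , drop = FALSE] +
        dmid * rep(wts$dw[u, v, ], each = plane)
    }
  }
  dx <- dxp[p$py[1] + seq_len(dim(cache$x)[1]),
            p$px[1] + seq_len(dim(cache$x)[2]), , drop = FALSE]
  # skip path
  if (is.null(wts$skip)) {
    dx <- dx + dpre
    g_skip <- NULL
  } else {
    xs <- strided_subsample(cache$x, stride)
    xs_m <- matrix(xs, ncol = C)
    g_skip <- t(xs_m) %*% dpre_m
    dxs <- array(dpre_m %*% t(wts$skip), dim(xs))
    rows <- seq(1, dim(cache$x)[1], by = stride)
    cols <- seq(1, dim(cache$x)[2], by = stride)
    dx[rows, cols, ] <- dx[rows, cols, , drop = FALSE] + dxs
  }
  list(dx = dx, g = list(dw = g_dw, pw = g_pw, b = g_b, skip = g_skip))
}

#' Grafting layer, forward
#'
#' Broadcasts the handcrafted vector to every spatial location and appends
#' it along the channel axis; the convolutional channels pass through
#' unchanged (bit-identical).
#'
#' @param conv_feat `H x W x C` map; @param glpp numeric vector, length `d`.
#' @return `H x W x (C + d)` map.
#' @export
graft_forward <- function(conv_feat, glpp) {
  d <- length(glpp)
  if (d == 0L) return(conv_feat)
  dm <- dim(conv_feat)
  out <- array(0, c(dm[1], dm[2], dm[3] + d))
  out[, , seq_len(dm[3])] <- conv_feat
  out[, , dm[3] + seq_len(d)] <- rep(glpp, each = dm[1] * dm[2])
  out
}

#' Grafting layer, backward
#'
#' The grafted branch is a constant input: the returned gradient is the
#' upstream gradient restricted to the first `C` convolutional channels,
#' and nothing is propagated to the handcrafted-feature producer.
#'
#' @param dout upstream `H x W x (C + d)` gradient; @param C convolutional
#'   channel count.
#' @return `H x W x C` gradient with respect to `conv_feat`.
#' @export
graft_backward <- function(dout, C) {
  dout[, , seq_len(C), drop = FALSE]
}

## ---- full model forward / backward ----------------------------------------

model_forward <- function(model, x, glpp, keep_cache = FALSE) {
  spec <- model$spec
  caches <- vector("list", nrow(spec$blocks))
  conv_c_at_graft <- NA_integer_
  h <- x
  for (i in seq_len(nrow(spec$blocks))) {
    if (i - 1L == spec$graft_after_block && spec$glpp_dim > 0L) {
      conv_c_at_graft <- dim(h)[3]
      h <- graft_forward(h, glpp)
    }
    f <- block_forward(h, model$blocks[[i]])
    caches[[i]] <- if (keep_cache) f else NULL
    h <- f$out
  }
  if (spec$graft_after_block == nrow(spec$blocks) && spec$glpp_dim > 0L) {
    conv_c_at_graft <- dim(h)[3]
    h <- graft_forward(h, glpp)
  }
  pooled <- colMeans(matrix(h, ncol = dim(h)[3]))
  logits <- as.vector(pooled %*% model$head$W) + model$head$b
  list(logits = logits, pooled = pooled, last = h, caches = caches,
       conv_c_at_graft = conv_c_at_graft)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# backward pass for one sample; returns gradient list mirroring the model
model_backward <- function(model, fwd, y_index) {
  spec <- model$spec
  probs <- softmax(fwd$logits)
  dlogits <- probs
  dlogits[y_index] <- dlogits[y_index] - 1
  g_head_W <- outer(fwd$pooled, dlogits)
  g_head_b <- dlogits
  dpooled <- as.vector(model$head$W %*% dlogits)
  dlast <- dim(fwd$last)
  dmap <- array(rep(dpooled, each = dlast[1] * dlast[2]) / (dlast[1] * dlast[2]),
                dlast)
  n_blocks <- nrow(spec$blocks)
  if (spec$graft_after_block == n_blocks && spec$glpp_dim > 0L) {
    dmap <- graft_backward(dmap, fwd$conv_c_at_graft)
  }
  g_blocks <- vector("list", n_blocks)
  for (i in rev(seq_len(n_blocks))) {
    bb <- block_backward(fwd$caches[[i]], model$blocks[[i]], dmap)
    g_blocks[[i]] <- bb$g
    dmap <- bb$dx
    if (i - 1L == spec$graft_after_block && spec$glpp_dim > 0L) {
      dmap <- graft_backward(dmap, fwd$conv_c_at_graft)
    }
  }
  list(blocks = g_blocks, head = list(W = g_head_W, b = g_head_b),
       loss = -log(max(probs[y_index], 1e-12)))
}

## ---- training --------------------------------------------------------------

#' Training configuration
#'
#' @param epochs passes over the training split.
#' @param batch_size minibatch size (per-class training counts must be at
#'   least this large).
#' @param lr learning rate; @param momentum SGD momentum.
#' @param seed integer governing initialisation and shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 4L, batch_size = 16L, lr = 0.01,
                         momentum = 0.9, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, lr >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, seed = as.integer(seed)),
            class = "train_config")
}

prepare_inputs <- function(tiles, spec) {
  purrr::map(tiles$tiles, function(tl) {
    resize_image(tl, spec$input_size[1:2]) / 255 - 0.5
  })
}

glpp_matrix_for <- function(tiles, glpp_tbl, glpp_dim) {
  if (glpp_dim == 0L) {
    return(matrix(0, length(tiles$tiles), 0L))
  }
  stopifnot(!is.null(glpp_tbl))
  idx <- match(tiles$manifest$id, glpp_tbl$id)
  if (anyNA(idx)) abort("glpp feature table is missing some tile ids")
  m <- as.matrix(glpp_tbl[idx, setdiff(names(glpp_tbl), c("id", "label", "split"))])
  if (ncol(m) != glpp_dim) {
    abort(sprintf("glpp features have length %d but spec$glpp_dim = %d",
                  ncol(m), glpp_dim))
  }
  m
}

#' Train the network
#'
#' Minimises multinomial cross-entropy by minibatch SGD with momentum.
#' The validation split is evaluated after every epoch. Fully seeded: two
#' runs with the same config produce identical histories and weights.
#'
#' @param spec a [network_spec()].
#' @param tiles a [tile_set] with assigned splits (train/val used here).
#' @param glpp_tbl tibble from [glpp_feature_table()] (or `NULL` when
#'   `spec$glpp_dim == 0`).
#' @param config a [train_config()].
#' @return a trained `histofuse_model`; `$history` is a tibble with
#'   per-epoch train/val loss and accuracy.
#' @export
train_network <- function(spec, tiles, glpp_tbl = NULL,
                          config = train_config()) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "train_config"))
  man <- tiles$manifest
  counts <- table(man$label[man$split == "train"])
  if (any(counts == 0) || length(counts) < spec$n_classes) {
    abort("every class needs at least one training tile")
  }
  if (min(counts) < config$batch_size) {
    abort(sprintf("per-class training count %d is below batch_size %d",
                  min(counts), config$batch_size))
  }
  levels <- sort(unique(man$label))
  y_all <- match(man$label, levels)
  xs <- prepare_inputs(tiles, spec)
  gm <- glpp_matrix_for(tiles, glpp_tbl, spec$glpp_dim)

  model <- init_network(spec, seed = config$seed)
  vel <- grad_zero(model)
  idx_train <- which(man$split == "train")
  idx_val <- which(man$split == "val")

  history <- vector("list", config$epochs)
  with_seed_(child_seed(config$seed, "shuffle"), {
    for (ep in seq_len(config$epochs)) {
      ord <- idx_train[sample.int(length(idx_train))]
      ep_loss <- 0; ep_correct <- 0L
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (batch in batches) {
        acc <- grad_zero(model)
        for (j in batch) {
          fwd <- model_forward(model, xs[[j]], gm[j, ], keep_cache = TRUE)
          bwd <- model_backward(model, fwd, y_all[j])
          if (!is.finite(bwd$loss)) {
            abort(sprintf("non-finite training loss at epoch %d (tile %s)",
                          ep, man$id[j]))
          }
          ep_loss <- ep_loss + bwd$loss
          ep_correct <- ep_correct + (which.max(fwd$logits) == y_all[j])
          acc <- grad_add(acc, bwd)
        }
        vel <- grad_axpy(vel, acc, config$momentum, 1 / length(batch))
        model <- apply_update(model, vel, config$lr)
      }
      val <- evaluate_split(model, xs, gm, y_all, idx_val)
      history[[ep]] <- tibble::tibble(
        epoch = ep,
        train_loss = ep_loss / length(ord),
        train_acc = ep_correct / length(ord),
        val_loss = val$loss, val_acc = val$acc
      )
    }
  })
  model$trained <- config$epochs > 0L
  model$levels <- levels
  model$history <- dplyr::bind_rows(history)
  model$config <- config
  model
}

evaluate_split <- function(model, xs, gm, y_all, idx) {
  if (!length(idx)) return(list(loss = NA_real_, acc = NA_real_))
  loss <- 0; correct <- 0L
  for (j in idx) {
    fwd <- model_forward(model, xs[[j]], gm[j, ])
    p <- softmax(fwd$logits)
    loss <- loss - log(max(p[y_all[j]], 1e-12))
    correct <- correct + (which.max(fwd$logits) == y_all[j])
  }
  list(loss = loss / length(idx), acc = correct / length(idx))
}

grad_zero <- function(model) {
  list(
    blocks = purrr::map(model$blocks, function(w) list(
      dw = array(0, dim(w$dw)), pw = matrix(0, nrow(w$pw), ncol(w$pw)),
      b = numeric(length(w$b)),
      skip = if (is.null(w$skip)) NULL else matrix(0, nrow(w$skip), ncol(w$skip))
    )),
    head = list(W = matrix(0, nrow(model$head$W), ncol(model$head$W)),
                b = numeric(length(model$head$b)))
  )
}

grad_add <- function(a, b) {
  a$blocks <- purrr::map2(a$blocks, b$blocks, function(x, y) {
    x$dw <- x$dw + y$dw; x$pw <- x$pw + y$pw; x$b <- x$b + y$b
    if (!is.null(x$skip)) x$skip <- x$skip + y$skip
    x
  })
  a$head$W <- a$head$W + b$head$W
  a$head$b <- a$head$b + b$head$b
  a
}

# vel = momentum * vel + scale * grad
grad_axpy <- function(vel, grad, momentum, scale) {
  vel$blocks <- purrr::map2(vel$blocks, grad$blocks, function(v, g) {
    v$dw <- momentum * v$dw + scale * g$dw
    v$pw <- momentum * v$pw + scale * g$pw
    v$b <- momentum * v$b + scale * g$b
    if (!is.null(v$skip)) v$skip <- momentum * v$skip + scale * g$skip
    v
  })
  vel$head$W <- momentum * vel$head$W + scale * grad$head$W
  vel$head$b <- momentum * vel$head$b + scale * grad$head$b
  vel
}

apply_update <- function(model, vel, lr) {
  model$blocks <- purrr::map2(model$blocks, vel$blocks, function(w, v) {
    w$dw <- w$dw - lr * v$dw; w$pw <- w$pw - lr * v$pw; w$b <- w$b - lr * v$b
    if (!is.null(w$skip)) w$skip <- w$skip - lr * v$skip
    w
  })
  model$head$W <- model$head$W - lr * vel$head$W
  model$head$b <- model$head$b - lr * vel$head$b
  model
}

#' Fused feature table
#'
#' Per tile: the global-average-pooled activations of the last (grafted)
#' map. With grafting enabled these are exactly the pooled convolutional
#' channels followed by the handcrafted vector, i.e. the fused
#' representation handed to the classical classifiers. Row order follows
#' the tile set.
#'
#' @param model a `histofuse_model` (a warning is issued when untrained).
#' @param tiles a [tile_set]; @param glpp_tbl as in [train_network()].
#' @return tibble: `id`, `label`, `split`, `cnn_*` pooled channels, then
#'   `glpp_*` columns when grafting is enabled.
#' @export
extract_fused_features <- function(model, tiles, glpp_tbl = NULL) {
  stopifnot(inherits(model, "histofuse_model"))
  if (!isTRUE(model$trained)) {
    warn("extracting features from an untrained model")
  }
  spec <- model$spec
  xs <- prepare_inputs(tiles, spec)
  gm <- glpp_matrix_for(tiles, glpp_tbl, spec$glpp_dim)
  pooled <- purrr::map(seq_along(xs), function(j) {
    model_forward(model, xs[[j]], gm[j, ])$pooled
  })
  pooled <- do.call(rbind, pooled)
  n_conv <- ncol(pooled) - spec$glpp_dim
  colnames(pooled) <- c(sprintf("cnn_%03d", seq_len(n_conv)),
                        if (spec$glpp_dim > 0L) sprintf("glpp_%04d", seq_len(spec$glpp_dim)))
  dplyr::bind_cols(tiles$manifest[, c("id", "label", "split")],
                   tibble::as_tibble(pooled))
}

#' Save / load a model checkpoint
#'
#' Weights go to an RDS file with a JSON sidecar echoing the architecture
#' and training configuration, so the architecture is reconstructable
#' without the binary.
#'
#' @param model a `histofuse_model`; @param path checkpoint path (`.rds`).
#' @return `save_model()` the path, invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(
    spec = list(input_size = model$spec$input_size,
                blocks = model$spec$blocks,
                graft_after_block = model$spec$graft_after_block,
                glpp_dim = model$spec$glpp_dim,
                n_classes = model$spec$n_classes),
    config = if (!is.null(model$config)) unclass(model$config),
    trained = model$trained
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
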