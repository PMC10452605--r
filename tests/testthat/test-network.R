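delta_kernel <- function(k, C) {
  dw <- array(0, c(k, k, C))
  mid <- (k + 1) %/% 2
  for (c in seq_len(C)) dw[mid, mid, c] <- 1
  dw
}

test_that("separable convolution reduces to identity and bias in edge cases", {
  set.seed(31)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  w <- list(dw = delta_kernel(3, 4), pw = diag(4), b = numeric(4))
  expect_equal(depthwise_separable_forward(x, w), x, tolerance = 1e-12)

  b <- rnorm(5)
  w0 <- list(dw = array(rnorm(3 * 3 * 4), c(3, 3, 4)),
             pw = matrix(rnorm(20), 4, 5), b = b)
  out <- depthwise_separable_forward(array(0, c(6, 6, 4)), w0)
  expect_equal(out, array(rep(b, each = 36), c(6, 6, 5)), tolerance = 1e-12)

  expect_error(depthwise_separable_forward(x, w0 <- list(dw = delta_kernel(3, 2),
                                                         pw = diag(2), b = numeric(2))),
               "channels")
})

test_that("separable convolution agrees with the quadruple-loop oracle", {
  set.seed(32)
  for (k in c(1, 3, 5)) {
    for (case in 1:20) {
      C <- sample(1:3, 1); Ct <- sample(1:4, 1)
      x <- array(rnorm(8 * 8 * C), c(8, 8, C))
      w <- list(dw = array(rnorm(k * k * C), c(k, k, C)),
                pw = matrix(rnorm(C * Ct), C, Ct), b = rnorm(Ct))
      got <- depthwise_separable_forward(x, w, stride = 1L)
      expect_lt(max(abs(got - oracle_sepconv(x, w$dw, w$pw, w$b))), 1e-6)
    }
  }
})

test_that("parameter counts follow the separable-convolution law", {
  pc <- param_count(network_spec(input_size = c(32, 32, 16),
                                 blocks = tibble::tibble(k = 3L, c_in = 16L,
                                                         c_out = 32L, stride = 1L),
                                 glpp_dim = 0L, n_classes = 2L))
  expect_equal(pc$separable[1], 3 * 3 * 16 + 16 * 32) # 656
  expect_equal(pc$standard_equiv[1], 4608)

  pc1 <- param_count(network_spec(input_size = c(16, 16, 4),
                                  blocks = tibble::tibble(k = 1L, c_in = 4L,
                                                          c_out = 6L, stride = 1L),
                                  glpp_dim = 0L, n_classes = 2L))
  expect_equal(pc1$separable[1], 4 + 4 * 6)

  pc2 <- param_count(network_spec(input_size = c(16, 16, 1),
                                  blocks = tibble::tibble(k = 3L, c_in = 1L,
                                                          c_out = 1L, stride = 1L),
                                  glpp_dim = 0L, n_classes = 2L))
  expect_equal(pc2$separable[1], 10)
})

count_allocated <- function(model) {
  n <- 0
  for (b in model$blocks) {
    n <- n + length(b$dw) + length(b$pw) + length(b$b) +
      if (is.null(b$skip)) 0 else length(b$skip)
  }
  n + length(model$head$W) + length(model$head$b)
}

test_that("parameter counts equal direct enumeration of allocated weights", {
  set.seed(33)
  for (case in 1:10) {
    n_blocks <- sample(1:4, 1)
    ks <- sample(c(1, 3, 5), n_blocks, replace = TRUE)
    chans <- c(3, sample(2:12, n_blocks, replace = TRUE))
    spec <- network_spec(
      input_size = c(32, 32, 3),
      blocks = tibble::tibble(k = as.integer(ks),
                              c_in = as.integer(chans[-length(chans)]),
                              c_out = as.integer(chans[-1]),
                              stride = sample(1:2, n_blocks, replace = TRUE)),
      graft_after_block = n_blocks,
      glpp_dim = sample(0:8, 1),
      n_classes = sample(2:5, 1)
    )
    pc <- param_count(spec)
    expect_equal(pc$separable, pc$depthwise + pc$pointwise)
    expect_equal(attr(pc, "total"), count_allocated(init_network(spec, case)))
  }
})

test_that("residual blocks add skip paths and halve dims under stride 2", {
  set.seed(34)
  x <- array(rnorm(7 * 7 * 4), c(7, 7, 4))
  wz <- list(dw = array(0, c(3, 3, 4)), pw = matrix(0, 4, 4), b = numeric(4),
             skip = NULL, stride = 1L, k = 3L)
  expect_equal(residual_block_forward(x, wz), pmax(x, 0), tolerance = 1e-12)

  w <- list(dw = array(rnorm(36), c(3, 3, 4)), pw = matrix(rnorm(16), 4, 4),
            b = rnorm(4), skip = NULL, stride = 1L, k = 3L)
  got <- residual_block_forward(x, w)
  main <- depthwise_separable_forward(x, w, stride = 1L)
  expect_equal(got, pmax(main + x, 0), tolerance = 1e-10)

  w2 <- list(dw = array(rnorm(36), c(3, 3, 4)), pw = matrix(rnorm(24), 4, 6),
             b = rnorm(6), skip = matrix(rnorm(24), 4, 6), stride = 2L, k = 3L)
  out2 <- residual_block_forward(x, w2)
  expect_equal(dim(out2), c(4, 4, 6)) # ceil(7/2)
})

test_that("the graft layer broadcasts and keeps conv channels bit-identical", {
  set.seed(35)
  x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  expect_identical(graft_forward(x, numeric(0)), x)

  g0 <- graft_forward(x, numeric(4))
  expect_identical(g0[, , 1:3], x)
  expect_true(all(g0[, , 4:7] == 0))

  g <- rnorm(4)
  gf <- graft_forward(x, g)
  expect_equal(dim(gf), c(4, 5, 7))
  for (i in seq_along(g)) expect_true(all(gf[, , 3 + i] == g[i]))
})

test_that("graft backward passes gradients to conv channels only", {
  set.seed(36)
  dout <- array(rnorm(4 * 4 * 7), c(4, 4, 7))
  dx <- graft_backward(dout, 3L)
  expect_identical(dx, dout[, , 1:3, drop = FALSE])
  dz <- dout; dz[, , 1:3] <- 0
  expect_true(all(graft_backward(dz, 3L) == 0))
})

test_that("full-model gradients pass a central-difference check", {
  set.seed(37)
  spec <- network_spec(
    input_size = c(12, 12, 2),
    blocks = tibble::tibble(k = 3L, c_in = c(2L, 4L), c_out = c(4L, 6L),
                            stride = c(2L, 1L)),
    glpp_dim = 3L, n_classes = 3L
  )
  model <- init_network(spec, 1)
  x <- array(rnorm(12 * 12 * 2, sd = 0.4), c(12, 12, 2))
  glpp <- rnorm(3)
  y <- 2L
  loss_fn <- function(m, xx, gg) {
    f <- histofuse:::model_forward(m, xx, gg)
    -log(histofuse:::softmax(f$logits)[y])
  }
  fwd <- histofuse:::model_forward(model, x, glpp, keep_cache = TRUE)
  bwd <- histofuse:::model_backward(model, fwd, y)
  eps <- 1e-5
  # weights in every component
  for (bi in 1:2) {
    for (comp in c("dw", "pw", "b", "skip")) {
      w <- model$blocks[[bi]][[comp]]
      if (is.null(w)) next
      for (idx in unique(c(1, length(w), sample(length(w), 2)))) {
        m2 <- model; m2$blocks[[bi]][[comp]][idx] <- w[idx] + eps
        m3 <- model; m3$blocks[[bi]][[comp]][idx] <- w[idx] - eps
        fd <- (loss_fn(m2, x, glpp) - loss_fn(m3, x, glpp)) / (2 * eps)
        an <- bwd$blocks[[bi]][[comp]][idx]
        expect_lt(abs(fd - an) / max(abs(fd), 1e-6), 1e-4)
      }
    }
  }
  # perturbing the grafted vector changes the forward output ...
  g2 <- glpp; g2[1] <- g2[1] + 0.5
  expect_gt(abs(loss_fn(model, x, g2) - loss_fn(model, x, glpp)), 0)
  # ... but the layer exposes no gradient to the handcrafted branch
  expect_equal(dim(histofuse:::graft_backward(array(1, c(2, 2, 5)), 2L))[3], 2L)
})

make_easy_tiles <- function(n_per_class = 8, size = 32, seed = 40) {
  # three flat-intensity classes: trivially separable by the network
  withr::with_seed(seed, {
    tiles <- list(); labels <- character()
    means <- c(a = 40, b = 128, c = 215)
    for (cls in names(means)) {
      for (i in seq_len(n_per_class)) {
        tiles[[length(tiles) + 1L]] <-
          array(pmin(pmax(round(rnorm(size * size * 3, means[cls], 8)), 0), 255),
                c(size, size, 3))
        labels <- c(labels, cls)
      }
    }
    assign_splits(tile_set(tiles, labels), c(0.5, 0.25, 0.25), seed = seed)
  })
}

test_that("training is seeded, monotone on easy data, and frozen at lr = 0", {
  ts <- make_easy_tiles()
  spec <- network_spec(
    input_size = c(16, 16, 3),
    blocks = tibble::tibble(k = 3L, c_in = c(3L, 8L), c_out = c(8L, 16L),
                            stride = 2L),
    glpp_dim = 0L, n_classes = 3L
  )
  cfg0 <- train_config(epochs = 2, batch_size = 4, lr = 0, seed = 3)
  m0 <- train_network(spec, ts, NULL, cfg0)
  init <- init_network(spec, seed = cfg0$seed)
  expect_equal(m0$blocks[[1]]$dw, init$blocks[[1]]$dw)
  expect_equal(m0$head$W, init$head$W)

  cfg <- train_config(epochs = 10, batch_size = 4, lr = 0.05, seed = 3)
  m1 <- train_network(spec, ts, NULL, cfg)
  expect_lt(m1$history$train_loss[nrow(m1$history)], m1$history$train_loss[1])

  m2 <- train_network(spec, ts, NULL, cfg)
  expect_identical(m1$history, m2$history)
})

test_that("training validates class counts and batch sizes", {
  ts <- make_easy_tiles(n_per_class = 3)
  spec <- network_spec(input_size = c(16, 16, 3),
                       blocks = tibble::tibble(k = 3L, c_in = 3L, c_out = 8L,
                                               stride = 2L),
                       glpp_dim = 0L, n_classes = 3L)
  expect_error(train_network(spec, ts, NULL, train_config(batch_size = 16)),
               "batch_size")
})

test_that("fused feature extraction concatenates pooled channels and glpp", {
  ts <- make_easy_tiles(n_per_class = 4)
  ts$tiles[[2]] <- ts$tiles[[1]] # force an identical pair
  cfg <- glpp_config(schedule = list(c(1, 8)))
  gl <- glpp_feature_table(ts, cfg, gray_fun = function(tl) tl[, , 1])
  d <- length(setdiff(names(gl), c("id", "label", "split")))
  spec <- network_spec(input_size = c(16, 16, 3),
                       blocks = tibble::tibble(k = 3L, c_in = 3L, c_out = 8L,
                                               stride = 2L),
                       glpp_dim = d, n_classes = 3L)
  model <- train_network(spec, ts, gl, train_config(epochs = 1, batch_size = 2,
                                                    seed = 5))
  feats <- extract_fused_features(model, ts, gl)
  fc <- setdiff(names(feats), c("id", "label", "split"))
  expect_length(fc, 8 + d)
  expect_equal(unlist(feats[1, fc]), unlist(feats[2, fc]))

  gl0 <- gl
  gl0[, setdiff(names(gl0), c("id", "label", "split"))] <- 0
  feats0 <- extract_fused_features(model, ts, gl0)
  cnn_cols <- grep("^cnn_", fc, value = TRUE)
  glpp_cols <- grep("^glpp_", fc, value = TRUE)
  expect_equal(feats0[, cnn_cols], feats[, cnn_cols])
  expect_true(all(feats0[, glpp_cols] == 0))

  expect_warning(extract_fused_features(init_network(spec, 1), ts, gl),
                 "untrained")
})
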