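vn <- asNamespace("vesselnoise")

test_that("model output has two softmax channels per pixel", {
  m <- build_unet(model_config(patch_size = 48L, depth = 2L, base_channels = 4L,
                               attention = "off"), seed = 1L)
  x <- array(runif(48 * 48 * 1 * 3), c(48, 48, 1, 3))
  fw <- vn$unet_forward(m, x, training = FALSE)
  expect_equal(dim(fw$probs), c(48, 48, 2, 3))
  sums <- fw$probs[, , 1, ] + fw$probs[, , 2, ]
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_error(build_unet(model_config(patch_size = 50L, depth = 2L)),
               "divisible")
})

test_that("fused convolution matches the explicit im2col + matmul route", {
  set.seed(9)
  x <- array(rnorm(7 * 6 * 3 * 2), c(7, 6, 3, 2))
  p <- vn$conv_init(3L, 4L, 3)
  y <- vn$conv_fwd(x, p)$y
  # independent route: explicit column matrix and BLAS matmul
  cols <- vn$nn_im2col(x, 3L)
  ref <- cols %*% p$W
  ref <- sweep(ref, 2, p$b, "+")
  # rows of the column matrix are ordered (h, w, n); fold back per sample
  ref <- aperm(array(ref, c(7, 6, 2, 4)), c(1, 2, 4, 3))
  expect_equal(y, ref, tolerance = 1e-12)
  # adjoint consistency: col2im is the transpose of im2col
  g <- array(rnorm(length(y)), dim(y))
  gx <- vn$conv_bwd(vn$conv_fwd(x, p), p, g)$gx
  gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = 4)
  gx_ref <- vn$nn_col2im(gm %*% t(p$W), 7L, 6L, 3L, 2L, 3L)
  expect_equal(gx, gx_ref, tolerance = 1e-12)
})

test_that("parameter count matches a hand-computed closed form", {
  m <- build_unet(model_config(patch_size = 16L, depth = 1L, base_channels = 4L,
                               attention = "off"), seed = 1L)
  # encoder: conv(1->4) 40, conv(4->4) 148, 2 BN pairs 16
  # bottleneck: conv(4->8) 296, conv(8->8) 584, 2 BN pairs 32
  # decoder: up conv(8->4) 292 + BN 8, conv(8->4) 292 + BN 8,
  #          conv(4->4) 148 + BN 8
  # head: 1x1 conv(4->2) 10
  expect_equal(m$n_parameters,
               40 + 148 + 16 + 296 + 584 + 32 + 292 + 8 + 292 + 8 + 148 + 8 + 10)
})

test_that("dynamic attention follows scaled dot-product algebra", {
  set.seed(3)
  # n = 1: the single attention weight is 1 and the context is V1
  p <- vn$att_init(3L, 3L, 3L)
  Hmap <- array(rnorm(3), c(1, 1, 3, 1))
  dmap <- array(rnorm(3), c(1, 1, 3, 1))
  out <- dynamic_attention(Hmap, dmap, p)
  Hv <- as.numeric(Hmap)
  dv <- as.numeric(dmap)
  V1 <- as.numeric(p$W_V %*% Hv)
  o <- as.numeric(p$W_o %*% c(V1, dv) + p$b_o)
  expect_equal(as.numeric(out$y), Hv + o, tolerance = 1e-12)

  # a 2-position hand-worked case: A = softmax(K Q / sqrt(dk)), C = A V
  p2 <- vn$att_init(2L, 2L, 2L)
  Hmap2 <- array(c(1, 0, 0.5, -1, 0.25, 2, -0.5, 1), c(2, 1, 2, 2))[, , , 1, drop = FALSE]
  Hmap2 <- array(c(1, 0.5, -0.25, 2), c(2, 1, 2, 1))  # positions (1,0.5) ch1, (-0.25,2) ch2
  dmap2 <- array(c(0.3, -0.7, 1.1, 0.2), c(2, 1, 2, 1))
  out2 <- dynamic_attention(Hmap2, dmap2, p2)
  Hm <- matrix(Hmap2[, , , 1], 2)            # 2 positions x 2 channels
  dvec <- colMeans(matrix(dmap2[, , , 1], 2))
  Q <- p2$W_Q %*% dvec
  K <- Hm %*% t(p2$W_K)
  V <- Hm %*% t(p2$W_V)
  s <- as.numeric(K %*% Q) / sqrt(2)
  A <- exp(s) / sum(exp(s))
  expect_equal(sum(A), 1)
  Cvec <- as.numeric(t(V) %*% A)
  o2 <- as.numeric(p2$W_o %*% c(Cvec, dvec) + p2$b_o)
  expect_equal(matrix(out2$y[, , , 1], 2) - Hm,
               matrix(rep(o2, each = 2), 2), tolerance = 1e-12)

  # uniform scores (K = 0) average the value rows into the context
  p3 <- vn$att_init(2L, 2L, 2L)
  p3$W_K[] <- 0
  Hmap3 <- array(rnorm(8), c(2, 2, 2, 1))
  dmap3 <- array(rnorm(8), c(2, 2, 2, 1))
  out3 <- dynamic_attention(Hmap3, dmap3, p3)
  Hm3 <- matrix(Hmap3[, , , 1], 4)
  dv3 <- colMeans(matrix(dmap3[, , , 1], 4))
  Cmean <- colMeans(Hm3 %*% t(p3$W_V))
  o3 <- as.numeric(p3$W_o %*% c(Cmean, dv3) + p3$b_o)
  expect_equal(matrix(out3$y[, , , 1], 4) - Hm3,
               matrix(rep(o3, each = 4), 4), tolerance = 1e-12)
})

test_that("cross-entropy loss matches closed forms", {
  onehot <- vn$onehot_labels(array(c(1, 0, 0, 1), c(2, 2, 1)))
  perfect <- onehot
  expect_equal(cross_entropy_loss(perfect, onehot), 0)
  uniform <- array(0.5, dim(onehot))
  expect_equal(cross_entropy_loss(uniform, onehot), log(2), tolerance = 1e-12)
  # hand-summed 2x2 mixed case
  probs <- array(0, c(2, 2, 2, 1))
  pv <- matrix(c(0.9, 0.2, 0.6, 0.5), 2)    # vessel-channel probabilities
  probs[, , 2, 1] <- pv
  probs[, , 1, 1] <- 1 - pv
  y <- array(c(1, 0, 0, 1), c(2, 2, 1))
  hand <- -(log(0.9) + log(1 - 0.2) + log(1 - 0.6) + log(0.5)) / 4
  expect_equal(cross_entropy_loss(probs, vn$onehot_labels(y)), hand,
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(uniform, onehot[1:1, , , , drop = FALSE]),
               "shape")
})

test_that("backward pass matches finite differences", {
  set.seed(42)
  cfg <- model_config(patch_size = 8L, depth = 2L, base_channels = 2L,
                      dropout_rate = 0, attention = "bottleneck_and_skips")
  m <- build_unet(cfg, seed = 7L)
  xb <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  yb <- vn$onehot_labels(array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 2)))
  lossfn <- function(model)
    cross_entropy_loss(vn$unet_forward(model, xb, TRUE)$probs, yb)
  fw <- vn$unet_forward(m, xb, training = TRUE)
  gr <- vn$unet_backward(m, fw, (fw$probs - yb) / (8 * 8 * 2))
  probes <- list(
    list(\(p) p$enc[[1]]$u1$conv$W[5, 1], \(p, e) {p$enc[[1]]$u1$conv$W[5, 1] <- p$enc[[1]]$u1$conv$W[5, 1] + e; p},
         gr$enc[[1]]$u1$conv$W[5, 1]),
    list(NULL, \(p, e) {p$bott$u2$bn$gamma[3] <- p$bott$u2$bn$gamma[3] + e; p},
         gr$bott$u2$bn$gamma[3]),
    list(NULL, \(p, e) {p$dec[[1]]$u2$bn$beta[2] <- p$dec[[1]]$u2$bn$beta[2] + e; p},
         gr$dec[[1]]$u2$bn$beta[2]),
    list(NULL, \(p, e) {p$att_bott$W_Q[2, 3] <- p$att_bott$W_Q[2, 3] + e; p},
         gr$att_bott$W_Q[2, 3]),
    list(NULL, \(p, e) {p$att_skip[[2]]$W_K[1, 2] <- p$att_skip[[2]]$W_K[1, 2] + e; p},
         gr$att_skip[[2]]$W_K[1, 2]),
    list(NULL, \(p, e) {p$head$W[2, 2] <- p$head$W[2, 2] + e; p},
         gr$head$W[2, 2]))
  eps <- 1e-5
  for (pr in probes) {
    m1 <- m; m1$params <- pr[[2]](m$params, eps)
    m2 <- m; m2$params <- pr[[2]](m$params, -eps)
    num <- (lossfn(m1) - lossfn(m2)) / (2 * eps)
    expect_equal(pr[[3]], num, tolerance = 1e-4)
  }
})

test_that("predictions are probabilities, stateless across batch order, and stable", {
  m <- build_unet(model_config(patch_size = 16L, depth = 2L, base_channels = 2L,
                               attention = "bottleneck"), seed = 2L)
  m$cfg$patch_size <- 16L
  patches <- array(runif(16 * 16 * 5, 0, 255), c(16, 16, 5))
  p1 <- predict_patches(m, patches, batch_size = 2L)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # batch splitting does not change per-patch outputs
  p2 <- predict_patches(m, patches, batch_size = 5L)
  expect_equal(p1, p2, tolerance = 1e-12)
  # order invariance
  p3 <- predict_patches(m, patches[, , c(3, 1, 2, 5, 4)], batch_size = 3L)
  expect_equal(p3[, , 2], p1[, , 1], tolerance = 1e-12)
  # repeated-run equality
  expect_identical(p1, predict_patches(m, patches, batch_size = 2L))
  expect_error(predict_patches(m, array(0, c(8, 8, 2))), "shape")
})

test_that("a tiny network overfits a handful of patches", {
  smp <- fix_preprocessed()
  ps <- extract_training_patches(smp, sampling_config(patches_per_image = 32L),
                                 seed = 4L)
  m <- build_unet(model_config(depth = 2L, base_channels = 8L,
                               attention = "bottleneck"), seed = 4L)
  tr <- train_unet(m, ps, train_config(epochs = 60L, batch_size = 32L, seed = 4L))
  expect_lt(min(tr$loss_trace), 0.05)
  # the loss trace trends downward over training
  expect_lt(mean(utils::tail(tr$loss_trace, 5)), mean(utils::head(tr$loss_trace, 5)))
})
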