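# Low-level neural-network layers on (H, W, C, N) arrays.
#
# Convolutions go through the im2col kernels in src/ plus BLAS matmul; all
# backward passes are hand-derived and checked against finite differences in
# the test suite. Tensors are plain R arrays, parameters plain R matrices.

# ---- convolution (stride 1, 'same' zero padding) ---------------------------

conv_init <- function(cin, cout, k, gain = sqrt(2)) {
  fan_in <- k * k * cin
  list(W = matrix(rnorm(fan_in * cout, 0, gain / sqrt(fan_in)), fan_in, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

conv_fwd <- function(x, p) {
  list(y = nn_conv_forward(x, p$W, p$b, p$k), x = x)
}

conv_bwd <- function(cache, p, gy, need_gx = TRUE) {
  g <- nn_conv_backward(cache$x, p$W, gy, p$k, need_gx)
  list(gx = g$gx, gW = g$gW, gb = g$gb)
}

# ---- batch normalization ---------------------------------------------------
#
# Per-channel statistics over all pixels and samples, computed by the single
# pass kernels in src/bn_ops.cpp.

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

bn_fwd <- function(x, p, training, eps = 1e-5, momentum = 0.9) {
  r <- nn_bn_forward(x, p$gamma, p$beta, p$run_mean, p$run_var, eps,
                     compute_stats = training)
  if (training) {
    p$run_mean <- momentum * p$run_mean + (1 - momentum) * r$mu
    p$run_var <- momentum * p$run_var + (1 - momentum) * r$var
  }
  list(y = r$y, xhat = r$xhat, inv_std = r$inv_std, d = dim(x),
       training = training, p = p)
}

bn_bwd <- function(cache, p, gy) {
  r <- nn_bn_backward(gy, cache$xhat, p$gamma, cache$inv_std,
                      as.integer(cache$d), cache$training)
  list(gx = r$gx, ggamma = r$ggamma, gbeta = r$gbeta)
}

relu_fwd <- function(x) {
  y <- nn_relu_forward(x)
  list(y = y, mask = y)          # y > 0 encodes the active set
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  nn_dropout_forward(x, rate)
}

upsample2_fwd <- function(x) nn_upsample2_forward(x)

upsample2_bwd <- function(gy) nn_upsample2_backward(gy)

concat_ch <- function(a, b) nn_concat_ch(a, b)

split_ch <- function(g, ca) nn_split_ch(g, as.integer(ca))

# ---- dynamic attention -----------------------------------------------------

att_init <- function(denc, ddec, cout) {
  dk <- denc
  mk <- function(nr, nc) matrix(rnorm(nr * nc, 0, 1 / sqrt(nc)), nr, nc)
  list(W_Q = mk(dk, ddec), W_K = mk(dk, denc), W_V = mk(dk, denc),
       W_o = mk(cout, dk + ddec), b_o = numeric(cout), dk = dk)
}

#' Dynamic attention refinement
#'
#' Scaled dot-product attention between a decoder state and the spatial
#' positions of an encoder feature map. The positions of `Hmap` form the
#' key/value sequence (one vector of channels per position); the aligned
#' decoder map `dmap` is global-average-pooled into the query state `d`.
#' Scores `S = Q K^T / sqrt(d_k)` are normalized row-wise by softmax into
#' weights `A`, the context `C = A V` is concatenated with `d`, projected
#' through `W_o`, and broadcast-added to `Hmap` as a per-channel refinement.
#'
#' @param Hmap encoder feature map, array `(H, W, C_enc, N)`.
#' @param dmap decoder feature map of the same spatial size,
#'   `(H, W, C_dec, N)`.
#' @param p attention weights (`W_Q`, `W_K`, `W_V`, `W_o`, `b_o`).
#' @return list with the refined map `y` and a cache for the backward pass.
#' @export
dynamic_attention <- function(Hmap, dmap, p) {
  d <- dim(Hmap)
  npos <- d[1] * d[2]
  N <- d[4]
  y <- Hmap
  per <- vector("list", N)
  for (n in seq_len(N)) {
    Hm <- matrix(Hmap[, , , n], npos)            # npos x denc
    dvec <- colMeans(matrix(dmap[, , , n], npos))
    Q <- p$W_Q %*% dvec                          # dk
    K <- Hm %*% t(p$W_K)                         # npos x dk
    V <- Hm %*% t(p$W_V)                         # npos x dk
    s <- as.numeric(K %*% Q) / sqrt(p$dk)
    a <- exp(s - max(s)); a <- a / sum(a)
    Cvec <- as.numeric(crossprod(V, a))
    z <- c(Cvec, dvec)
    o <- as.numeric(p$W_o %*% z + p$b_o)
    y[, , , n] <- Hmap[, , , n] + rep(o, each = npos)
    per[[n]] <- list(Hm = Hm, dvec = dvec, Q = Q, K = K, V = V, a = a, z = z)
  }
  list(y = y, per = per, dims = d, ddims = dim(dmap))
}

att_bwd <- function(cache, p, gy) {
  d <- cache$dims
  npos <- d[1] * d[2]
  N <- d[4]
  gH <- gy                                      # identity branch of the residual
  gD <- array(0, cache$ddims)
  gW_Q <- 0 * p$W_Q; gW_K <- 0 * p$W_K; gW_V <- 0 * p$W_V
  gW_o <- 0 * p$W_o; gb_o <- 0 * p$b_o
  dk <- p$dk
  ddec <- ncol(p$W_Q)
  for (n in seq_len(N)) {
    cc <- cache$per[[n]]
    go <- colSums(matrix(gy[, , , n], npos))    # broadcast add -> sum over positions
    gW_o <- gW_o + go %*% t(cc$z)
    gb_o <- gb_o + go
    gz <- as.numeric(crossprod(p$W_o, go))
    gC <- gz[seq_len(dk)]
    gd2 <- gz[dk + seq_len(ddec)]
    ga <- as.numeric(cc$V %*% gC)
    gV <- cc$a %*% t(gC)                        # npos x dk
    gs <- cc$a * (ga - sum(cc$a * ga))
    gQ <- as.numeric(crossprod(cc$K, gs)) / sqrt(dk)
    gK <- (gs %*% t(cc$Q)) / sqrt(dk)           # npos x dk
    gW_Q <- gW_Q + gQ %*% t(cc$dvec)
    gd1 <- as.numeric(crossprod(p$W_Q, gQ))
    gHm <- gK %*% p$W_K + gV %*% p$W_V
    gW_K <- gW_K + crossprod(gK, cc$Hm)
    gW_V <- gW_V + crossprod(gV, cc$Hm)
    gH[, , , n] <- gH[, , , n] + array(gHm, d[1:3])
    gd_vec <- (gd1 + gd2) / npos                # GAP backward
    gD[, , , n] <- gD[, , , n] + rep(gd_vec, each = npos)
  }
  list(gH = gH, gD = gD,
       grads = list(W_Q = gW_Q, W_K = gW_K, W_V = gW_V, W_o = gW_o, b_o = gb_o))
}

# ---- softmax + cross-entropy ----------------------------------------------

softmax_ch <- function(logits) {
  d <- dim(logits)
  C <- d[3]
  a <- array(logits, c(d[1] * d[2], C, d[4]))
  mx <- a[, 1, ]
  for (c in seq_len(C)[-1]) mx <- pmax(mx, a[, c, ])
  denom <- 0
  for (c in seq_len(C)) {
    a[, c, ] <- exp(a[, c, ] - mx)
    denom <- denom + a[, c, ]
  }
  for (c in seq_len(C)) a[, c, ] <- a[, c, ] / denom
  dim(a) <- d
  a
}

#' Pixel-wise cross-entropy loss on one-hot labels
#'
#' `L = -(1/(H*W)) * sum_{i,j,c} y_ijc * log p_ijc`, averaged over the batch.
#' Probabilities are clamped at 1e-12 inside the log; the loss is 0 exactly
#' when the predicted probability is 1 at every true class.
#'
#' @param probs array `(H, W, C, N)` of per-pixel class probabilities
#'   (channels sum to 1).
#' @param onehot array of the same shape with one-hot labels.
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, onehot) {
  abort_if(!identical(dim(probs), dim(onehot)), "shape mismatch")
  d <- dim(probs)
  -sum(onehot * log(pmax(probs, 1e-12))) / (d[1] * d[2]) / d[4]
}

#' One-hot encode a stack of binary label windows
#'
#' @param labels binary array `(s, s, N)`.
#' @return array `(s, s, 2, N)` with channel 1 = background, channel 2 = vessel.
#' @export
onehot_labels <- function(labels) {
  d <- dim(labels)
  out <- array(0, c(d[1], d[2], 2, d[3]))
  out[, , 1, ] <- 1 - labels
  out[, , 2, ] <- labels
  out
}
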