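#' Model configuration
#'
#' A lightweight U-Net: `depth` encoder stages of paired 3 x 3 convolutions
#' (batch norm + ReLU + 20% dropout) with 2 x 2 max pooling, a symmetric
#' decoder with 2 x 2 nearest-neighbor upsampling and skip concatenation,
#' and a 1 x 1 two-class softmax head. Dynamic attention can refine the
#' bottleneck alone or the bottleneck plus every skip connection.
#'
#' @param patch_size input side length `s` (must be divisible by `2^depth`).
#' @param depth number of pooling stages.
#' @param base_channels channels of the first encoder stage (doubled per
#'   stage).
#' @param dropout_rate dropout after each conv pair, in `[0, 1)`.
#' @param attention `"off"`, `"bottleneck"` or `"bottleneck_and_skips"`.
#' @return a `model_config`.
#' @export
model_config <- function(patch_size = 48L, depth = 4L, base_channels = 16L,
                         dropout_rate = 0.2,
                         attention = c("bottleneck_and_skips", "bottleneck", "off")) {
  attention <- match.arg(attention)
  abort_if(patch_size %% 2^depth != 0,
           "patch_size must be divisible by 2^depth")
  abort_if(dropout_rate < 0 || dropout_rate >= 1, "dropout_rate must be in [0, 1)")
  structure(list(patch_size = as.integer(patch_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dropout_rate = dropout_rate, attention = attention,
                 classes = 2L),
            class = "model_config")
}

# One conv(+BN) unit
unit_init <- function(cin, cout, k = 3) {
  list(conv = conv_init(cin, cout, k), bn = bn_init(cout))
}

#' Build a U-Net model
#'
#' Initializes all weights (He normal, seeded) and returns the model handle
#' together with its exact trainable parameter count.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return a `unet_model` with elements `cfg`, `params`, `n_parameters`.
#' @export
build_unet <- function(cfg = model_config(), seed = 1L) {
  D <- cfg$depth; B <- cfg$base_channels
  ch <- B * 2^(0:(D - 1))          # encoder stage channels
  cb <- B * 2^D                    # bottleneck channels
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    p$enc <- lapply(seq_len(D), function(i) {
      u <- list(u1 = unit_init(if (i == 1) 1L else ch[i - 1], ch[i]),
                u2 = unit_init(ch[i], ch[i]))
      u
    })
    p$bott <- list(u1 = unit_init(ch[D], cb), u2 = unit_init(cb, cb))
    p$dec <- lapply(seq_len(D), function(i) {
      above <- if (i == D) cb else ch[i + 1]
      list(up = unit_init(above, ch[i]),
           u1 = unit_init(2L * ch[i], ch[i]),
           u2 = unit_init(ch[i], ch[i]))
    })
    p$head <- conv_init(ch[1], cfg$classes, k = 1, gain = 1)
    if (cfg$attention != "off")
      p$att_bott <- att_init(cb, cb, cb)
    if (cfg$attention == "bottleneck_and_skips")
      p$att_skip <- lapply(seq_len(D), function(i) att_init(ch[i], ch[i], ch[i]))
    p
  })
  model <- structure(list(cfg = cfg, params = params), class = "unet_model")
  model$n_parameters <- count_parameters(model)
  model
}

# Trainable parameter names within a unit / the model, as flat lists.
trainable_names <- c("W", "b", "gamma", "beta", "W_Q", "W_K", "W_V", "W_o", "b_o")

walk_params <- function(x, f, path = character()) {
  for (nm in names(x)) {
    el <- x[[nm]]
    if (is.list(el)) walk_params(el, f, c(path, nm))
    else if (nm %in% trainable_names) f(c(path, nm), el)
  }
  if (is.null(names(x)) && is.list(x)) {
    for (i in seq_along(x)) walk_params(x[[i]], f, c(path, as.character(i)))
  }
  invisible(NULL)
}

#' Exact trainable parameter count of a model
#'
#' Counts convolution weights/biases, batch-norm scale/shift, and attention
#' projections (running statistics are not trainable).
#'
#' @param model a `unet_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  total <- 0
  walk_params(model$params, function(path, value) total <<- total + length(value))
  as.integer(total)
}

#' @export
print.unet_model <- function(x, ...) {
  cat("<unet_model> depth", x$cfg$depth, "| base", x$cfg$base_channels,
      "| attention:", x$cfg$attention, "|", x$n_parameters, "parameters\n")
  invisible(x)
}

# Conv -> BN -> ReLU unit forward/backward. Updates running BN stats via the
# returned cache (caller reassigns model params from cache$bn$p).
unit_fwd <- function(x, u, training) {
  cv <- conv_fwd(x, u$conv)
  bn <- bn_fwd(cv$y, u$bn, training)
  rl <- relu_fwd(bn$y)
  list(y = rl$y, cv = cv, bn = bn, mask = rl$mask)
}

unit_bwd <- function(cache, u, gy, need_gx = TRUE) {
  g <- nn_relu_backward(gy, cache$mask)
  gb <- bn_bwd(cache$bn, u$bn, g)
  gc <- conv_bwd(cache$cv, u$conv, gb$gx, need_gx)
  list(gx = gc$gx,
       grads = list(conv = list(W = gc$gW, b = gc$gb),
                    bn = list(gamma = gb$ggamma, beta = gb$gbeta)))
}

# Full forward pass. Returns probabilities; when training, also a cache for
# unet_backward() and BN running-stat updates folded into `model`.
unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg; p <- model$params
  D <- cfg$depth
  cache <- list(enc = vector("list", D), dec = vector("list", D))
  cur <- x
  for (i in seq_len(D)) {
    c1 <- unit_fwd(cur, p$enc[[i]]$u1, training)
    c2 <- unit_fwd(c1$y, p$enc[[i]]$u2, training)
    dp <- dropout_fwd(c2$y, cfg$dropout_rate, training)
    mp <- nn_maxpool(dp$y)
    cache$enc[[i]] <- list(c1 = c1, c2 = c2, dp = dp, mp = mp,
                           dims = dim(dp$y))
    p$enc[[i]]$u1$bn <- c1$bn$p; p$enc[[i]]$u2$bn <- c2$bn$p
    cur <- mp$y
  }
  b1 <- unit_fwd(cur, p$bott$u1, training)
  b2 <- unit_fwd(b1$y, p$bott$u2, training)
  bd <- dropout_fwd(b2$y, cfg$dropout_rate, training)
  p$bott$u1$bn <- b1$bn$p; p$bott$u2$bn <- b2$bn$p
  cur <- bd$y
  att_b <- NULL
  if (cfg$attention != "off") {
    att_b <- dynamic_attention(cur, cur, p$att_bott)
    cur <- att_b$y
  }
  cache$bott <- list(b1 = b1, b2 = b2, bd = bd, att = att_b)
  for (i in rev(seq_len(D))) {
    upin <- cur
    up <- unit_fwd(upsample2_fwd(upin), p$dec[[i]]$up, training)
    sk <- cache$enc[[i]]$dp$y
    att_s <- NULL
    if (cfg$attention == "bottleneck_and_skips") {
      att_s <- dynamic_attention(sk, up$y, p$att_skip[[i]])
      sk <- att_s$y
    }
    cat_ <- concat_ch(sk, up$y)
    d1 <- unit_fwd(cat_, p$dec[[i]]$u1, training)
    d2 <- unit_fwd(d1$y, p$dec[[i]]$u2, training)
    dp <- dropout_fwd(d2$y, cfg$dropout_rate, training)
    cache$dec[[i]] <- list(up = up, att = att_s, d1 = d1, d2 = d2, dp = dp,
                           up_in_dims = dim(upin), ca = dim(sk)[3])
    p$dec[[i]]$up$bn <- up$bn$p
    p$dec[[i]]$u1$bn <- d1$bn$p; p$dec[[i]]$u2$bn <- d2$bn$p
    cur <- dp$y
  }
  hd <- conv_fwd(cur, p$head)
  probs <- softmax_ch(hd$y)
  model$params <- p
  list(probs = probs, logits = hd$y, cache = c(cache, list(head = hd)),
       model = model)
}

# Backward pass from the softmax + cross-entropy gradient. `glogits` is the
# gradient of the loss w.r.t. the logits. Returns grads mirroring params.
unet_backward <- function(model, fw, glogits) {
  cfg <- model$cfg; p <- model$params
  D <- cfg$depth
  grads <- list(enc = vector("list", D), dec = vector("list", D))
  gh <- conv_bwd(fw$cache$head, p$head, glogits)
  grads$head <- list(W = gh$gW, b = gh$gb)
  g <- gh$gx
  for (i in seq_len(D)) {
    cc <- fw$cache$dec[[i]]
    if (!is.null(cc$dp$mask)) g <- nn_mask_mul(g, cc$dp$mask)
    g2 <- unit_bwd(cc$d2, p$dec[[i]]$u2, g)
    g1 <- unit_bwd(cc$d1, p$dec[[i]]$u1, g2$gx)
    sp <- split_ch(g1$gx, cc$ca)
    g_sk <- sp$a
    g_up <- sp$b
    if (cfg$attention == "bottleneck_and_skips") {
      ab <- att_bwd(cc$att, p$att_skip[[i]], g_sk)
      grads$att_skip[[i]] <- ab$grads
      g_sk <- ab$gH
      g_up <- g_up + ab$gD
    }
    gu <- unit_bwd(cc$up, p$dec[[i]]$up, g_up)
    grads$dec[[i]] <- list(up = gu$grads, u1 = g1$grads, u2 = g2$grads)
    # g_sk flows into the encoder skip; store for the encoder sweep
    fw$cache$enc[[i]]$g_skip <- g_sk
    g <- upsample2_bwd(gu$gx)
  }
  bc <- fw$cache$bott
  if (cfg$attention != "off") {
    ab <- att_bwd(bc$att, p$att_bott, g)
    grads$att_bott <- ab$grads
    g <- ab$gH + ab$gD                 # H and d are the same bottleneck map
  }
  if (!is.null(bc$bd$mask)) g <- nn_mask_mul(g, bc$bd$mask)
  g2 <- unit_bwd(bc$b2, p$bott$u2, g)
  g1 <- unit_bwd(bc$b1, p$bott$u1, g2$gx)
  grads$bott <- list(u1 = g1$grads, u2 = g2$grads)
  g <- g1$gx
  for (i in rev(seq_len(D))) {
    cc <- fw$cache$enc[[i]]
    gpool <- nn_maxpool_backward(g, cc$mp$idx, cc$dims[1], cc$dims[2],
                                 cc$dims[3], cc$dims[4])
    gd <- gpool + cc$g_skip
    if (!is.null(cc$dp$mask)) gd <- nn_mask_mul(gd, cc$dp$mask)
    g2 <- unit_bwd(cc$c2, p$enc[[i]]$u2, gd)
    g1 <- unit_bwd(cc$c1, p$enc[[i]]$u1, g2$gx, need_gx = i > 1)
    grads$enc[[i]] <- list(u1 = g1$grads, u2 = g2$grads)
    g <- g1$gx
  }
  grads
}

#' Predict vessel probabilities for a stack of patches
#'
#' Runs the model in inference mode (batch-norm running statistics, no
#' dropout) and returns the vessel-class channel of the softmax output.
#'
#' @param model a trained `unet_model`.
#' @param patches `s x s x n` array of image patches on the 8-bit scale, or
#'   a `patch_set`.
#' @param batch_size forward-pass batch size.
#' @return `s x s x n` array of vessel probabilities in `[0, 1]`.
#' @export
predict_patches <- function(model, patches, batch_size = 64L) {
  if (inherits(patches, "patch_set")) patches <- patches$images
  d <- dim(patches)
  abort_if(d[1] != model$cfg$patch_size || d[2] != model$cfg$patch_size,
           "patch shape does not match the model configuration")
  n <- d[3]
  out <- array(0, d)
  x <- scale_input(patches)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    xb <- array(x[, , idx], c(d[1], d[2], 1, length(idx)))
    fw <- unet_forward(model, xb, training = FALSE)
    out[, , idx] <- fw$probs[, , 2, ]
  }
  out
}

# Map 8-bit patch intensities to the unit interval for the network input.
scale_input <- function(patches) patches / 255
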