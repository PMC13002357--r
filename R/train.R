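#' Training configuration
#'
#' Defaults follow the standard protocol: 20 epochs of SGD with mini-batch
#' size 32, learning rate 0.1 and momentum 0.9.
#'
#' @param epochs number of passes over the training patches.
#' @param batch_size mini-batch size.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum in `[0, 1)`.
#' @param seed integer seed (weight init and epoch shuffling).
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 32L, learning_rate = 0.1,
                         momentum = 0.9, seed = 1L) {
  abort_if(epochs < 0 || batch_size <= 0 || learning_rate <= 0,
           "epochs, batch_size and learning_rate must be positive")
  abort_if(momentum < 0 || momentum >= 1, "momentum must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Recursive SGD + momentum update. `v` mirrors the gradient structure.
sgd_update <- function(p, g, v, lr, mom) {
  for (nm in names(g)) {
    if (is.list(g[[nm]])) {
      if (is.null(v[[nm]])) v[[nm]] <- list()
      r <- sgd_update(p[[nm]], g[[nm]], v[[nm]], lr, mom)
      p[[nm]] <- r$p; v[[nm]] <- r$v
    } else {
      vel <- if (is.null(v[[nm]])) 0 else v[[nm]]
      vel <- mom * vel - lr * g[[nm]]
      p[[nm]] <- p[[nm]] + vel
      v[[nm]] <- vel
    }
  }
  if (is.null(names(g))) {
    for (i in seq_along(g)) {
      if (length(v) < i || is.null(v[[i]])) v[[i]] <- list()
      r <- sgd_update(p[[i]], g[[i]], v[[i]], lr, mom)
      p[[i]] <- r$p; v[[i]] <- r$v
    }
  }
  list(p = p, v = v)
}

#' Train a U-Net on a patch set
#'
#' Stochastic gradient descent with momentum on the pixel-wise cross-entropy
#' loss over seeded, shuffled mini-batches. The same seed reproduces the
#' same loss trace on one platform.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param ps a `patch_set` with (possibly noisy) binary labels.
#' @param cfg a [train_config()].
#' @param prior_bias initialize the output-layer bias to the class log-odds
#'   of the training labels. This standard guard keeps small training sets
#'   from collapsing into the all-background solution early on; disable it
#'   when resuming from trained weights.
#' @return the trained model, with the per-epoch mean loss in `$loss_trace`.
#' @export
train_unet <- function(model, ps, cfg = train_config(), prior_bias = TRUE) {
  N <- n_patches(ps)
  abort_if(N == 0, "empty patch set")
  s <- model$cfg$patch_size
  x <- scale_input(ps$images)
  y <- onehot_labels(ps$labels)
  v <- list()
  trace <- numeric(cfg$epochs)
  if (cfg$epochs == 0) {
    model$loss_trace <- numeric(0)
    return(model)
  }
  if (prior_bias) {
    prior <- clamp(mean(ps$labels), 1e-6, 1 - 1e-6)
    model$params$head$b <- c(log(1 - prior), log(prior))
  }
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(stage_seed(cfg$seed, paste0("shuffle:", ep)), sample.int(N))
    losses <- c()
    set.seed(stage_seed(cfg$seed, paste0("dropout:", ep)))
    for (start in seq(1, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, N)]
      nb <- length(idx)
      xb <- array(x[, , idx], c(s, s, 1, nb))
      yb <- y[, , , idx, drop = FALSE]
      fw <- unet_forward(model, xb, training = TRUE)
      model <- fw$model                       # BN running stats
      losses <- c(losses, cross_entropy_loss(fw$probs, yb))
      glogits <- (fw$probs - yb) / (s * s * nb)
      grads <- unet_backward(model, fw, glogits)
      upd <- sgd_update(model$params, grads, v, cfg$learning_rate, cfg$momentum)
      model$params <- upd$p
      v <- upd$v
    }
    trace[ep] <- mean(losses)
  }
  model$loss_trace <- trace
  model
}
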