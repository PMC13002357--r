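#' Noise specification
#'
#' Describes one corruption condition: the noise level `lambda` (magnitude of
#' the positional deformation; 0 is the identity), the noise ratio `rho`
#' (fraction of label patches deformed), the corruption kind, and the seed.
#'
#' @param lambda noise level in `[0, 1]`; the canonical experimental grid is
#'   `c(0, 0.2, 0.4, 0.6, 0.8)`.
#' @param rho noise ratio in `[0, 1]`; canonical grid `c(0, 0.25, 0.5, 0.75, 1)`.
#' @param corruption one of `"nonlinear"`, `"gaussian"`, `"lowres"`,
#'   `"uniform_blur"`, `"fovea_blur"`, `"none"`.
#' @param direction_mode how the radial exponent is derived from `lambda`:
#'   `"zoom_in"` (`beta = 1 + lambda`), `"zoom_out"` (`beta = 1/(1 + lambda)`)
#'   or `"random"` (either, with equal probability per patch).
#' @param seed integer seed.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(lambda = 0, rho = 1,
                       corruption = c("nonlinear", "gaussian", "lowres",
                                      "uniform_blur", "fovea_blur", "none"),
                       direction_mode = c("zoom_in", "zoom_out", "random"),
                       seed = 1L) {
  corruption <- match.arg(corruption)
  direction_mode <- match.arg(direction_mode)
  abort_if(lambda < 0 || lambda > 1, "lambda must lie in [0, 1]")
  abort_if(rho < 0 || rho > 1, "rho must lie in [0, 1]")
  structure(list(lambda = lambda, rho = rho, corruption = corruption,
                 direction_mode = direction_mode, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Map a noise level to the deformation exponent beta
#'
#' `beta` controls the strength of the radial deformation: `beta > 1` zooms
#' the central region in, `beta < 1` zooms it out, `beta = 1` is the
#' identity. The level `lambda` is the deformation distance, mapped as
#' `beta = 1 + lambda` (zoom in), `beta = 1 / (1 + lambda)` (zoom out), or
#' one of the two chosen with equal probability (seeded) - only the
#' displacement magnitude matters for noise sensitivity, not its direction.
#'
#' @param lambda noise level (>= 0); 0 yields `beta = 1` in every mode.
#' @param direction `"zoom_in"`, `"zoom_out"` or `"random"`.
#' @param seed integer seed (used by `"random"` only).
#' @return positive scalar `beta`.
#' @export
beta_from_level <- function(lambda, direction = c("zoom_in", "zoom_out", "random"),
                            seed = 1L) {
  direction <- match.arg(direction)
  abort_if(lambda < 0, "lambda must be >= 0")
  if (lambda == 0) return(1)
  zin <- 1 + lambda
  switch(direction,
         zoom_in = zin,
         zoom_out = 1 / zin,
         random = if (with_seed(seed, runif(1)) < 0.5) zin else 1 / zin)
}

#' Build a radial deformation field
#'
#' For a square `s x s` patch with center `c` and radius `R = s / 2` (half
#' the side), every pixel at distance at most `R` from the center is
#' resampled from the source point at radius `r' = R * (r / R)^beta` along
#' the same ray: `p' = c + (r' / (r + eps)) * (p - c)`; pixels beyond `R` are left
#' untouched. The field stores the per-pixel offsets `delta_x = x' - x` and
#' `delta_y = y' - y`. Coordinates are 0-based pixel centers, so
#' `c = ((s-1)/2, (s-1)/2)`.
#'
#' @param patch_size side length `s` (>= 2).
#' @param beta radial exponent (> 0); 1 gives a (numerically) zero field.
#' @param eps small constant guarding the division at the center.
#' @return a `deformation_field` with matrices `delta_x`, `delta_y` (pixels).
#' @export
radial_field <- function(patch_size, beta, eps = 1e-8) {
  s <- as.integer(patch_size)
  abort_if(s < 2, "patch_size must be >= 2")
  abort_if(beta <= 0, "beta must be > 0")
  R <- s / 2
  ctr <- (s - 1) / 2
  x <- matrix(rep(0:(s - 1), each = s), s, s)   # column coordinate
  y <- matrix(rep(0:(s - 1), times = s), s, s)  # row coordinate
  dx <- x - ctr; dy <- y - ctr
  r <- sqrt(dx^2 + dy^2)
  rprime <- R * (r / R)^beta
  scale <- rprime / (r + eps)
  inside <- r <= R
  delta_x <- ifelse(inside, (scale - 1) * dx, 0)
  delta_y <- ifelse(inside, (scale - 1) * dy, 0)
  structure(list(delta_x = delta_x, delta_y = delta_y, beta = beta,
                 radius = R, eps = eps, patch_size = s),
            class = "deformation_field")
}

#' Warp a binary label window through a deformation field
#'
#' The output at each pixel `p` is the input sampled at `p' = p + delta`,
#' using nearest-neighbor sampling so the result stays binary. Source
#' coordinates falling outside the window read as background 0 (possible
#' only for `beta < 1`).
#'
#' @param label_window binary `s x s` matrix.
#' @param field a `deformation_field` of matching size.
#' @return binary `s x s` matrix.
#' @export
warp_label <- function(label_window, field) {
  s <- field$patch_size
  abort_if(!identical(dim(label_window), c(s, s)),
           "label window and field shapes differ")
  ctr <- (s - 1) / 2
  x <- matrix(rep(0:(s - 1), each = s), s, s)
  y <- matrix(rep(0:(s - 1), times = s), s, s)
  xs <- round_half_away(x + field$delta_x)  # nearest-neighbor source coords
  ys <- round_half_away(y + field$delta_y)
  out <- matrix(0, s, s)
  ok <- xs >= 0 & xs < s & ys >= 0 & ys < s
  out[ok] <- label_window[cbind(ys[ok] + 1, xs[ok] + 1)]
  out
}

# Box blur with edge replication via a summed-area table.
box_blur <- function(image, width) {
  if (width <= 1) return(image)
  h <- (width - 1) %/% 2
  H <- nrow(image); W <- ncol(image)
  padded <- image[clamp(seq(1 - h, H + h), 1, H), clamp(seq(1 - h, W + h), 1, W)]
  S <- sat(padded)
  r0 <- 0:(H - 1); c0 <- 0:(W - 1)
  grid <- expand.grid(r = r0, c = c0)
  matrix(window_sums(S, grid$r, grid$c, width) / width^2, H, W)
}

#' Apply a baseline image corruption
#'
#' The four image-level corruptions used in the noise-type ablation:
#' \describe{
#'   \item{gaussian}{additive zero-mean noise, `sd = lambda * 25` gray levels.}
#'   \item{lowres}{bilinear downsampling by factor `1 + 3 * lambda`, then
#'     bilinear upsampling back to the original size.}
#'   \item{uniform_blur}{box blur with kernel width `1 + 2 * round(4 * lambda)`.}
#'   \item{fovea_blur}{the same box blur, blended in only over the central
#'     disc of radius `min(H, W) / 4` with a smooth radial weight.}
#' }
#' `lambda = 0` is the identity for every kind. Corruption strengths are
#' package conventions (the ablation defines the kinds, not the scales).
#'
#' @param image numeric matrix on the 8-bit scale.
#' @param kind corruption kind.
#' @param lambda strength in `[0, 1]`.
#' @param seed integer seed (gaussian noise).
#' @return corrupted image, clipped to `[0, 255]`.
#' @export
corrupt_image <- function(image, kind = c("gaussian", "lowres", "uniform_blur",
                                          "fovea_blur"),
                          lambda, seed = 1L) {
  kind <- match.arg(kind)
  abort_if(lambda < 0 || lambda > 1, "lambda must lie in [0, 1]")
  if (lambda == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  out <- switch(kind,
    gaussian = image + with_seed(seed, matrix(rnorm(H * W, 0, lambda * 25), H, W)),
    lowres = {
      f <- 1 + 3 * lambda
      small <- EBImage::resize(EBImage::Image(t(image / 255)),
                               w = max(2, round(W / f)), h = max(2, round(H / f)))
      big <- EBImage::resize(small, w = W, h = H)
      t(EBImage::imageData(big)) * 255
    },
    uniform_blur = box_blur(image, 1 + 2 * round_half_away(4 * lambda)),
    fovea_blur = {
      blurred <- box_blur(image, 1 + 2 * round_half_away(4 * lambda))
      R <- min(H, W) / 4
      rr <- sqrt(outer((seq_len(H) - (H + 1) / 2)^2,
                       (seq_len(W) - (W + 1) / 2)^2, "+"))
      wgt <- pmax(0, 1 - rr / R)   # 1 at the center, 0 beyond radius R
      image * (1 - wgt) + blurred * wgt
    })
  clamp(out, 0, 255)
}

#' Mix clean and noisy labels at a given ratio
#'
#' Selects exactly `round(rho * N)` patches uniformly without replacement
#' (seeded) and replaces their labels by the radial deformation at level
#' `lambda` (per-patch `beta` via [beta_from_level()], seeded per patch);
#' the remaining labels stay clean. The returned `patch_set` carries noise
#' flags recording the selection.
#'
#' @param ps a `patch_set`.
#' @param spec a [noise_spec()] (uses `lambda`, `rho`, `direction_mode`, `seed`).
#' @return a `patch_set` with noisy labels and updated `noisy` flags.
#' @export
mix_labels <- function(ps, spec) {
  N <- n_patches(ps)
  k <- round(spec$rho * N)
  if (k == 0) return(ps)
  sel <- with_seed(stage_seed(spec$seed, "mix"), sample.int(N, k))
  labels <- ps$labels
  for (i in sel) {
    beta <- beta_from_level(spec$lambda, spec$direction_mode,
                            seed = stage_seed(spec$seed, paste0("beta:", i)))
    if (beta != 1) {
      field <- radial_field(ps$patch_size, beta)
      labels[, , i] <- warp_label(ps$labels[, , i], field)
    }
  }
  noisy <- ps$noisy
  noisy[sel] <- TRUE
  patch_set(ps$images, labels, ps$origins, noisy)
}

#' Drop noise-flagged patches
#'
#' The label-cleaning arm: keeps only patches whose labels were never
#' noise-injected.
#'
#' @param ps a `patch_set` with noise flags.
#' @return a `patch_set` of the clean subset.
#' @export
remove_noisy <- function(ps) {
  keep <- !ps$noisy
  abort_if(!any(keep), "no clean patches remain")
  subset_patches(ps, keep)
}
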