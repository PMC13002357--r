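#' Patch sampling configuration
#'
#' Defaults reproduce the standard protocol: 2200 overlapping 48 x 48
#' patches per training image, 80% drawn uniformly and 20% from the
#' small-vessel pool (label windows with 1-200 vessel pixels), and stride-10
#' overlapping tiling at test time.
#'
#' @param patches_per_image number of training patches per image.
#' @param patch_size side length `s` of the square patches.
#' @param random_fraction fraction `P` of patches drawn uniformly; the rest
#'   are drawn from the small-vessel pool.
#' @param small_vessel_bound upper bound on white pixels for a patch to count
#'   as a small-vessel patch.
#' @param test_stride stride for overlapping test tiling.
#' @param include_empty if `TRUE`, windows with zero vessel pixels also
#'   qualify for the small-vessel pool (literal 0-200 reading); the default
#'   requires at least one vessel pixel.
#' @return a `sampling_config` list. Rotation angles are fixed at
#'   90/180/270 degrees (see [rotate_augment()]).
#' @export
sampling_config <- function(patches_per_image = 2200L, patch_size = 48L,
                            random_fraction = 0.8, small_vessel_bound = 200L,
                            test_stride = 10L, include_empty = FALSE) {
  abort_if(patch_size < 1 || test_stride < 1, "patch size and stride must be positive")
  abort_if(random_fraction < 0 || random_fraction > 1,
           "random_fraction must lie in [0, 1]")
  abort_if(small_vessel_bound < 0, "small_vessel_bound must be >= 0")
  structure(list(patches_per_image = as.integer(patches_per_image),
                 patch_size = as.integer(patch_size),
                 random_fraction = random_fraction,
                 small_vessel_bound = as.integer(small_vessel_bound),
                 test_stride = as.integer(test_stride),
                 include_empty = isTRUE(include_empty)),
            class = "sampling_config")
}

#' Count white (vessel) pixels in a binary label window
#'
#' @param label_window binary matrix.
#' @return integer count of 1-pixels.
#' @export
count_white <- function(label_window) {
  abort_if(!is_binary(label_window), "label window must be binary {0,1}")
  sum(label_window)
}

#' Is a label window a small-vessel patch?
#'
#' True when the window holds between 1 and `bound` vessel pixels (an empty
#' window contains no vessel to oversample; set `include_empty = TRUE` for
#' the literal 0-`bound` range).
#'
#' @param label_window binary matrix.
#' @param bound upper white-pixel bound (default 200).
#' @param include_empty include zero-pixel windows.
#' @return logical.
#' @export
is_small_vessel_patch <- function(label_window, bound = 200L,
                                  include_empty = FALSE) {
  n <- count_white(label_window)
  lower <- if (include_empty) 0L else 1L
  n >= lower && n <= bound
}

# Summed-area table with a leading zero row/col, so window sums are O(1).
sat <- function(m) {
  s <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed double cumsum
  s <- t(s)
  rbind(0, cbind(0, s))
}

# Sum of each s x s window at 0-based origins (r, c): vectors.
window_sums <- function(S, r, c, s) {
  S[cbind(r + s + 1, c + s + 1)] - S[cbind(r + 1, c + s + 1)] -
    S[cbind(r + s + 1, c + 1)] + S[cbind(r + 1, c + 1)]
}

# All 0-based origins whose s x s window lies entirely inside the FOV,
# together with the white-pixel count of the label window at each.
valid_origins <- function(sample, s) {
  H <- nrow(sample$fov_mask); W <- ncol(sample$fov_mask)
  abort_if(H < s || W < s, "image smaller than the patch size")
  Sf <- sat(sample$fov_mask)
  Sv <- sat(sample$vessel_mask)
  grid <- expand.grid(r = 0:(H - s), c = 0:(W - s))
  fov_ok <- window_sums(Sf, grid$r, grid$c, s) == s * s
  grid <- grid[fov_ok, , drop = FALSE]
  abort_if(nrow(grid) == 0, "no patch position lies fully inside the FOV")
  grid$white <- window_sums(Sv, grid$r, grid$c, s)
  grid
}

# Gather s x s windows at 0-based origins from a matrix into an s x s x n array.
gather_patches <- function(m, r, c, s) {
  H <- nrow(m)
  n <- length(r)
  off <- as.vector(outer(seq_len(s), (seq_len(s) - 1) * H, "+"))  # window offsets
  base <- c * H + r                                     # linear index of origin - 1
  idx <- as.vector(outer(off, base, "+"))  # plain vector: a 2-column index
                                           # matrix would be read as (row, col)
  array(m[idx], dim = c(s, s, n))
}

#' Create a patch set
#'
#' @param images `s x s x n` array of image windows.
#' @param labels `s x s x n` binary array of label windows.
#' @param origins data frame with columns `sample_id`, `row`, `col` (0-based
#'   top-left corners).
#' @param noisy optional logical vector flagging noise-injected labels.
#' @return a `patch_set`.
#' @export
patch_set <- function(images, labels, origins, noisy = NULL) {
  s <- dim(images)[1]
  abort_if(dim(images)[2] != s || !identical(dim(images), dim(labels)),
           "image and label windows must be square with identical dims")
  abort_if(!is_binary(labels), "labels must be binary")
  n <- dim(images)[3]
  abort_if(nrow(origins) != n, "origins must have one row per patch")
  if (is.null(noisy)) noisy <- rep(FALSE, n)
  structure(list(images = images, labels = labels, origins = origins,
                 noisy = noisy, patch_size = s),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set>", n_patches(x), "patches of", x$patch_size, "x",
      x$patch_size, "|", sum(x$noisy), "flagged noisy\n")
  invisible(x)
}

#' Number of patches in a patch set
#' @param ps a `patch_set`.
#' @return integer.
#' @export
n_patches <- function(ps) dim(ps$images)[3]

#' Concatenate patch sets
#' @param ... `patch_set` objects with equal patch size.
#' @return a single `patch_set`.
#' @export
bind_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "patch_set"))
    sets <- sets[[1]]
  s <- sets[[1]]$patch_size
  abort_if(!all(vapply(sets, function(x) x$patch_size, 0L) == s),
           "patch sizes differ")
  patch_set(
    images = array(unlist(lapply(sets, `[[`, "images")),
                   dim = c(s, s, sum(vapply(sets, n_patches, 0L)))),
    labels = array(unlist(lapply(sets, `[[`, "labels")),
                   dim = c(s, s, sum(vapply(sets, n_patches, 0L)))),
    origins = do.call(rbind, lapply(sets, `[[`, "origins")),
    noisy = unlist(lapply(sets, `[[`, "noisy"))
  )
}

#' Subset a patch set
#' @param ps a `patch_set`.
#' @param idx integer or logical index.
#' @return a `patch_set` with the selected patches.
#' @export
subset_patches <- function(ps, idx) {
  patch_set(ps$images[, , idx, drop = FALSE], ps$labels[, , idx, drop = FALSE],
            ps$origins[idx, , drop = FALSE], ps$noisy[idx])
}

#' Estimate the small-vessel patch fraction of an image
#'
#' Uniformly samples `n_probe` FOV-interior patch positions and returns the
#' fraction whose label windows qualify as small-vessel patches. This is the
#' per-dataset estimate `f` feeding [solve_balance_fraction()].
#'
#' @param sample a [fundus_sample()].
#' @param cfg a [sampling_config()].
#' @param n_probe number of probe patches (default 1000).
#' @param seed integer seed.
#' @return estimated fraction in `[0, 1]`.
#' @export
estimate_small_vessel_fraction <- function(sample, cfg = sampling_config(),
                                           n_probe = 1000L, seed = 1L) {
  g <- valid_origins(sample, cfg$patch_size)
  pick <- with_seed(seed, sample.int(nrow(g), n_probe, replace = TRUE))
  w <- g$white[pick]
  lower <- if (cfg$include_empty) 0L else 1L
  mean(w >= lower & w <= cfg$small_vessel_bound)
}

#' Solve the oversampling balance equation
#'
#' Given a source small-vessel fraction `f` among uniformly drawn patches and
#' a target fraction `g` for the mixed pool, returns the uniform share `P`
#' solving `f * P + (1 - P) = g`, i.e. `P = (1 - g) / (1 - f)`, clamped to
#' `[0, 1]`. With `f = 0.37` and target `0.5` this gives `P ~ 0.794`,
#' conventionally rounded to 0.8.
#'
#' @param source_fraction `f`, in `[0, 1)`.
#' @param target `g`, with `f <= g <= 1`.
#' @return `P` in `[0, 1]`.
#' @export
solve_balance_fraction <- function(source_fraction, target = 0.5) {
  abort_if(source_fraction >= 1 || source_fraction < 0,
           "source fraction must lie in [0, 1)")
  abort_if(target < source_fraction || target > 1,
           "target must lie in [source_fraction, 1]")
  clamp((1 - target) / (1 - source_fraction), 0, 1)
}

#' Extract balanced training patches from one sample
#'
#' Draws `floor(P * n)` patches uniformly (with replacement) over all
#' FOV-interior positions and the remaining `n - floor(P * n)` uniformly over
#' positions whose label windows are small-vessel patches. Every patch lies
#' fully inside the FOV.
#'
#' @param sample a [fundus_sample()] (typically preprocessed).
#' @param cfg a [sampling_config()].
#' @param seed integer seed.
#' @param fallback_uniform if the small-vessel pool is empty, reallocate its
#'   share to uniform sampling (with a warning) instead of erroring.
#' @return a `patch_set` of exactly `cfg$patches_per_image` patches.
#' @export
extract_training_patches <- function(sample, cfg = sampling_config(), seed = 1L,
                                     fallback_uniform = FALSE) {
  s <- cfg$patch_size
  n <- cfg$patches_per_image
  g <- valid_origins(sample, s)
  lower <- if (cfg$include_empty) 0L else 1L
  pool <- which(g$white >= lower & g$white <= cfg$small_vessel_bound)
  n_rand <- floor(cfg$random_fraction * n)
  n_small <- n - n_rand
  if (n_small > 0 && length(pool) == 0) {
    abort_if(!fallback_uniform,
             "small-vessel pool is empty; rerun with fallback_uniform = TRUE")
    warning("small-vessel pool empty: reallocating ", n_small,
            " patches to uniform sampling", call. = FALSE)
    n_rand <- n; n_small <- 0
  }
  idx <- with_seed(seed, {
    c(sample.int(nrow(g), n_rand, replace = TRUE),
      if (n_small > 0) pool[sample.int(length(pool), n_small, replace = TRUE)])
  })
  r <- g$r[idx]; c <- g$c[idx]
  patch_set(
    images = gather_patches(sample$image, r, c, s),
    labels = gather_patches(sample$vessel_mask, r, c, s),
    origins = data.frame(sample_id = sample$sample_id, row = r, col = c,
                         stringsAsFactors = FALSE)
  )
}

# Rotate an s x s x n array by k * 90 degrees counter-clockwise, exactly.
rot90_stack <- function(a, k) {
  k <- k %% 4
  if (k == 0) return(a)
  s <- dim(a)[1]
  for (i in seq_len(k)) a <- aperm(a, c(2, 1, 3))[s:1, , , drop = FALSE]
  a
}

#' Quadruple a patch set by 90/180/270-degree rotations
#'
#' Exact array rotations (no interpolation); image and label windows are
#' rotated identically and noise flags are carried over.
#'
#' @param ps a `patch_set` of square patches.
#' @return a `patch_set` of four times the size (originals first).
#' @export
rotate_augment <- function(ps) {
  sets <- lapply(0:3, function(k) {
    patch_set(rot90_stack(ps$images, k), rot90_stack(ps$labels, k),
              ps$origins, ps$noisy)
  })
  bind_patch_sets(sets)
}

#' Tile an image into overlapping test patches
#'
#' Zero-pads the image on the bottom/right so the stride grid covers it
#' exactly, and returns every grid patch plus the layout needed by
#' [recombine()]. `stride = patch_size` reproduces seamless tiling.
#'
#' @param image numeric matrix.
#' @param cfg a [sampling_config()] (uses `patch_size` and `test_stride`).
#' @return list with `layout` (a `tile_layout`) and `patches`
#'   (`s x s x n` array).
#' @export
tile_test_patches <- function(image, cfg = sampling_config()) {
  s <- cfg$patch_size; st <- cfg$test_stride
  abort_if(st > s, "stride greater than patch size would leave coverage gaps")
  H <- nrow(image); W <- ncol(image)
  Hp <- if (H <= s) s else s + st * ceiling((H - s) / st)
  Wp <- if (W <= s) s else s + st * ceiling((W - s) / st)
  padded <- matrix(0, Hp, Wp)
  padded[1:H, 1:W] <- image
  org <- expand.grid(r = seq(0, Hp - s, by = st), c = seq(0, Wp - s, by = st))
  layout <- structure(list(shape = c(H, W), padded_shape = c(Hp, Wp),
                           origins = org, stride = st, patch_size = s),
                      class = "tile_layout")
  list(layout = layout, patches = gather_patches(padded, org$r, org$c, s))
}

#' Recombine overlapping patch predictions by averaging
#'
#' Each output pixel is the arithmetic mean of every patch prediction
#' covering it; bottom/right padding is cropped away.
#'
#' @param patch_probs `s x s x n` array of per-patch probability rasters,
#'   one per layout origin.
#' @param layout the `tile_layout` from [tile_test_patches()].
#' @return full-frame probability matrix in `[0, 1]`.
#' @export
recombine <- function(patch_probs, layout) {
  s <- layout$patch_size
  org <- layout$origins
  abort_if(dim(patch_probs)[3] != nrow(org),
           "need exactly one probability raster per layout origin")
  Hp <- layout$padded_shape[1]; Wp <- layout$padded_shape[2]
  acc <- matrix(0, Hp, Wp); cnt <- matrix(0, Hp, Wp)
  for (i in seq_len(nrow(org))) {
    ri <- (org$r[i] + 1):(org$r[i] + s)
    ci <- (org$c[i] + 1):(org$c[i] + s)
    acc[ri, ci] <- acc[ri, ci] + patch_probs[, , i]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  out <- acc / cnt
  out[1:layout$shape[1], 1:layout$shape[2], drop = FALSE]
}
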