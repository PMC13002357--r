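#' Preprocessing configuration
#'
#' Defaults follow the pipeline's tuned setting: gamma 1.6 with CLAHE clip
#' limit 2.0 on an 8 x 8 tile grid.
#'
#' @param grayscale_mode `"luma"` (ITU-R 601 weights 0.299/0.587/0.114) or
#'   `"green_channel"` (vessel information in fundus photographs is largely
#'   confined to the green channel).
#' @param gamma gamma adjustment exponent parameter (> 0); values above 1
#'   brighten dark areas.
#' @param clahe_clip CLAHE clip limit `c` (> 0), a multiple of the average
#'   histogram bin height.
#' @param clahe_tiles CLAHE tile grid size `t` per dimension (>= 1).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(grayscale_mode = c("luma", "green_channel"),
                              gamma = 1.6, clahe_clip = 2.0, clahe_tiles = 8L) {
  grayscale_mode <- match.arg(grayscale_mode)
  abort_if(gamma <= 0, "gamma must be > 0")
  abort_if(clahe_clip <= 0, "clahe_clip must be > 0")
  abort_if(clahe_tiles < 1, "clahe_tiles must be >= 1")
  structure(list(grayscale_mode = grayscale_mode, gamma = gamma,
                 clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles)),
            class = "preprocess_config")
}

# ITU-R 601 luma weights
.LUMA <- c(0.299, 0.587, 0.114)

#' Convert an image to one grayscale channel
#'
#' @param image H x W matrix (passed through) or H x W x 3 array on the
#'   8-bit scale.
#' @param mode `"luma"` or `"green_channel"`.
#' @return numeric H x W matrix in `[0, 255]`.
#' @export
to_grayscale <- function(image, mode = c("luma", "green_channel")) {
  mode <- match.arg(mode)
  d <- dim(image)
  if (length(d) == 2) return(image)
  abort_if(length(d) != 3 || d[3] != 3,
           "image must have 1 or 3 channels")
  if (mode == "green_channel") image[, , 2]
  else .LUMA[1] * image[, , 1] + .LUMA[2] * image[, , 2] + .LUMA[3] * image[, , 3]
}

#' Z-score normalize a raster
#'
#' Subtracts the mean of all pixels and divides by the population standard
#' deviation, yielding mean 0 and population SD 1.
#'
#' @param gray numeric matrix.
#' @return numeric matrix with zero mean, unit population SD.
#' @export
zscore_normalize <- function(gray) {
  abort_if(length(gray) == 0, "empty raster")
  mu <- mean(gray)
  sigma <- sqrt(mean((gray - mu)^2))
  abort_if(sigma == 0, "constant raster: population SD is 0, cannot normalize")
  (gray - mu) / sigma
}

#' Rescale a real-valued raster to the 8-bit range
#'
#' Affine min-max map onto `[0, 255]`, rounded half away from zero. Bridges
#' the real-valued normalized raster and CLAHE, which operates on 8-bit
#' histograms.
#'
#' @param x numeric matrix with at least two distinct values.
#' @return integer-valued matrix in `[0, 255]`.
#' @export
rescale_to_8bit <- function(x) {
  rng <- range(x)
  abort_if(rng[1] == rng[2], "all-equal raster cannot be min-max rescaled")
  round_half_away((x - rng[1]) / (rng[2] - rng[1]) * 255)
}

# Tile mapping tables for CLAHE: 256 x (t*t) matrix of output gray levels.
clahe_tile_maps <- function(gray, clip, tiles) {
  H <- nrow(gray); W <- ncol(gray); t <- tiles
  re <- round(seq(0, H, length.out = t + 1))
  ce <- round(seq(0, W, length.out = t + 1))
  maps <- matrix(0, 256, t * t)
  for (i in seq_len(t)) {
    for (j in seq_len(t)) {
      tile <- gray[(re[i] + 1):re[i + 1], (ce[j] + 1):ce[j + 1]]
      npix <- length(tile)
      h <- tabulate(tile + 1, nbins = 256)
      # clip limit is a multiple of the average bin height; excess mass is
      # redistributed uniformly over all 256 bins in one pass
      lim <- max(1, clip * npix / 256)
      excess <- sum(pmax(h - lim, 0))
      h <- pmin(h, lim) + excess / 256
      cdf <- cumsum(h) / npix
      maps[, (i - 1) * t + j] <- round_half_away(255 * cdf)
    }
  }
  list(maps = maps, row_edges = re, col_edges = ce)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a `tiles` x `tiles` grid; a 256-bin histogram is
#' computed per tile, bins are capped at `clip` times the average bin height,
#' the clipped excess is redistributed uniformly over all bins in one pass,
#' and each tile's equalization mapping is blended bilinearly between
#' neighboring tile centers to suppress block artifacts.
#'
#' @param gray integer-valued matrix in `[0, 255]`.
#' @param clip clip limit `c` (> 0).
#' @param tiles tile grid size `t` per dimension.
#' @return integer-valued matrix in `[0, 255]` with the same dimensions.
#' @export
clahe <- function(gray, clip = 2.0, tiles = 8L) {
  H <- nrow(gray); W <- ncol(gray); t <- as.integer(tiles)
  abort_if(H < t || W < t, "image smaller than the tile grid")
  abort_if(clip <= 0, "clip must be > 0")
  tm <- clahe_tile_maps(gray, clip, t)
  # tile centers along each axis
  rc <- (tm$row_edges[-1] + tm$row_edges[-(t + 1)]) / 2
  cc <- (tm$col_edges[-1] + tm$col_edges[-(t + 1)]) / 2
  # for each pixel coordinate find bracketing tile indices + weights
  interp_index <- function(pos, centers) {
    lo <- findInterval(pos, centers)
    lo <- clamp(lo, 1, length(centers))        # below first center -> clamp
    hi <- clamp(lo + 1, 1, length(centers))
    lo <- ifelse(pos < centers[1], 1, lo)
    w <- ifelse(hi == lo, 0,
                (pos - centers[lo]) / (centers[hi] - centers[lo]))
    w <- clamp(w, 0, 1)
    list(lo = lo, hi = hi, w = w)
  }
  ry <- interp_index(seq_len(H) - 0.5, rc)
  cx <- interp_index(seq_len(W) - 0.5, cc)
  v <- as.integer(gray) + 1L                     # gray level -> map row
  rlo <- rep(ry$lo, W); rhi <- rep(ry$hi, W); rw <- rep(ry$w, W)
  clo <- rep(cx$lo, each = H); chi <- rep(cx$hi, each = H)
  cw <- rep(cx$w, each = H)
  tilecol <- function(ri, ci) (ri - 1L) * t + ci
  m <- tm$maps
  look <- function(ri, ci) m[cbind(v, tilecol(ri, ci))]
  out <- (1 - rw) * ((1 - cw) * look(rlo, clo) + cw * look(rlo, chi)) +
         rw       * ((1 - cw) * look(rhi, clo) + cw * look(rhi, chi))
  matrix(round_half_away(out), H, W)
}

#' Gamma adjustment
#'
#' Applies the tone curve `J = 255 * (I / 255)^(1 / gamma)`, rounded half
#' away from zero. For `gamma > 1` the exponent `1/gamma < 1` brightens dark
#' areas while compressing highlights; 0 and 255 are fixed points.
#'
#' @param gray integer-valued matrix in `[0, 255]`.
#' @param gamma positive exponent parameter.
#' @return integer-valued matrix in `[0, 255]`.
#' @export
gamma_adjust <- function(gray, gamma) {
  abort_if(gamma <= 0, "gamma must be > 0")
  round_half_away(255 * (gray / 255)^(1 / gamma))
}

#' Run the full preprocessing pipeline on a sample
#'
#' Applies, in order: grayscale conversion, z-score normalization, min-max
#' rescale to 8-bit, CLAHE, gamma adjustment. Masks are never modified.
#'
#' @param sample a [fundus_sample()].
#' @param cfg a [preprocess_config()].
#' @return the sample with its image replaced by the preprocessed raster.
#' @export
preprocess_sample <- function(sample, cfg = preprocess_config()) {
  stage <- function(name, f) {
    function(x) tryCatch(f(x), error = function(e)
      stop("preprocess stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  x <- stage("grayscale", function(x) to_grayscale(x, cfg$grayscale_mode))(sample$image)
  x <- stage("normalize", zscore_normalize)(x)
  x <- stage("rescale", rescale_to_8bit)(x)
  x <- stage("clahe", function(x) clahe(x, cfg$clahe_clip, cfg$clahe_tiles))(x)
  x <- stage("gamma", function(x) gamma_adjust(x, cfg$gamma))(x)
  sample$image <- x
  sample
}
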