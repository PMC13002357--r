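#' Synthetic fundus configuration
#'
#' Parameters of the seeded synthetic fundus generator: a circular FOV on a
#' dark surround, a brighter textured background with radial illumination
#' falloff, and dark branching vessel trees whose widths span capillaries
#' (~1 px) to trunks (~8 px), with the exact rasterized support as ground
#' truth.
#'
#' @param image_size `(H, W)` in pixels; each must be at least twice the
#'   patch size in use.
#' @param n_trees number of vessel trees rooted near the FOV border.
#' @param trunk_width trunk width in pixels.
#' @param min_width minimum vessel width in pixels (capillaries).
#' @param branch_decay per-generation width multiplier in `(0, 1)`.
#' @param vessel_contrast intensity drop of vessels below background
#'   (8-bit units).
#' @param illumination_gradient relative radial illumination falloff in
#'   `[0, 1)`.
#' @param background_noise_sd SD of additive background texture noise.
#' @param fov_margin gap between the FOV disc and the frame border (px).
#' @param light_reflex add a bright 1-px central reflex ridge along trunks.
#' @param seed integer seed.
#' @return a `synth_config`.
#' @export
synth_config <- function(image_size = c(160L, 160L), n_trees = 2L,
                         trunk_width = 8, min_width = 1, branch_decay = 0.55,
                         vessel_contrast = 60, illumination_gradient = 0.3,
                         background_noise_sd = 6, fov_margin = 4L,
                         light_reflex = FALSE, seed = 1L) {
  abort_if(min_width < 1, "min_width must be >= 1")
  abort_if(trunk_width < min_width, "trunk_width must be >= min_width")
  abort_if(branch_decay <= 0 || branch_decay >= 1,
           "branch_decay must lie in (0, 1)")
  structure(list(image_size = as.integer(image_size), n_trees = as.integer(n_trees),
                 trunk_width = trunk_width, min_width = min_width,
                 branch_decay = branch_decay, vessel_contrast = vessel_contrast,
                 illumination_gradient = illumination_gradient,
                 background_noise_sd = background_noise_sd,
                 fov_margin = as.integer(fov_margin),
                 light_reflex = isTRUE(light_reflex), seed = as.integer(seed)),
            class = "synth_config")
}

# Midpoint-displaced polyline between two points (wiggly vessel centerline).
wiggle_path <- function(p0, p1, n_levels = 4, amp = 0.18) {
  pts <- rbind(p0, p1)
  for (lev in seq_len(n_levels)) {
    out <- pts[1, , drop = FALSE]
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      mid <- (a + b) / 2
      d <- b - a
      nrm <- c(-d[2], d[1])
      mid <- mid + nrm * rnorm(1, 0, amp / lev)
      out <- rbind(out, mid, b)
    }
    pts <- out
  }
  pts
}

# Stamp a polyline of the given width onto mask/ridge matrices.
# Width-exact rasterization: a pixel is vessel iff its center lies within
# width/2 of the (densely sampled) centerline.
stamp_path <- function(mask, ridge, pts, width) {
  H <- nrow(mask); W <- ncol(mask)
  # densify: one sample every ~0.4 px
  dens <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2, ceiling(len / 0.4)))
    dens[[i]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  dens <- do.call(rbind, dens)
  rad <- width / 2
  ir <- ceiling(rad)
  off <- expand.grid(dr = -ir:ir, dc = -ir:ir)
  off <- off[off$dr^2 + off$dc^2 <= rad^2, , drop = FALSE]
  rows <- round(rep(dens[, 1], each = nrow(off))) + off$dr
  cols <- round(rep(dens[, 2], each = nrow(off))) + off$dc
  ok <- rows >= 1 & rows <= H & cols >= 1 & cols <= W
  mask[cbind(rows[ok], cols[ok])] <- 1
  if (!is.null(ridge) && width >= 4) {
    rr <- round(dens[, 1]); cc <- round(dens[, 2])
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    ridge[cbind(rr[ok], cc[ok])] <- 1
  }
  list(mask = mask, ridge = ridge)
}

# Recursively grow one vessel tree from a root point and direction.
grow_tree <- function(mask, ridge, p0, dir, width, len, cfg, depth = 0) {
  if (width < cfg$min_width || len < 7 || depth > 4)
    return(list(mask = mask, ridge = ridge))
  p1 <- p0 + dir * len
  pts <- wiggle_path(p0, p1, amp = 0.12 * len / 4)
  st <- stamp_path(mask, ridge, pts, width)
  mask <- st$mask; ridge <- st$ridge
  n_children <- if (width > 3) 2L else 1L
  for (k in seq_len(n_children)) {
    ang <- atan2(dir[1], dir[2]) + rnorm(1, 0, 0.5)
    child_dir <- c(sin(ang), cos(ang))
    res <- grow_tree(mask, ridge, p1, child_dir,
                     width * cfg$branch_decay * runif(1, 0.85, 1.05),
                     len * runif(1, 0.55, 0.75), cfg, depth + 1)
    mask <- res$mask; ridge <- res$ridge
  }
  list(mask = mask, ridge = ridge)
}

#' Generate one synthetic fundus sample
#'
#' Dark branching vessel trees on a brighter textured background with radial
#' illumination falloff, restricted to a centered circular FOV; the binary
#' vessel mask is the exact rasterized support. Deterministic given the
#' config seed.
#'
#' @param cfg a [synth_config()].
#' @param sample_id identifier for the sample.
#' @return a [fundus_sample()].
#' @export
generate_sample <- function(cfg = synth_config(), sample_id = "synth_01") {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  R <- min(H, W) / 2 - cfg$fov_margin
  rr <- sqrt(outer((seq_len(H) - ctr[1])^2, (seq_len(W) - ctr[2])^2, "+"))
  fov <- (rr <= R) * 1
  with_seed(cfg$seed, {
    mask <- matrix(0, H, W)
    ridge <- if (cfg$light_reflex) matrix(0, H, W) else NULL
    for (k in seq_len(cfg$n_trees)) {
      ang0 <- runif(1, 0, 2 * pi)
      root <- ctr + 0.85 * R * c(sin(ang0), cos(ang0))
      dir <- -c(sin(ang0), cos(ang0))        # grow inward
      ang <- atan2(dir[1], dir[2]) + rnorm(1, 0, 0.3)
      dir <- c(sin(ang), cos(ang))
      res <- grow_tree(mask, ridge, root, dir,
                       width = cfg$trunk_width * runif(1, 0.85, 1),
                       len = 0.4 * R, cfg)
      mask <- res$mask; ridge <- res$ridge
    }
    mask <- mask * fov
    # background: radial illumination falloff plus texture noise
    bg <- 175 * (1 - cfg$illumination_gradient * (rr / max(R, 1))^2)
    img <- bg - cfg$vessel_contrast * mask
    if (cfg$light_reflex && !is.null(ridge))
      img <- img + 0.6 * cfg$vessel_contrast * ridge * mask
    img <- img + matrix(rnorm(H * W, 0, cfg$background_noise_sd), H, W)
    img <- img * fov + 8 * (1 - fov)
    img <- clamp(round_half_away(img), 0, 255)
    fundus_sample(sample_id, img, mask, fov, source_path = "synthetic")
  })
}

#' Write a synthetic dataset with manifest
#'
#' Generates `n_train + n_test` samples (seeds derived from the config seed),
#' writes images, vessel masks and FOV masks as PNG plus a manifest CSV,
#' and returns the reloaded manifest.
#'
#' @param cfg a [synth_config()].
#' @param n_train,n_test split sizes (>= 1).
#' @param out_dir output directory (created if missing).
#' @return the `dataset_manifest` loaded back from disk.
#' @export
write_dataset <- function(cfg = synth_config(), n_train = 20L, n_test = 20L,
                          out_dir) {
  abort_if(n_train < 1 || n_test < 1, "n_train and n_test must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_train + n_test
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("synth_%02d", i)
    ci <- cfg
    ci$seed <- stage_seed(cfg$seed, paste0("sample:", i))
    smp <- generate_sample(ci, id)
    write_image_8bit(smp$image, file.path(out_dir, paste0(id, "_img.png")))
    write_mask(smp$vessel_mask, file.path(out_dir, paste0(id, "_vessel.png")))
    write_mask(smp$fov_mask, file.path(out_dir, paste0(id, "_fov.png")))
    rows[[i]] <- data.frame(
      sample_id = id, image = paste0(id, "_img.png"),
      vessel_mask = paste0(id, "_vessel.png"),
      fov_mask = paste0(id, "_fov.png"),
      split = if (i <= n_train) "train" else "test",
      stringsAsFactors = FALSE)
  }
  path <- file.path(out_dir, "manifest.csv")
  write_manifest(do.call(rbind, rows), path)
  load_manifest(path)
}

#' Generate an in-memory synthetic dataset
#'
#' Convenience wrapper used by the sweep harnesses and tests: returns train
#' and test sample lists without touching the filesystem.
#'
#' @param cfg a [synth_config()].
#' @param n_train,n_test split sizes.
#' @return list with elements `train` and `test` (lists of `fundus_sample`).
#' @export
generate_dataset <- function(cfg = synth_config(), n_train = 4L, n_test = 2L) {
  make <- function(i, split) {
    ci <- cfg
    ci$seed <- stage_seed(cfg$seed, paste0("sample:", i))
    generate_sample(ci, sprintf("synth_%02d", i))
  }
  n <- n_train + n_test
  all <- lapply(seq_len(n), make)
  list(train = all[seq_len(n_train)], test = all[n_train + seq_len(n_test)])
}
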