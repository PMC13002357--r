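#' Construct a fundus sample
#'
#' A fundus sample bundles one image with its binary vessel annotation and
#' field-of-view (FOV) mask. Masks are binarized (any non-zero value becomes
#' 1) and vessel pixels falling outside the FOV are repaired by intersection
#' with a warning, so the invariant `vessel_mask <= fov_mask` always holds.
#'
#' @param sample_id character identifier.
#' @param image numeric matrix (grayscale) or H x W x 3 array, values on the
#'   8-bit scale `[0, 255]`.
#' @param vessel_mask binary matrix matching the image height/width.
#' @param fov_mask binary matrix, or `NULL` for a full-frame FOV (logged).
#' @param source_path optional provenance string.
#' @return an object of class `fundus_sample`.
#' @export
fundus_sample <- function(sample_id, image, vessel_mask, fov_mask = NULL,
                          source_path = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  dims <- dim(image)[1:2]
  if (is.null(fov_mask)) {
    message("sample ", sample_id, ": no FOV mask, substituting full frame")
    fov_mask <- matrix(1, dims[1], dims[2])
  }
  vessel_mask <- (vessel_mask != 0) * 1
  fov_mask <- (fov_mask != 0) * 1
  abort_if(!identical(dim(vessel_mask), dims) || !identical(dim(fov_mask), dims),
           paste0("sample ", sample_id, ": image and masks differ in shape"))
  outside <- sum(vessel_mask > fov_mask)
  if (outside > 0) {
    warning("sample ", sample_id, ": ", outside,
            " vessel pixel(s) outside FOV removed by intersection",
            call. = FALSE)
    vessel_mask <- vessel_mask * fov_mask
  }
  structure(list(sample_id = sample_id, image = image,
                 vessel_mask = vessel_mask, fov_mask = fov_mask,
                 source_path = source_path),
            class = "fundus_sample")
}

#' @export
print.fundus_sample <- function(x, ...) {
  d <- dim(x$image)
  cat("<fundus_sample>", x$sample_id, ":", d[1], "x", d[2],
      if (length(d) == 3) "RGB" else "gray",
      "| vessel px:", sum(x$vessel_mask),
      "| FOV px:", sum(x$fov_mask), "\n")
  invisible(x)
}

read_raster <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores images (x, y [, channel]) in [0,1]; transpose to (row, col)
  if (length(dim(a)) == 2) {
    t(a) * 255
  } else {
    aperm(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(2, 1, 3)) * 255
  }
}

read_mask <- function(path) {
  a <- read_raster(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  (a > 0) * 1
}

write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask)), path, type = "png")
  invisible(path)
}

write_image_8bit <- function(image, path) {
  a <- clamp(image / 255, 0, 1)
  img <- if (length(dim(a)) == 3) {
    EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
  } else EBImage::Image(t(a))
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

#' Load a dataset manifest
#'
#' The manifest dialect is a flat CSV with header
#' `sample_id,image,vessel_mask,fov_mask,split`; paths are resolved relative
#' to the manifest's directory. An empty `fov_mask` field is permitted (a
#' full-frame FOV is substituted at load time).
#'
#' @param path path to the manifest CSV.
#' @return a `dataset_manifest`: data frame of entries plus the base
#'   directory as attribute `"base_dir"`.
#' @export
load_manifest <- function(path) {
  abort_if(!file.exists(path), paste0("manifest not found: ", path))
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "image", "vessel_mask", "fov_mask", "split")
  abort_if(!all(need %in% names(m)),
           paste0("manifest must have columns: ", paste(need, collapse = ",")))
  dup <- m$sample_id[duplicated(m$sample_id)]
  abort_if(length(dup) > 0,
           paste0("duplicate sample_id in manifest: ", paste(dup, collapse = ",")))
  abort_if(!all(m$split %in% c("train", "test")),
           "split must be 'train' or 'test'")
  base <- dirname(normalizePath(path))
  for (i in seq_len(nrow(m))) {
    for (col in c("image", "vessel_mask")) {
      p <- file.path(base, m[[col]][i])
      abort_if(!file.exists(p),
               paste0("sample ", m$sample_id[i], ": missing ", col, " file ", p))
    }
    if (!is.na(m$fov_mask[i]) && nzchar(m$fov_mask[i])) {
      p <- file.path(base, m$fov_mask[i])
      abort_if(!file.exists(p),
               paste0("sample ", m$sample_id[i], ": missing fov_mask file ", p))
    }
  }
  structure(m, base_dir = base, class = c("dataset_manifest", "data.frame"))
}

#' Write a dataset manifest
#'
#' @param manifest a `dataset_manifest` or data frame with the manifest columns.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)[, c("sample_id", "image", "vessel_mask",
                                    "fov_mask", "split")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load one sample from a manifest
#'
#' Masks are binarized (non-zero -> 1) and the vessel mask is intersected
#' with the FOV if needed; see [fundus_sample()].
#'
#' @param manifest a `dataset_manifest`.
#' @param sample_id which entry to load.
#' @return a `fundus_sample`.
#' @export
load_sample <- function(manifest, sample_id) {
  base <- attr(manifest, "base_dir")
  row <- manifest[manifest$sample_id == sample_id, , drop = FALSE]
  abort_if(nrow(row) != 1, paste0("sample_id not in manifest: ", sample_id))
  image <- read_raster(file.path(base, row$image))
  vmask <- read_mask(file.path(base, row$vessel_mask))
  fmask <- if (!is.na(row$fov_mask) && nzchar(row$fov_mask))
    read_mask(file.path(base, row$fov_mask)) else NULL
  fundus_sample(sample_id, image, vmask, fmask,
                source_path = file.path(base, row$image))
}

#' Load every sample of one split
#'
#' @param manifest a `dataset_manifest`.
#' @param split `"train"` or `"test"`.
#' @return a named list of `fundus_sample` objects.
#' @export
load_split <- function(manifest, split = c("train", "test")) {
  split <- match.arg(split)
  ids <- manifest$sample_id[manifest$split == split]
  abort_if(length(ids) == 0, paste0("no samples in split '", split, "'"))
  stats::setNames(lapply(ids, function(id) load_sample(manifest, id)), ids)
}

#' Save a probability map losslessly enough for evaluation
#'
#' Maps are stored as 16-bit grayscale TIFF, so a reload reproduces every
#' value within 1/65535 (16-bit quantization).
#'
#' @param map numeric matrix with values in `[0, 1]`.
#' @param path destination path (`.tif`).
#' @return the path, invisibly.
#' @export
save_probability_map <- function(map, path) {
  abort_if(any(map < 0 | map > 1), "probability map values must lie in [0, 1]")
  tiff::writeTIFF(map, path, bits.per.sample = 16L)
  invisible(path)
}

#' Load a probability map written by [save_probability_map()]
#'
#' @param path path to the 16-bit TIFF.
#' @return numeric matrix in `[0, 1]`.
#' @export
load_probability_map <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  tiff::readTIFF(path)
}
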