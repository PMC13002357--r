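test_that("noise level maps to the radial exponent in every mode", {
  expect_equal(beta_from_level(0, "zoom_in"), 1)
  expect_equal(beta_from_level(0, "zoom_out"), 1)
  expect_equal(beta_from_level(0, "random"), 1)
  expect_equal(beta_from_level(0.5, "zoom_in"), 1.5)
  expect_equal(beta_from_level(0.8, "zoom_out"), 1 / 1.8)
  b <- beta_from_level(0.4, "random", seed = 11L)
  expect_true(b %in% c(1.4, 1 / 1.4))
  expect_identical(b, beta_from_level(0.4, "random", seed = 11L))
  expect_error(beta_from_level(-0.1), "lambda")
})

test_that("radial deformation field matches the closed form", {
  # beta = 1 is the identity up to the epsilon guard
  f1 <- radial_field(48L, 1)
  expect_lte(max(abs(f1$delta_x)), 1e-6)
  expect_lte(max(abs(f1$delta_y)), 1e-6)

  f <- radial_field(48L, 1.5)
  ctr <- (48 - 1) / 2
  # closed form at one concrete pixel (row 24, col 37): p - c = (-0.5, 12.5)
  y0 <- 23; x0 <- 36
  dx <- x0 - ctr; dy <- y0 - ctr
  r <- sqrt(dx^2 + dy^2)
  rprime <- 24 * (r / 24)^1.5
  scale <- rprime / (r + 1e-8)
  expect_equal(f$delta_x[y0 + 1, x0 + 1], (scale - 1) * dx, tolerance = 1e-9)
  expect_equal(f$delta_y[y0 + 1, x0 + 1], (scale - 1) * dy, tolerance = 1e-9)
  # the half-radius landmark: r = 12 maps to r' = 24 * 0.5^1.5 ~ 8.4853
  expect_equal(24 * 0.5^1.5, 8.4853, tolerance = 1e-4)

  # pixels beyond the radius R = 24 are untouched; the center never moves
  x <- matrix(rep(0:47, each = 48), 48); y <- t(x)
  rr <- sqrt((x - ctr)^2 + (y - ctr)^2)
  expect_true(all(f$delta_x[rr > 24] == 0))
  expect_true(all(f$delta_y[rr > 24] == 0))
  # displacement is bounded by R and vanishes at both ends of the radius
  disp <- sqrt(f$delta_x^2 + f$delta_y^2)
  expect_lte(max(disp), 24)
  expect_lt(disp[24, 24], 0.7)             # near-center pixels barely move
  interior <- disp[rr > 5 & rr < 20]
  expect_gt(max(interior), 1)              # interior radii move visibly
  expect_error(radial_field(48L, 0), "beta")
})

test_that("label warping is binary, exact for identity, and matches a brute-force oracle", {
  w <- fix_segment_window()
  expect_equal(warp_label(matrix(0, 48, 48), radial_field(48L, 1.7)),
               matrix(0, 48, 48))
  expect_equal(warp_label(w, radial_field(48L, 1)), w)
  # single white pixel at the center is a fixed point
  cpix <- matrix(0, 48, 48)
  ctr <- round((48 - 1) / 2) + 1
  cpix[ctr, ctr] <- 1
  expect_equal(warp_label(cpix, radial_field(48L, 1.5))[ctr, ctr], 1)

  # brute-force per-pixel resampling oracle over all pixels, on a ring
  ring <- matrix(0, 48, 48)
  cc <- (48 - 1) / 2
  for (i in 1:48) for (j in 1:48) {
    r <- sqrt((i - 1 - cc)^2 + (j - 1 - cc)^2)
    if (abs(r - 18) <= 1) ring[i, j] <- 1
  }
  f <- radial_field(48L, 1.5)
  got <- warp_label(ring, f)
  oracle <- matrix(0, 48, 48)
  for (i in 1:48) for (j in 1:48) {
    yy <- i - 1; xx <- j - 1
    r <- sqrt((yy - cc)^2 + (xx - cc)^2)
    if (r <= 24) {
      rp <- 24 * (r / 24)^1.5
      sy <- cc + (rp / (r + 1e-8)) * (yy - cc)
      sx <- cc + (rp / (r + 1e-8)) * (xx - cc)
    } else { sy <- yy; sx <- xx }
    sy <- trunc(sy + sign(sy) * 0.5); sx <- trunc(sx + sign(sx) * 0.5)
    if (sy >= 0 && sy < 48 && sx >= 0 && sx < 48) oracle[i, j] <- ring[sy + 1, sx + 1]
  }
  expect_identical(got, oracle)
  expect_true(all(got %in% c(0, 1)))
  # a ring under beta > 1 appears at a larger radius (zoom in pulls sources inward)
  d <- function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    mean(sqrt((idx[, 1] - 1 - cc)^2 + (idx[, 2] - 1 - cc)^2))
  }
  expect_gt(d(got), d(ring))
  expect_error(warp_label(matrix(0, 10, 10), f), "shape")
})

test_that("image corruptions are identity at zero strength and seeded", {
  img <- fix_sample()$image
  for (kind in c("gaussian", "lowres", "uniform_blur", "fovea_blur"))
    expect_identical(corrupt_image(img, kind, 0), img)
  g1 <- corrupt_image(img, "gaussian", 0.5, seed = 4L)
  expect_identical(g1, corrupt_image(img, "gaussian", 0.5, seed = 4L))
  expect_false(identical(g1, corrupt_image(img, "gaussian", 0.5, seed = 5L)))
  expect_true(all(g1 >= 0 & g1 <= 255))
  # lowres at full strength equals the explicit down/up resampling chain
  lr <- corrupt_image(img, "lowres", 1)
  H <- nrow(img); W <- ncol(img)
  small <- EBImage::resize(EBImage::Image(t(img / 255)),
                           w = max(2, round(W / 4)), h = max(2, round(H / 4)))
  ref <- t(EBImage::imageData(EBImage::resize(small, w = W, h = H))) * 255
  expect_equal(lr, pmin(pmax(ref, 0), 255))
  # blur preserves the mean roughly and reduces variance
  ub <- corrupt_image(img, "uniform_blur", 1)
  expect_lt(stats::var(as.vector(ub)), stats::var(as.vector(img)))
  # fovea blur only changes the central disc
  fb <- corrupt_image(img, "fovea_blur", 1)
  rr <- sqrt(outer((seq_len(H) - (H + 1) / 2)^2, (seq_len(W) - (W + 1) / 2)^2, "+"))
  expect_identical(fb[rr > min(H, W) / 4 + 1], img[rr > min(H, W) / 4 + 1])
  expect_false(identical(fb[rr < min(H, W) / 8], img[rr < min(H, W) / 8]))
})

test_that("label mixing flags exactly the requested share and cleaning undoes it", {
  smp <- fix_sample()
  ps <- extract_training_patches(smp, sampling_config(patches_per_image = 100L),
                                 seed = 6L)
  # rho = 0: bit-identical labels
  s0 <- mix_labels(ps, noise_spec(lambda = 0.6, rho = 0, seed = 1L))
  expect_identical(s0$labels, ps$labels)
  # rho = 1 with lambda = 0: all flagged, labels unchanged
  s1 <- mix_labels(ps, noise_spec(lambda = 0, rho = 1, seed = 1L))
  expect_true(all(s1$noisy))
  expect_identical(s1$labels, ps$labels)
  # rho = 0.5 on 100 patches: exactly 50 flagged, the rest untouched
  s5 <- mix_labels(ps, noise_spec(lambda = 0.6, rho = 0.5, seed = 2L))
  expect_equal(sum(s5$noisy), 50)
  expect_identical(s5$labels[, , !s5$noisy], ps$labels[, , !s5$noisy])
  # warped labels stay binary
  expect_true(all(s5$labels %in% c(0, 1)))
  # cleaning retains exactly the clean complement with original labels
  cl <- remove_noisy(s5)
  expect_equal(n_patches(cl), 50)
  expect_identical(cl$labels, ps$labels[, , !s5$noisy])
  # rho = 0.25 on 1000 -> 750 survive (counting contract)
  expect_equal(1000 - round(0.25 * 1000), 750)
})
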