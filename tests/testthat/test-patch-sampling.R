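test_that("white-pixel counting and the small-vessel predicate", {
  expect_equal(count_white(matrix(0, 48, 48)), 0)
  expect_equal(count_white(matrix(1, 48, 48)), 2304)
  expect_equal(count_white(fix_segment_window()), 5)
  expect_error(count_white(matrix(0.5, 4, 4)), "binary")
  w150 <- matrix(0, 48, 48); w150[seq_len(150)] <- 1
  w201 <- matrix(0, 48, 48); w201[seq_len(201)] <- 1
  expect_true(is_small_vessel_patch(w150, 200))
  expect_false(is_small_vessel_patch(matrix(0, 48, 48), 200))
  expect_true(is_small_vessel_patch(matrix(0, 48, 48), 200, include_empty = TRUE))
  expect_false(is_small_vessel_patch(w201, 200))
})

test_that("balance fraction solves the oversampling equation", {
  p <- solve_balance_fraction(0.37, 0.5)
  expect_equal(p, (1 - 0.5) / (1 - 0.37))
  expect_equal(round(p, 1), 0.8)
  expect_equal(solve_balance_fraction(0.4, 0.4), 1)
  expect_equal(solve_balance_fraction(0.25, 0.5), 2 / 3)
  expect_error(solve_balance_fraction(1, 1), "source fraction")
  # mixed-pool fraction recovered at the conventional P = 0.8
  expect_equal(round(0.37 * 0.8 + (1 - 0.8), 1), 0.5)
})

test_that("small-vessel fraction estimate agrees with exhaustive enumeration", {
  smp <- fix_sample()
  cfg <- sampling_config()
  g <- vesselnoise:::valid_origins(smp, cfg$patch_size)
  truth <- mean(g$white >= 1 & g$white <= cfg$small_vessel_bound)
  est <- estimate_small_vessel_fraction(smp, cfg, n_probe = 1000L, seed = 5L)
  se <- sqrt(truth * (1 - truth) / 1000)
  expect_lt(abs(est - truth), 3 * se + 1e-9)
  # determinism and the empty-mask degenerate case
  expect_identical(est, estimate_small_vessel_fraction(smp, cfg, 1000L, seed = 5L))
  empty <- smp; empty$vessel_mask <- matrix(0, nrow(smp$image), ncol(smp$image))
  expect_equal(estimate_small_vessel_fraction(empty, cfg, 200L, seed = 1L), 0)
})

test_that("balanced extraction honors counts, pools and FOV containment", {
  smp <- fix_sample()
  cfg <- sampling_config(patches_per_image = 10L)
  ps <- extract_training_patches(smp, cfg, seed = 2L)
  expect_equal(n_patches(ps), 10)
  # the 2 dedicated patches are small-vessel windows
  counts <- apply(ps$labels[, , 9:10], 3, sum)
  expect_true(all(counts >= 1 & counts <= 200))
  # every patch window lies fully inside the FOV
  s <- cfg$patch_size
  for (i in seq_len(10)) {
    r <- ps$origins$row[i]; c <- ps$origins$col[i]
    expect_equal(sum(smp$fov_mask[(r + 1):(r + s), (c + 1):(c + s)]), s * s)
    expect_equal(ps$labels[, , i],
                 smp$vessel_mask[(r + 1):(r + s), (c + 1):(c + s)])
  }
  # determinism and P = 1 degenerate split
  ps2 <- extract_training_patches(smp, cfg, seed = 2L)
  expect_identical(ps$origins, ps2$origins)
  cfg1 <- sampling_config(patches_per_image = 10L, random_fraction = 1)
  expect_equal(n_patches(extract_training_patches(smp, cfg1, seed = 1L)), 10)
  # empty small-vessel pool: error by default, fallback on request
  empty <- smp; empty$vessel_mask <- 0 * smp$vessel_mask
  expect_error(extract_training_patches(empty, cfg, seed = 1L), "pool")
  expect_warning(psf <- extract_training_patches(empty, cfg, seed = 1L,
                                                 fallback_uniform = TRUE),
                 "uniform")
  expect_equal(n_patches(psf), 10)
})

test_that("balanced pool small-vessel rate matches the mixing expectation", {
  smp <- fix_sample()
  cfg <- sampling_config(patches_per_image = 2200L)
  g <- vesselnoise:::valid_origins(smp, cfg$patch_size)
  f <- mean(g$white >= 1 & g$white <= cfg$small_vessel_bound)
  ps <- extract_training_patches(smp, cfg, seed = 9L)
  got <- mean(apply(ps$labels, 3, function(w) sum(w) >= 1 && sum(w) <= 200))
  expected <- f * cfg$random_fraction + (1 - cfg$random_fraction)
  se <- sqrt(expected * (1 - expected) / 2200)
  expect_lt(abs(got - expected), 3 * se)
})

test_that("rotation augmentation quadruples patches exactly", {
  smp <- fix_sample()
  ps <- extract_training_patches(smp, sampling_config(patches_per_image = 5L),
                                 seed = 3L)
  aug <- rotate_augment(ps)
  expect_equal(n_patches(aug), 20)
  # white-pixel count is invariant under rotation
  expect_equal(apply(aug$labels, 3, sum), rep(apply(ps$labels, 3, sum), 4))
  # four successive 90-degree rotations give back the original
  r <- ps
  for (k in 1:4) r <- patch_set(vesselnoise:::rot90_stack(r$images, 1),
                                vesselnoise:::rot90_stack(r$labels, 1),
                                r$origins, r$noisy)
  expect_identical(r$images, ps$images)
  # image and label rotate together
  expect_equal(aug$images[, , 6], vesselnoise:::rot90_stack(ps$images, 1)[, , 1])
  expect_equal(aug$labels[, , 6], vesselnoise:::rot90_stack(ps$labels, 1)[, , 1])
})

test_that("test tiling covers the frame and recombination averages", {
  cfg48 <- sampling_config(patch_size = 48L, test_stride = 48L)
  tl <- tile_test_patches(matrix(0, 48, 48), cfg48)
  expect_equal(nrow(tl$layout$origins), 1)
  cfg10 <- sampling_config(patch_size = 48L, test_stride = 10L)
  img <- matrix(rnorm(68 * 68), 68)
  tl <- tile_test_patches(img, cfg10)
  expect_equal(sort(unique(tl$layout$origins$r)), c(0, 10, 20))
  expect_equal(sort(unique(tl$layout$origins$c)), c(0, 10, 20))
  expect_equal(dim(tl$patches)[3], 9)
  expect_error(tile_test_patches(img, sampling_config(patch_size = 8L,
                                                      test_stride = 10L)),
               "stride")

  # constant predictions recombine losslessly
  probs <- array(0.3, dim(tl$patches))
  expect_equal(recombine(probs, tl$layout), matrix(0.3, 68, 68))
  # brute-force accumulate-and-divide oracle on random predictions
  probs <- array(runif(48 * 48 * 9), c(48, 48, 9))
  acc <- matrix(0, 68, 68); cnt <- matrix(0, 68, 68)
  for (i in 1:9) {
    rr <- tl$layout$origins$r[i] + 1:48
    cc <- tl$layout$origins$c[i] + 1:48
    acc[rr, cc] <- acc[rr, cc] + probs[, , i]
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  expect_equal(recombine(probs, tl$layout), acc / cnt)
  # permutation invariance in patch order
  perm <- sample(9)
  lay2 <- tl$layout; lay2$origins <- tl$layout$origins[perm, ]
  expect_equal(recombine(probs[, , perm], lay2), recombine(probs, tl$layout))
  # two overlapping tiles predicting 0 and 1 average to 0.5
  cfg2 <- sampling_config(patch_size = 4L, test_stride = 2L)
  t2 <- tile_test_patches(matrix(0, 4, 6), cfg2)
  p2 <- array(0, c(4, 4, nrow(t2$layout$origins)))
  p2[, , 2] <- 1
  out <- recombine(p2, t2$layout)
  expect_equal(out[1, 3], 0.5)
})

test_that("padding is cropped and every original pixel is covered", {
  cfg <- sampling_config(patch_size = 48L, test_stride = 10L)
  img <- matrix(rnorm(75 * 91), 75)
  tl <- tile_test_patches(img, cfg)
  expect_equal(tl$layout$shape, c(75, 91))
  cover <- matrix(0, tl$layout$padded_shape[1], tl$layout$padded_shape[2])
  for (i in seq_len(nrow(tl$layout$origins))) {
    rr <- tl$layout$origins$r[i] + 1:48
    cc <- tl$layout$origins$c[i] + 1:48
    cover[rr, cc] <- 1
  }
  expect_true(all(cover == 1))
  out <- recombine(array(1, c(48, 48, nrow(tl$layout$origins))), tl$layout)
  expect_equal(dim(out), c(75, 91))
})
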