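# Experiment harnesses: noise-level, noise-ratio, noise-type and cleaning
# sweeps. Each condition trains a fresh seeded model on balanced patches
# from the training split and scores every test sample inside its FOV.

preprocess_all <- function(samples, cfg) {
  lapply(samples, preprocess_sample, cfg = cfg$preprocess)
}

# Balanced patches for all training samples (per-image derived seeds).
prepare_training_patches <- function(train_samples, cfg, tag = "extract") {
  sets <- lapply(seq_along(train_samples), function(i) {
    extract_training_patches(train_samples[[i]], cfg$sampling,
                             seed = stage_seed(cfg$seed, paste0(tag, ":", i)))
  })
  ps <- bind_patch_sets(sets)
  if (cfg$augment) ps <- rotate_augment(ps)
  ps
}

# Train one fresh model on a patch set and score the test split.
run_condition <- function(ps, test_samples, cfg, cond_tag, meta) {
  mseed <- stage_seed(cfg$seed, paste0("init:", cond_tag))
  model <- build_unet(cfg$model, seed = mseed)
  tcfg <- cfg$train
  tcfg$seed <- stage_seed(cfg$seed, paste0("train:", cond_tag))
  model <- train_unet(model, ps, tcfg)
  rows <- lapply(test_samples, function(smp) {
    rep <- evaluate_sample(model, smp, cfg$sampling, cfg$threshold)
    attr(rep, "prob_map") <- NULL
    cbind(as.data.frame(meta, stringsAsFactors = FALSE), rep)
  })
  list(table = do.call(rbind, rows), model = model)
}

#' Sweep over noise levels
#'
#' For each level `lambda`: deform all training labels (`rho = 1`), train a
#' fresh seeded model, and evaluate on the clean test split. `lambda = 0`
#' is the clean baseline.
#'
#' @param data list with `train` and `test` lists of [fundus_sample()]
#'   objects (raw; preprocessing is applied internally unless
#'   `preprocess = FALSE`).
#' @param lambda_list noise levels to sweep.
#' @param cfg an [experiment_config()].
#' @param preprocess apply the preprocessing pipeline first.
#' @return data frame with one row per (lambda, test sample).
#' @export
sweep_noise_level <- function(data, lambda_list = c(0, 0.2, 0.4, 0.6, 0.8),
                              cfg = experiment_config(), preprocess = TRUE) {
  if (preprocess) {
    data$train <- preprocess_all(data$train, cfg)
    data$test <- preprocess_all(data$test, cfg)
  }
  base_ps <- prepare_training_patches(data$train, cfg)
  out <- lapply(seq_along(lambda_list), function(i) {
    lam <- lambda_list[i]
    spec <- noise_spec(lambda = lam, rho = if (lam > 0) 1 else 0,
                       corruption = "nonlinear",
                       direction_mode = cfg$direction_mode,
                       seed = stage_seed(cfg$seed, paste0("noise:level:", i)))
    ps <- mix_labels(base_ps, spec)
    run_condition(ps, data$test, cfg, paste0("level:", i),
                  list(lambda = lam, rho = spec$rho, corruption = "nonlinear"))$table
  })
  do.call(rbind, out)
}

#' Sweep over noise ratios (crossed with levels)
#'
#' For each `(lambda, rho)` pair, deforms a seeded random fraction `rho` of
#' the training labels, trains a fresh model, and scores the clean test
#' split.
#'
#' @param data list with `train` and `test` sample lists.
#' @param lambda_list noise levels.
#' @param rho_list noise ratios.
#' @param cfg an [experiment_config()].
#' @param preprocess apply the preprocessing pipeline first.
#' @return data frame with one row per (lambda, rho, test sample).
#' @export
sweep_noise_ratio <- function(data, lambda_list = c(0.6),
                              rho_list = c(0, 0.25, 0.5, 0.75, 1),
                              cfg = experiment_config(), preprocess = TRUE) {
  if (preprocess) {
    data$train <- preprocess_all(data$train, cfg)
    data$test <- preprocess_all(data$test, cfg)
  }
  base_ps <- prepare_training_patches(data$train, cfg)
  grid <- expand.grid(lambda = lambda_list, rho = rho_list)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- noise_spec(lambda = grid$lambda[i], rho = grid$rho[i],
                       corruption = "nonlinear",
                       direction_mode = cfg$direction_mode,
                       seed = stage_seed(cfg$seed, paste0("noise:ratio:", i)))
    ps <- mix_labels(base_ps, spec)
    run_condition(ps, data$test, cfg, paste0("ratio:", i),
                  list(lambda = grid$lambda[i], rho = grid$rho[i],
                       corruption = "nonlinear"))$table
  })
  do.call(rbind, out)
}

#' Sweep over noise types
#'
#' The `"nonlinear"` kind corrupts training labels (at level `lambda`,
#' `rho = 1`); the image-level kinds (`"gaussian"`, `"lowres"`,
#' `"uniform_blur"`, `"fovea_blur"`) corrupt the training images and keep
#' labels clean; `"none"` is the clean baseline. One fresh model per kind.
#'
#' @param data list with `train` and `test` sample lists.
#' @param kinds corruption kinds to compare.
#' @param lambda corruption strength shared by all kinds.
#' @param cfg an [experiment_config()].
#' @param preprocess apply the preprocessing pipeline first.
#' @return data frame with one row per (kind, test sample).
#' @export
sweep_noise_type <- function(data,
                             kinds = c("nonlinear", "gaussian", "lowres",
                                       "uniform_blur", "fovea_blur"),
                             lambda = 0.6, cfg = experiment_config(),
                             preprocess = TRUE) {
  if (preprocess) {
    data$train <- preprocess_all(data$train, cfg)
    data$test <- preprocess_all(data$test, cfg)
  }
  out <- lapply(seq_along(kinds), function(i) {
    kind <- kinds[i]
    train_i <- data$train
    if (kind %in% c("gaussian", "lowres", "uniform_blur", "fovea_blur")) {
      train_i <- lapply(seq_along(train_i), function(j) {
        smp <- train_i[[j]]
        smp$image <- corrupt_image(smp$image, kind, lambda,
                                   seed = stage_seed(cfg$seed, paste0("corrupt:", i, ":", j)))
        smp
      })
    }
    ps <- prepare_training_patches(train_i, cfg, tag = paste0("extract:type", i))
    if (kind == "nonlinear") {
      spec <- noise_spec(lambda = lambda, rho = 1, corruption = "nonlinear",
                         direction_mode = cfg$direction_mode,
                         seed = stage_seed(cfg$seed, paste0("noise:type:", i)))
      ps <- mix_labels(ps, spec)
    }
    run_condition(ps, data$test, cfg, paste0("type:", i),
                  list(lambda = if (kind == "none") 0 else lambda,
                       rho = if (kind == "nonlinear") 1 else 0,
                       corruption = kind))$table
  })
  do.call(rbind, out)
}

#' Cleaning comparison: noisy-full vs clean-subset training
#'
#' For each noise ratio, arm A trains on the full mixed patch set (clean +
#' deformed labels) while arm B trains only on the patches whose labels were
#' never deformed (so `N * (1 - rho)` patches). Both arms are scored on the
#' clean test split.
#'
#' @param data list with `train` and `test` sample lists.
#' @param lambda noise level of the deformed labels.
#' @param rho_list noise ratios, each in `(0, 1)`.
#' @param cfg an [experiment_config()].
#' @param preprocess apply the preprocessing pipeline first.
#' @return data frame with one row per (rho, arm, test sample); column `arm`
#'   is `"noisy"` or `"cleaned"`.
#' @export
cleaning_comparison <- function(data, lambda = 0.6, rho_list = c(0.25, 0.5, 0.75),
                                cfg = experiment_config(), preprocess = TRUE) {
  abort_if(any(rho_list <= 0 | rho_list >= 1),
           "rho_list values must lie strictly between 0 and 1")
  if (preprocess) {
    data$train <- preprocess_all(data$train, cfg)
    data$test <- preprocess_all(data$test, cfg)
  }
  base_ps <- prepare_training_patches(data$train, cfg)
  out <- lapply(seq_along(rho_list), function(i) {
    rho <- rho_list[i]
    spec <- noise_spec(lambda = lambda, rho = rho, corruption = "nonlinear",
                       direction_mode = cfg$direction_mode,
                       seed = stage_seed(cfg$seed, paste0("noise:clean:", i)))
    mixed <- mix_labels(base_ps, spec)
    cleaned <- remove_noisy(mixed)
    a <- run_condition(mixed, data$test, cfg, paste0("cleanA:", i),
                       list(lambda = lambda, rho = rho, corruption = "nonlinear",
                            arm = "noisy"))$table
    b <- run_condition(cleaned, data$test, cfg, paste0("cleanB:", i),
                       list(lambda = lambda, rho = rho, corruption = "nonlinear",
                            arm = "cleaned"))$table
    rbind(a, b)
  })
  do.call(rbind, out)
}

#' Per-condition means of a sweep table
#'
#' @param tbl a sweep result table.
#' @param by metadata columns to group by.
#' @return data frame of group means for the metric columns.
#' @export
summarize_sweep <- function(tbl, by = intersect(c("lambda", "rho", "corruption", "arm"),
                                                names(tbl))) {
  metrics <- intersect(c("acc", "sp", "sn", "precision", "f1", "auc"), names(tbl))
  stats::aggregate(tbl[metrics], by = tbl[by], FUN = mean, na.rm = TRUE)
}
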