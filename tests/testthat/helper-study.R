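# Desk-scale noise study shared by the sweep-sensitivity tests: 4 training /
# 2 test synthetic images, 200 patches per image, a depth-2 U-Net with
# bottleneck attention trained for 10 epochs, repeated over 3 seeds. Six
# conditions cover the clean baseline, the strongest deformation, the ratio
# grid at lambda = 0.6, and the cleaning comparison at rho = 0.75.

desk_study_conditions <- function() {
  list(
    list(tag = "base",      lambda = 0,   rho = 0,    arm = "full"),
    list(tag = "l08_r1",    lambda = 0.8, rho = 1,    arm = "full"),
    list(tag = "l06_r05",   lambda = 0.6, rho = 0.5,  arm = "full"),
    list(tag = "l06_r1",    lambda = 0.6, rho = 1,    arm = "full"),
    list(tag = "l06_r075",  lambda = 0.6, rho = 0.75, arm = "full"),
    list(tag = "l06_r075c", lambda = 0.6, rho = 0.75, arm = "clean"))
}

run_desk_study <- function(run_seed = 100L, n_seeds = 3L) {
  results <- list()
  for (k in seq_len(n_seeds)) {
    seed_k <- run_seed + k
    data <- generate_dataset(synth_config(seed = stage_seed(seed_k, "data")),
                             n_train = 4, n_test = 2)
    cfg <- desk_config(seed = seed_k)
    data$train <- lapply(data$train, preprocess_sample, cfg = cfg$preprocess)
    data$test <- lapply(data$test, preprocess_sample, cfg = cfg$preprocess)
    base_ps <- vesselnoise:::prepare_training_patches(data$train, cfg)
    for (cd in desk_study_conditions()) {
      spec <- noise_spec(lambda = cd$lambda, rho = cd$rho,
                         corruption = "nonlinear",
                         seed = stage_seed(seed_k, paste0("noise:", cd$tag)))
      ps <- mix_labels(base_ps, spec)
      if (cd$arm == "clean") ps <- remove_noisy(ps)
      r <- vesselnoise:::run_condition(
        ps, data$test, cfg, paste0(cd$tag, ":", k),
        list(lambda = cd$lambda, rho = cd$rho, arm = cd$arm))
      tb <- r$table
      tb$seed_rep <- k
      tb$tag <- cd$tag
      results[[paste0(cd$tag, ":", k)]] <- tb
    }
  }
  do.call(rbind, results)
}

# cached across acceptance test blocks
desk_study <- function() fixture("desk_study", function() run_desk_study(100L))

# per-(tag, seed) means of one metric
study_stat <- function(tbl, tag, metric) {
  vapply(sort(unique(tbl$seed_rep)), function(k) {
    mean(tbl[[metric]][tbl$tag == tag & tbl$seed_rep == k])
  }, 0)
}
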