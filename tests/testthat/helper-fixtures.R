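# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# one default synthetic sample
fix_sample <- function() fixture("sample", function() {
  generate_sample(synth_config(seed = 7L), "fix_01")
})

# the same sample preprocessed with defaults
fix_preprocessed <- function() fixture("preprocessed", function() {
  preprocess_sample(fix_sample())
})

# a small binary window with a hand-placed 5-pixel vessel segment
fix_segment_window <- function(s = 48L) {
  w <- matrix(0, s, s)
  w[10, 11:15] <- 1
  w
}

# desk-scale experiment configuration used by the sweep tests: depth-2
# U-Net with bottleneck attention on 200 patches/image, 10 epochs
desk_config <- function(seed = 1L) {
  experiment_config(
    sampling = sampling_config(patches_per_image = 200L),
    model = model_config(depth = 2L, base_channels = 4L,
                         attention = "bottleneck"),
    train = train_config(epochs = 10L),
    augment = FALSE, seed = as.integer(seed))
}
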