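# Shared fixtures, built in code at test time.

# A reduced-scale classification problem for training-behaviour property
# tests: small images, a small network, fast epochs. The images keep the
# features that matter (intact vs broken strand grids); only the scale is
# reduced.
tiny_dataset <- function(n, seed, quality_mixture = c(0.5, 0.5),
                         plant_perfect = FALSE) {
  generate_labeled_dataset(
    n_images = n, quality_mixture = quality_mixture, seed = seed,
    image_size = 128, mm_per_pixel = 0.1, target_size = c(64, 64),
    plant_perfect = plant_perfect
  )
}

tiny_model <- function(seed) {
  build_classifier(seed = seed, input_size = 64, depths = c(8, 16),
                   dense_units = 16)
}

tiny_config <- function(seed, ...) {
  defaults <- list(initial_dataset = 40, batch_increment = 40,
                   epochs_per_stage = 3, early_stopping_patience = 2,
                   batch_size = 16, seed = seed)
  do.call(training_config, utils::modifyList(defaults, list(...)))
}

train_tiny <- function(ds, seed, ...) {
  cfg <- tiny_config(seed, ...)
  train_incremental(ds, cfg, model = tiny_model(seed))
}

# deterministic non-trivial test image
pattern_image <- function(n = 32) {
  outer(seq_len(n), seq_len(n), function(i, j) ((i * 7 + j * 3) %% 13) / 12)
}
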