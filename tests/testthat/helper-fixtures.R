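# Shared fixtures, built in code.  The synthetic acceptance dataset and
# its trained runs are expensive, so they are generated lazily once per
# test session and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# small hand-written manifest: 2 leaves x 3 images
toy_manifest <- function() {
  as_manifest(data.frame(
    image_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    leaf_id = rep(c("leafA", "leafB"), each = 3),
    genotype = rep(c("LINE-X", "LINE-Y"), each = 3),
    score = rep(c("3", "4/4+"), each = 3),
    leaf_number = rep(c(3L, 4L), each = 3),
    year = "Y1", environment = "GH", site = "N",
    vein_index = rep(1:3, 2), position_index = 1L,
    is_first = rep(c(TRUE, FALSE, FALSE), 2),
    image_path = paste0(c("a1", "a2", "a3", "b1", "b2", "b3"), ".png")))
}

# metadata-only manifest over the full genotype grid (no image files):
# used by split-grammar tests; cheap (seconds)
grid_manifest <- function() {
  if (is.null(.fixtures$grid_manifest)) {
    cfg <- synth_config(plants_per_genotype = 2L, seed = 42L)
    .fixtures$grid_manifest <- generate_dataset(
      grid_panel(), cfg, out_dir = file.path(tempdir(), "leafhair_grid"),
      write_images = FALSE)
  }
  .fixtures$grid_manifest
}

# the desk-scale acceptance dataset: 9 well-separated classes, one
# genotype per class, 3 plants x L3/L4 -> 54 leaves, 9-15 images each,
# at the generator's default 256 x 192 resolution
acceptance_dataset <- function() {
  if (is.null(.fixtures$acc_manifest)) {
    dir <- file.path(tempdir(), "leafhair_acceptance")
    .fixtures$acc_manifest <- generate_dataset(
      default_panel(), synth_config(plants_per_genotype = 3L, seed = 20260911L),
      out_dir = dir)
    cache <- lapply(.fixtures$acc_manifest$image_path, read_image_array)
    names(cache) <- .fixtures$acc_manifest$image_id
    .fixtures$acc_cache <- cache
  }
  .fixtures$acc_manifest
}

acceptance_cache <- function() {
  acceptance_dataset()
  .fixtures$acc_cache
}

# desk-scale training configuration for the tiny backbone (see the
# methods vignette for the rationale behind these choices)
acceptance_train_config <- function(seed = 20260911L) {
  train_config(optimizer = "Adam", learning_rate = 2e-3, epochs = 10L,
               batch_size = 8L, n_runs = 3L, seed = seed,
               augmentation = augment_config(ops = c("rv_flip", "rh_flip"),
                                             target_size = 64L),
               network = network_config("tiny"))
}

# three independent training runs on a whole-style 80/20 split, shared
# by the class-recovery and noise-robustness acceptance tests
acceptance_runs <- function() {
  if (is.null(.fixtures$acc_runs)) {
    m <- acceptance_dataset()
    split <- make_split(m, seed = 20260911L, name = "whole")
    cfg <- acceptance_train_config()
    .fixtures$acc_split <- split
    .fixtures$acc_runs <- lapply(1:3, function(r)
      train_model(m, split, cfg, run_index = r,
                  image_cache = acceptance_cache()))
  }
  .fixtures$acc_runs
}

acceptance_split <- function() {
  acceptance_runs()
  .fixtures$acc_split
}

# small fast dataset for optimization-sanity and CLI tests: 2 classes,
# low resolution, few leaves
small_dataset <- function() {
  if (is.null(.fixtures$small_manifest)) {
    cfg <- synth_config(image_width = 64L, image_height = 48L,
                        plants_per_genotype = 3L,
                        images_per_leaf_range = c(4L, 6L), seed = 31L)
    .fixtures$small_manifest <- generate_dataset(
      default_panel()[c(1, 9)], cfg,
      out_dir = file.path(tempdir(), "leafhair_small"))
    cache <- lapply(.fixtures$small_manifest$image_path, read_image_array)
    names(cache) <- .fixtures$small_manifest$image_id
    .fixtures$small_cache <- cache
  }
  .fixtures$small_manifest
}

small_cfg <- function(...) {
  args <- list(learning_rate = 2e-3, epochs = 5L, batch_size = 8L,
               seed = 77L, augmentation = augment_config(target_size = 32L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(train_config, args)
}
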