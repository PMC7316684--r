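# The reference desk-scale benchmark: simulate -> train -> evaluate with one
# seed. This is the package's reproducible end-to-end accuracy experiment.

#' Run the reference desk-scale benchmark
#'
#' Generates a clean-background synthetic screw dataset (1500 training and
#' 200 test images, 256 x 256 px, source-detector distance 1000 mm, detector
#' pixel spacing 0.5 mm/px), trains the CPU-scale landmark regressor
#' (3 blocks, base 32 channels, Adam, initial learning rate 5e-3 with the
#' staged schedule compressed proportionally to the shortened epoch count),
#' and evaluates the 3-iteration estimator from 2 randomly drawn initial
#' poses per test image (within 2.5 mm / 30 degrees), filtering cases with
#' ground-truth |tau| > 80 degrees.
#'
#' Relative to the full-scale protocol (200k patches, 80 epochs) the patch
#' count and epochs are reduced to fit a single-CPU budget of roughly ten
#' minutes; all other components are identical. See the methods vignette
#' for the scaling rationale.
#'
#' @param seed master seed driving every random component (data generation,
#'   weight init, shuffling/dropout, initial-pose draws).
#' @param n_train,n_test training / test images.
#' @param variations_per_image prior perturbations per training image.
#' @param epochs training epochs.
#' @param k initial poses per test image.
#' @param quiet suppress progress messages.
#' @return A list with `model` (the trained `landmark_cnn`), `experiment`
#'   (an `fp_experiment`), `train_data` summary and all timings (seconds).
#' @export
run_reference_benchmark <- function(seed = 1L, n_train = 1500L, n_test = 200L,
                                    variations_per_image = 6L, epochs = 12L,
                                    k = 2L, quiet = FALSE) {
  seed <- as.integer(seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  geom <- projection_geometry(d_sdd = 1000, delta_ds = 0.5,
                              width = 256L, height = 256L)
  fid <- make_fiducial("screw")
  bg <- background_config()           # clean configuration
  ranges <- sim_pose_ranges()
  tm <- list()

  t0 <- proc.time()[3]
  ds_train <- generate_dataset(n_train, fid, geom, ranges, bg,
                               split = "train", seed = seed)
  ds_test <- generate_dataset(n_test, fid, geom, ranges, bg,
                              split = "test", seed = seed + 500009L)
  tm$generate <- proc.time()[3] - t0
  say("generated %d train + %d test images (%.1f s)", n_train, n_test, tm$generate)

  t0 <- proc.time()[3]
  td <- build_patch_dataset(ds_train, variations_per_image = variations_per_image,
                            seed = seed + 1L)
  tm$patches <- proc.time()[3] - t0
  say("built %d training patches (%.1f s)", ncol(td$patches), tm$patches)

  # dropout off for this benchmark: the task is clean and deterministic, and
  # ablation shows the 0.5 default costs a factor ~2.5 in validation MSE at
  # this scale (see the methods vignette)
  arch <- arch_config(blocks = 3L, convs_per_block = 1L, base_channels = 32L,
                      fc_layers = 2L, fc_hidden = 512L, dropout = 0)
  model <- build_regressor(arch, seed = seed + 2L)
  # staged schedule compressed to the shortened run: stage length 35/80 of
  # the epochs, so both decade drops of the full protocol occur; gradient
  # clipping tames the 5e-3 stage in float32
  drop_every <- max(1L, as.integer(floor(epochs * 35 / 80)))
  cfg <- train_config(lr_initial = 5e-3, lr_drop_every = drop_every,
                      max_epochs = as.integer(epochs), batch_size = 64L,
                      optimizer = "adam", seed = seed + 3L, clip_norm = 1,
                      variations_per_image = as.integer(variations_per_image))
  t0 <- proc.time()[3]
  model <- train_regressor(model, td, cfg)
  tm$train <- proc.time()[3] - t0
  say("trained %d epochs, best epoch %d, val MSE %.3g (%.1f s)",
      epochs, model$best_epoch, min(model$history$val_loss, na.rm = TRUE),
      tm$train)

  t0 <- proc.time()[3]
  exp <- run_experiment(ds_test, model, k = k, n_iter = 3L,
                        seed = seed + 4L, n_crops = 9L)
  tm$evaluate <- proc.time()[3] - t0
  say("evaluated %d cases (%.1f s)", exp$errors$n_evaluated, tm$evaluate)

  list(model = model, experiment = exp, geom = geom,
       n_patches = ncol(td$patches), timings = tm)
}
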