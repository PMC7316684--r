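# small trained models shared across test files (trained once per run)

.fx_cache <- new.env(parent = emptyenv())

# compact landmark regressor trained on a small clean synthetic set; strong
# enough for sub-pixel behavior checks at a fraction of the reference cost
fx_small_model <- function() {
  if (!is.null(.fx_cache$model)) return(.fx_cache$model)
  f <- make_fiducial("screw")
  g <- fx_geom()
  ds <- generate_dataset(200, f, g, seed = 2024)
  td <- build_patch_dataset(ds, variations_per_image = 6L, seed = 2025)
  arch <- arch_config(blocks = 3L, convs_per_block = 1L, base_channels = 16L,
                      fc_layers = 2L, fc_hidden = 256L, dropout = 0)
  m <- build_regressor(arch, seed = 2026)
  cfg <- train_config(lr_initial = 5e-3, lr_drop_every = 8L, max_epochs = 20L,
                      batch_size = 64L, seed = 2027, clip_norm = 1,
                      variations_per_image = 6L)
  m <- train_regressor(m, td, cfg)
  .fx_cache$model <- m
  .fx_cache$train_ds <- ds
  m
}

fx_test_ds <- function(n = 30, seed = 3030) {
  key <- paste0("ds_", n, "_", seed)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- generate_dataset(n, make_fiducial("screw"), fx_geom(),
                                         split = "test", seed = seed)
  .fx_cache[[key]]
}
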