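# Shared fixtures, built once per test run, on the validated 96^3 study
# geometry (one centrum semiovale lesion at WM mean + 3 SD).

.fixture_cache <- new.env(parent = emptyenv())

test_grid <- c(96L, 96L, 96L)

test_blob <- function(atlas, radius_mm = 4.2, offset_sd = 3) {
  cs_blob(atlas, radius_mm = radius_mm, offset_sd = offset_sd)
}

# default-noise phantom + full pipeline output
fixture_default <- function() {
  if (is.null(.fixture_cache$default)) {
    atlas <- make_atlas(grid_shape = test_grid, seed = 42)
    blob <- test_blob(atlas)
    spec <- phantom_spec(grid_shape = test_grid, dwma_blobs = list(blob),
                         seed = 7)
    ph <- make_phantom(spec, atlas)
    pipe <- run_pipeline(ph$volume, atlas)
    .fixture_cache$default <- list(atlas = atlas, blob = blob, spec = spec,
                                   phantom = ph, pipe = pipe)
  }
  .fixture_cache$default
}

# clean phantom: tight tissue texture, no bias, no extra noise
fixture_clean <- function() {
  if (is.null(.fixture_cache$clean)) {
    atlas <- make_atlas(grid_shape = test_grid, seed = 42)
    blob <- test_blob(atlas)
    spec <- phantom_spec(grid_shape = test_grid, dwma_blobs = list(blob),
                         class_sds = c(background = 0.5, csf = 1, gm = 1, wm = 1),
                         bias_amplitude = 0, noise_sigma = 0, seed = 7)
    ph <- make_phantom(spec, atlas)
    .fixture_cache$clean <- list(atlas = atlas, blob = blob, spec = spec,
                                 phantom = ph)
  }
  .fixture_cache$clean
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
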