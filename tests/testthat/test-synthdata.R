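# Synthetic atlas, phantom and cohort generators.

test_that("atlas probabilities are normalised and ventricles sit inside WM", {
  atlas <- make_atlas(grid_shape = c(64, 64, 64), smoothing_mm = 2, seed = 3)
  tot <- atlas$prob[, , , 1] + atlas$prob[, , , 2] +
    atlas$prob[, , , 3] + atlas$prob[, , , 4]
  expect_lt(max(abs(tot - 1)), 1e-6)
  expect_true(all(atlas$prob >= 0))

  lab <- neodwma:::atlas_hard_labels(atlas)
  # ventricle CSF components: interior CSF not connected to the rim
  vent <- lab == 1L & atlas$ventricle_prior > 0.25
  comp <- label_components(vent, 26)
  expect_equal(max(comp), 2L)
  # each ventricle is fully surrounded by WM: dilating by one voxel only
  # reaches WM or ventricle voxels
  d <- dim(lab)
  idx <- which(vent, arr.ind = TRUE)
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    nb <- sweep(idx, 2, o, "+")
    keep <- nb[,1] >= 1 & nb[,1] <= d[1] & nb[,2] >= 1 & nb[,2] <= d[2] &
      nb[,3] >= 1 & nb[,3] <= d[3]
    vals <- lab[nb[keep, , drop = FALSE]]
    expect_true(all(vals %in% c(1L, 3L)))   # CSF (ventricle) or WM only
  }
})

test_that("zero smoothing gives 0/1 indicator priors", {
  atlas <- make_atlas(grid_shape = c(64, 64, 64), smoothing_mm = 0)
  expect_true(all(atlas$prob %in% c(0, 1)))
})

test_that("too-small grids are rejected", {
  expect_error(make_atlas(grid_shape = c(16, 48, 48)), "grid too small")
})

test_that("phantom generation is seed-deterministic and truth-consistent", {
  atlas <- make_atlas(grid_shape = c(64, 64, 64), seed = 5)
  spec <- phantom_spec(grid_shape = c(64, 64, 64), seed = 11)
  a <- make_phantom(spec, atlas)
  b <- make_phantom(spec, atlas)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$dwma_mask, b$truth$dwma_mask)

  # empty blob list: no DWMA anywhere
  expect_equal(a$truth$dwma_true_volume_mm3, 0)
  expect_false(any(a$truth$dwma_mask))
})

test_that("DWMA truth volume equals voxel volume times voxel count", {
  atlas <- make_atlas(grid_shape = c(64, 64, 64), seed = 5)
  blob <- cs_blob(atlas, radius_mm = 3, lateral_mm = 5, anterior_mm = 8)
  spec <- phantom_spec(grid_shape = c(64, 64, 64), dwma_blobs = list(blob),
                       seed = 11)
  ph <- make_phantom(spec, atlas)
  n <- sum(ph$truth$dwma_mask)
  expect_gt(n, 0)
  expect_identical(ph$truth$dwma_true_volume_mm3, n * prod(c(0.93, 0.93, 1.0)))
  # center-in voxel membership oracle
  ctr <- blob$center; semi <- blob$radius_mm
  d <- dim(ph$truth$label_volume)
  cnt <- 0L
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    q <- ((i - ctr[1]) * 0.93 / semi[1])^2 + ((j - ctr[2]) * 0.93 / semi[2])^2 +
      ((k - ctr[3]) * 1.0 / semi[3])^2
    if (q <= 1 && ph$truth$label_volume[i, j, k] == 3L) cnt <- cnt + 1L
  }
  expect_identical(n, cnt)
})

test_that("blob centred outside white matter is rejected by name", {
  atlas <- make_atlas(grid_shape = c(64, 64, 64), seed = 5)
  bad <- list(center = c(2, 2, 2), radius_mm = 3, offset_sd = 3)
  spec <- phantom_spec(grid_shape = c(64, 64, 64), dwma_blobs = list(bad))
  expect_error(make_phantom(spec, atlas), "blob 1")
})

test_that("noiseless phantom intensities follow CSF > WM > GM ordering", {
  atlas <- make_atlas(grid_shape = c(64, 64, 64), seed = 5)
  spec <- phantom_spec(grid_shape = c(64, 64, 64),
                       class_sds = c(background = 0, csf = 0, gm = 0, wm = 0),
                       bias_amplitude = 0, noise_sigma = 0, seed = 1)
  ph <- make_phantom(spec, atlas)
  lab <- ph$truth$label_volume
  x <- ph$volume$data
  expect_equal(unique(x[lab == 1L]), 160)   # every CSF voxel at its class mean
  expect_equal(unique(x[lab == 3L]), 108)
  expect_equal(unique(x[lab == 2L]), 90)
  expect_gt(mean(x[lab == 1L]), mean(x[lab == 3L]))
  expect_gt(mean(x[lab == 3L]), mean(x[lab == 2L]))
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(class_means = c(background = 15, csf = 90, gm = 90, wm = 108)),
               "distinct")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(dwma_blobs = list(list(center = c(1, 1, 1),
                                                   radius_mm = 2,
                                                   offset_sd = 0))),
               "offset")
})

test_that("degenerate cohort: zero betas and zero noise give constant Bayley", {
  sp <- cohort_spec(n_subjects = 50, intercept = 90, beta_dwma_per10pct = 0,
                    beta_ga = 0, beta_global = 0, residual_sd = 0)
  co <- make_cohort(sp)
  expect_true(all(co$bayley_motor == 90))
})

test_that("cohorts are reproducible, bounded and on the documented scale", {
  sp <- cohort_spec(n_subjects = 5000, seed = 21)
  co <- make_cohort(sp)
  expect_identical(co, make_cohort(sp))
  expect_true(all(co$bayley_motor >= 40 & co$bayley_motor <= 160))
  expect_true(all(co$ndwma >= 0 & co$ndwma < 1))
  expect_true(all(co$visual_dwma_grade %in% 0:3))
  # Monte-Carlo check of the normalized-DWMA scale
  expect_gt(median(co$ndwma), 0.003)
  expect_lt(median(co$ndwma), 0.015)
})

test_that("OLS refit recovers the generating DWMA coefficient", {
  st <- cohort_recovery_study(n_replicates = 5, n_subjects = 5000, seed = 3)
  expect_true(all(st$ok_lin))
  expect_true(all(st$ok_log))
})
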