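# Cerebral statistics, centrum semiovale definition, DWMA detection.

test_that("cerebral stats: constant case, enumeration oracle, tau monotonicity", {
  fx <- fixture_default()
  nv <- fx$pipe$normalized
  seg <- fx$pipe$segmentation
  st <- cerebral_stats(nv, seg, 0.95)
  # brute-force loop over eligible voxels
  el <- seg$posteriors[, , , "gm"] >= 0.95 | seg$posteriors[, , , "wm"] >= 0.95
  x <- nv$data[el]
  expect_identical(st[["n"]], as.numeric(length(x)))
  expect_equal(st[["mean"]], mean(x))
  expect_equal(st[["sd"]], sqrt(mean((x - mean(x))^2)))
  # raising tau never enlarges the eligible set
  st99 <- cerebral_stats(nv, seg, 0.99)
  expect_lte(st99[["n"]], st[["n"]])

  # constant intensities give sd 0
  d <- c(6, 6, 6)
  post <- array(0, c(d, 3)); post[, , , 3] <- 1
  dimnames(post) <- list(NULL, NULL, NULL, c("csf", "gm", "wm"))
  segc <- structure(list(posteriors = post, mask = array(TRUE, d),
                         voxel_dims = c(1, 1, 1)), class = "tissue_segmentation")
  vc <- brain_volume(array(42, d), c(1, 1, 1))
  expect_equal(unname(cerebral_stats(vc, segc)[c("mean", "sd")]), c(42, 0))
})

test_that("centrum semiovale sits on the two slices above the ventricles", {
  fx <- fixture_default()
  cs <- fx$pipe$cs_mask
  vent <- fx$pipe$ventricles
  k <- max(which(apply(vent, 3, any)))
  slices <- which(apply(cs, 3, any))
  expect_identical(slices, c(k + 1L, k + 2L))
  # subset of hard WM labels
  wm <- hard_labels(fx$pipe$segmentation) == 3L
  expect_true(all(!cs | wm))
  # brute-force reconstruction
  cfg <- dwma_config()
  d <- dim(vent)
  oracle <- erode_inplane(wm, 1)
  keepz <- array(FALSE, d); keepz[, , (k + 1):(k + 2)] <- TRUE
  oracle <- oracle & keepz
  mid <- (d[1] + 1) / 2
  band <- abs(seq_len(d[1]) - mid) <= cfg$midline_exclusion_voxels
  oracle[band, , ] <- FALSE
  expect_identical(cs, oracle)
})

test_that("centrum semiovale errors when slices run off the grid or are empty", {
  fx <- fixture_default()
  seg <- fx$pipe$segmentation
  vent_top <- array(FALSE, dim(fx$pipe$ventricles))
  vent_top[40, 40, dim(vent_top)[3] - 1L] <- TRUE
  expect_error(centrum_semiovale_mask(seg, vent_top, dwma_config()),
               "exceed")
  expect_error(centrum_semiovale_mask(seg, vent_top & FALSE, dwma_config()),
               "empty")
})

test_that("an extreme threshold yields an empty, zero-volume result", {
  fx <- fixture_default()
  res <- detect_dwma(fx$pipe$normalized, fx$pipe$segmentation, fx$pipe$cs_mask,
                     dwma_config(alpha = 10))
  expect_equal(res$n_voxels, 0)
  expect_equal(res$volume_mm3, 0)
  expect_equal(res$normalized_volume, 0)
  expect_equal(normalized_dwma(res), 0)
})

test_that("DWMA count is non-increasing in alpha and masks nest", {
  fx <- fixture_default()
  masks <- lapply(c(1.5, 1.8, 2.0), function(a)
    detect_dwma(fx$pipe$normalized, fx$pipe$segmentation, fx$pipe$cs_mask,
                dwma_config(alpha = a))$mask)
  expect_gte(sum(masks[[1]]), sum(masks[[2]]))
  expect_gte(sum(masks[[2]]), sum(masks[[3]]))
  # nesting of the raw candidate sets is inherited by the filtered masks:
  # a surviving component at a stricter alpha lies inside a (larger)
  # surviving component at the looser one
  expect_true(all(!masks[[3]] | masks[[2]]))
  expect_true(all(!masks[[2]] | masks[[1]]))
})

test_that("volume identity and normalization arithmetic are exact", {
  fx <- fixture_default()
  res <- fx$pipe$result
  expect_identical(res$volume_mm3, res$n_voxels * prod(res$voxel_dims))
  expect_identical(res$normalized_volume, res$volume_mm3 / res$wm_volume_mm3)
  expect_identical(normalized_dwma(res), res$normalized_volume)
  expect_true(res$normalized_volume >= 0 && res$normalized_volume < 1)
  # mask is confined to the centrum semiovale
  expect_true(all(!res$mask | fx$pipe$cs_mask))
  # worked numbers: 86.49 / 86490 = 0.001
  toy <- structure(list(n_voxels = 100L, volume_mm3 = 86.49,
                        wm_volume_mm3 = 86490, normalized_volume = 86.49 / 86490,
                        mask = array(TRUE, c(1, 1, 1)), voxel_dims = c(0.93, 0.93, 1)),
                   class = "dwma_result")
  expect_equal(normalized_dwma(toy), 0.001)
})

test_that("detection recovers the injected lesion on the default phantom", {
  fx <- fixture_default()
  res <- fx$pipe$result
  tr <- fx$phantom$truth
  expect_gte(dice_coef(res$mask, tr$dwma_mask), 0.7)
  expect_lt(abs(res$n_voxels - sum(tr$dwma_mask)) / sum(tr$dwma_mask), 0.3)
})

test_that("the DWMA mask is invariant to positive affine intensity maps", {
  fx <- fixture_default()
  cfg <- pipeline_config(bias_order = 0)     # isolate the affine property
  p1 <- run_pipeline(fx$phantom$volume, fx$atlas, cfg)
  va <- brain_volume(1.9 * fx$phantom$volume$data + 33,
                     fx$phantom$volume$voxel_dims)
  p2 <- run_pipeline(va, fx$atlas, cfg)
  expect_identical(p1$result$mask, p2$result$mask)
  # with bias correction on, pure rescaling is still exactly invariant
  cfgb <- pipeline_config()
  q1 <- run_pipeline(fx$phantom$volume, fx$atlas, cfgb)
  q2 <- run_pipeline(brain_volume(4 * fx$phantom$volume$data,
                                  fx$phantom$volume$voxel_dims), fx$atlas, cfgb)
  expect_identical(q1$result$mask, q2$result$mask)
})
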