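test_that("largest_component keeps the biggest blob only", {
  v <- array(0, c(12, 12, 12))
  v[2:3, 2:6, 2] <- 1                        # 10-voxel blob
  v[8:9, 8:9, 8] <- 1                        # 4-voxel blob
  v[8, 8, 10] <- 1                           # isolated voxel
  lab <- label_map(v)
  out <- largest_component(lab)
  expect_equal(sum(out$voxels), 10)
  expect_true(all(out$voxels[2:3, 2:6, 2] == 1))
  rep <- component_report(out)
  expect_equal(rep$count, 1L)
})

test_that("largest_component is idempotent and passes empty through", {
  lab <- sphere_label(10, radius = 3)
  expect_equal(largest_component(largest_component(lab))$voxels,
               largest_component(lab)$voxels)
  empty <- label_map(array(0, c(4, 4, 4)))
  expect_equal(sum(largest_component(empty)$voxels), 0)
})

test_that("size ties break toward the smaller lexicographic corner", {
  v <- array(0, c(10, 10, 10))
  v[7:8, 7, 7] <- 1            # two-voxel blob, corner (7,7,7)
  v[2:3, 8, 8] <- 1            # two-voxel blob, corner (2,8,8) -> smaller x
  out <- largest_component(label_map(v))
  expect_equal(sum(out$voxels), 2)
  expect_equal(out$voxels[2, 8, 8], 1)
})

test_that("component labeling matches the flood-fill oracle on random masks", {
  set.seed(51)
  for (i in 1:20) {
    mask <- array(runif(16^3) < 0.22, c(16, 16, 16))
    if (!any(mask)) next
    lab <- label_map(array(as.numeric(mask), c(16, 16, 16)))
    out <- largest_component(lab, connectivity = 26L)
    oracle <- oracle_components(mask, connectivity = 26L)
    sizes <- tabulate(oracle[oracle > 0])
    expect_equal(sum(out$voxels), max(sizes))
    # output is exactly one oracle component
    kept <- unique(oracle[out$voxels > 0])
    expect_length(kept, 1)
    rep <- component_report(lab, connectivity = 26L)
    expect_equal(rep$count, max(oracle))
    expect_equal(rep$sizes, sort(sizes, decreasing = TRUE))
  }
})

test_that("6- and 26-connectivity differ on diagonal touching", {
  v <- array(0, c(4, 4, 4))
  v[1, 1, 1] <- 1; v[2, 2, 2] <- 1
  lab <- label_map(v)
  expect_equal(component_report(lab, 26L)$count, 1L)
  expect_equal(component_report(lab, 6L)$count, 2L)
})

test_that("postprocess_segmentation composes clean-up, fill and resampling", {
  # hollow shell + satellite on a coarse working grid; original is finer
  shell <- array(0, c(16, 16, 16))
  shell[4:12, 4:12, 4:12] <- 1
  shell[5:11, 5:11, 5:11] <- 0
  shell[14, 14, 14] <- 1                     # satellite artifact
  raw <- label_map(shell, spacing = c(0.4, 0.4, 0.4))
  original <- volume_image(array(0, c(32, 32, 32)),
                           spacing = c(0.2, 0.2, 0.2))
  out <- postprocess_segmentation(raw, original)
  expect_identical(dim(out$voxels), c(32L, 32L, 32L))
  expect_equal(out$spacing, original$spacing)
  # satellite gone, cavity filled: compose the three stage oracles
  expected <- oracle_fill_holes(
    oracle_components(shell > 0, 26L) ==
      oracle_components(shell > 0, 26L)[4, 4, 4])
  exp_lab <- label_map(array(as.numeric(expected), c(16, 16, 16)),
                       spacing = c(0.4, 0.4, 0.4))
  expect_equal(out$voxels,
               resample_to_reference(exp_lab, original)$voxels)
  expect_equal(component_report(out)$count, 1L)
})

test_that("postprocess on a clean same-geometry input is the identity", {
  lab <- sphere_label(12, radius = 4)
  lab2 <- canonicalize_label(lab)
  out <- postprocess_segmentation(lab2, lab2)
  expect_equal(out$voxels, lab2$voxels)
  # empty raw yields an empty output on the requested geometry
  empty <- label_map(array(0, c(8, 8, 8)), spacing = c(0.4, 0.4, 0.4))
  ref <- volume_image(array(0, c(12, 12, 12)), spacing = c(0.3, 0.3, 0.3))
  out2 <- postprocess_segmentation(empty, ref)
  expect_equal(sum(out2$voxels), 0)
  expect_identical(dim(out2$voxels), c(12L, 12L, 12L))
})

test_that("postprocess never increases the component count", {
  set.seed(52)
  for (i in 1:10) {
    mask <- array(as.numeric(runif(12^3) < 0.25), c(12, 12, 12))
    lab <- label_map(mask, spacing = c(0.4, 0.4, 0.4))
    if (sum(mask) == 0) next
    before <- component_report(lab)$count
    out <- postprocess_segmentation(lab, lab)
    expect_lte(component_report(out)$count, min(before, 1L))
  }
})

test_that("predict_pipeline with an oracle model recovers the phantom truth", {
  # a noiseless solid phantom is exactly recoverable by thresholding, so a
  # threshold stub stands in for a perfectly trained network
  stub <- function(crop) {
    d <- dim(crop)
    fg <- as.numeric(crop > 0.5)
    array(c(1 - fg, fg), c(d, 2))
  }
  sp <- phantom_spec(grid_size = 32L, cavity = FALSE, n_satellites = 0L,
                     noise_sd = 0.01, seed = 61)
  ph <- generate_phantom(sp)
  # force the working spacing so no resampling happens
  ph$image$spacing <- c(0.4, 0.4, 0.4); ph$label$spacing <- c(0.4, 0.4, 0.4)
  seg <- predict_pipeline(stub, ph$image, spec = sliding_window_spec(16L, 0.2))
  expect_equal(dice_coefficient(seg, ph$label), 1)
  expect_true(same_geometry(seg, ph$image))

  # a finer-grained scan passes through resampling and returns to its own
  # grid with near-perfect overlap
  ph2 <- generate_phantom(phantom_spec(grid_size = 48L, cavity = FALSE,
                                       n_satellites = 0L, noise_sd = 0.01,
                                       seed = 62))
  ph2$image$spacing <- c(0.25, 0.25, 0.25)
  ph2$label$spacing <- c(0.25, 0.25, 0.25)
  seg2 <- predict_pipeline(stub, ph2$image,
                           spec = sliding_window_spec(16L, 0.2))
  expect_identical(dim(seg2$voxels), dim(ph2$image$voxels))
  expect_gte(dice_coefficient(seg2, ph2$label), 0.95)
})

test_that("the pipeline is deterministic for fixed weights and flags", {
  model <- unetr_init(micro_config(), seed = 63)
  ph <- generate_phantom(phantom_spec(grid_size = 24L, seed = 64))
  ph$image$spacing <- c(0.4, 0.4, 0.4)
  a <- predict_pipeline(model, ph$image, spec = sliding_window_spec(8L, 0.5))
  b <- predict_pipeline(model, ph$image, spec = sliding_window_spec(8L, 0.5))
  expect_identical(a$voxels, b$voxels)
})
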