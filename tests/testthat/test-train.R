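test_that("split_dataset slices each centre proportionally and deterministically", {
  one <- list(a = sprintf("f%02d", 1:10))
  sp <- split_dataset(one, c(0.7, 0.1, 0.2), seed = 1)
  expect_length(sp$train, 7)
  expect_length(sp$val, 1)
  expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$val, sp$test), one$a)

  two <- list(a = sprintf("a%02d", 1:10), b = sprintf("b%02d", 1:10))
  sp2 <- split_dataset(two, c(0.7, 0.1, 0.2), seed = 5)
  for (p in c("train", "val", "test")) {
    na <- sum(grepl("^a", sp2[[p]])); nb <- sum(grepl("^b", sp2[[p]]))
    expect_equal(na, nb)        # each centre contributes 7/1/2
  }
  expect_length(sp2$train, 14)

  expect_identical(split_dataset(two, seed = 42), split_dataset(two, seed = 42))
  expect_error(split_dataset(two, c(0.5, 0.2, 0.2)),
               class = "cbctseg_config_error")
  expect_error(split_dataset(list(a = character())),
               class = "cbctseg_config_error")
})

test_that("per-centre proportions stay within one file of the global fractions", {
  centers <- list(a = sprintf("a%d", 1:13), b = sprintf("b%d", 1:7),
                  c = sprintf("c%d", 1:21))
  sp <- split_dataset(centers, c(0.7, 0.1, 0.2), seed = 3)
  for (cn in names(centers)) {
    n <- length(centers[[cn]])
    for (i in 1:3) {
      part <- c("train", "val", "test")[i]
      got <- sum(sp[[part]] %in% centers[[cn]])
      expect_lte(abs(got - n * c(0.7, 0.1, 0.2)[i]), 1)
    }
  }
})

test_that("sample_crops draws aligned in-bounds crops", {
  set.seed(21)
  img <- volume_image(array(seq_len(20^3), c(20, 20, 20)))
  lab <- label_map(array(as.numeric(seq_len(20^3) %% 7 == 0), c(20, 20, 20)))
  crops <- sample_crops(img, lab, n_crops = 10, crop_edge = 8)
  expect_length(crops, 10)
  for (cr in crops) {
    expect_equal(dim(cr$image), c(8, 8, 8))
    # the image crop's first voxel identifies its corner; the whole crop
    # must equal the sub-grid there, and the label crop must be aligned
    v0 <- cr$image[1, 1, 1] - 1
    cx <- v0 %% 20; cy <- (v0 %/% 20) %% 20; cz <- v0 %/% 400
    expect_equal(cr$image,
                 img$voxels[cx + 1:8, cy + 1:8, cz + 1:8])
    expect_equal(cr$label,
                 lab$voxels[cx + 1:8, cy + 1:8, cz + 1:8])
  }
})

test_that("a crop-sized volume yields the volume itself; small ones are padded", {
  img <- volume_image(array(runif(8^3), c(8, 8, 8)))
  lab <- label_map(array(1, c(8, 8, 8)))
  crops <- sample_crops(img, lab, n_crops = 3, crop_edge = 8)
  for (cr in crops) expect_equal(cr$image, img$voxels)
  small <- volume_image(array(1, c(4, 4, 4)))
  slab <- label_map(array(1, c(4, 4, 4)))
  cr <- sample_crops(small, slab, 1, 8)[[1]]
  expect_equal(dim(cr$image), c(8, 8, 8))
  expect_equal(sum(cr$label), 64)        # original foreground preserved
})

test_that("augmentation with zero probabilities is the identity", {
  set.seed(22)
  pair <- list(image = array(runif(6^3), c(6, 6, 6)),
               label = array(as.numeric(runif(6^3) < 0.3), c(6, 6, 6)))
  spec <- augmentation_spec(flip_rot_prob_per_axis = 0,
                            intensity_shift_prob = 0, gamma_prob = 0)
  out <- augment_pair(pair, spec)
  expect_equal(out$image, pair$image)
  expect_equal(out$label, pair$label)
})

test_that("geometric augmentation preserves the label foreground count", {
  set.seed(23)
  for (i in 1:50) {
    pair <- list(image = array(runif(6^3), c(6, 6, 6)),
                 label = array(as.numeric(runif(6^3) < 0.3), c(6, 6, 6)))
    out <- augment_pair(pair, augmentation_spec())
    expect_equal(sum(out$label), sum(pair$label))
    expect_true(all(out$image >= 0 & out$image <= 1))
  }
})

test_that("recorded augmentation ops reproduce the transformation", {
  set.seed(24)
  pair <- list(image = array(runif(6^3), c(6, 6, 6)),
               label = array(as.numeric(runif(6^3) < 0.4), c(6, 6, 6)))
  for (i in 1:20) {
    out <- augment_pair(pair, augmentation_spec())
    ops <- attr(out, "ops")
    img <- pair$image; lab <- pair$label
    for (a in 1:3) {
      if (ops$flips[a]) {
        img <- cbctseg:::flip_axis(img, a); lab <- cbctseg:::flip_axis(lab, a)
      }
      if (ops$rotations[a]) {
        img <- cbctseg:::rot90_about(img, a)
        lab <- cbctseg:::rot90_about(lab, a)
      }
    }
    img <- img + ops$shift
    if (!is.na(ops$gamma)) img <- pmax(img, 0)^ops$gamma
    img <- pmin(pmax(img, 0), 1)
    expect_equal(out$image, img)
    expect_equal(out$label, lab)
  }
})

test_that("dice_loss matches its formula and the Dice coefficient identity", {
  expect_equal(dice_loss(rep(1, 8), rep(1, 8), eps = 0), 0)
  expect_equal(dice_loss(rep(1, 8), rep(0, 8), eps = 0), 1)
  expect_equal(dice_loss(rep(0.5, 4), c(1, 1, 0, 0), eps = 0), 1 / 3)
  set.seed(25)
  for (i in 1:20) {
    p <- as.numeric(runif(64) < 0.5)
    g <- as.numeric(runif(64) < 0.5)
    if (sum(p) + sum(g) == 0) next
    expect_equal(dice_loss(p, g, eps = 0),
                 1 - dice_coefficient(array(p, c(4, 4, 4)),
                                      array(g, c(4, 4, 4))),
                 tolerance = 1e-12)
  }
  expect_error(dice_loss(rep(1, 4), rep(1, 5)), class = "cbctseg_shape_error")
})

test_that("ce_loss matches its formula", {
  # uniform scores: -log(1/C)
  expect_equal(ce_loss(matrix(0, 3, 2), c(0, 1, 0)), log(2),
               tolerance = 1e-12)
  expect_equal(ce_loss(matrix(0, 3, 4), c(0, 3, 2)), log(4),
               tolerance = 1e-12)
  # saturated true-class score drives the loss to zero
  expect_lt(ce_loss(matrix(c(100, 0), 1, 2, byrow = TRUE), 0), 1e-10)
  # linear in the class weights
  set.seed(26)
  sc <- matrix(rnorm(20), 10, 2)
  y <- rbinom(10, 1, 0.5)
  expect_equal(ce_loss(sc, y, class_weights = c(2, 2)),
               2 * ce_loss(sc, y), tolerance = 1e-12)
})

test_that("combined_loss is the weighted average and validates weights", {
  expect_equal(combined_loss(0.4, 0.6, 1, 1), 0.5)
  expect_equal(combined_loss(0.4, 0.6, 1, 0), 0.4)
  expect_equal(combined_loss(0.4, 0.6, 0, 1), 0.6)
  expect_error(combined_loss(0.4, 0.6, 0, 0), class = "cbctseg_config_error")
})

test_that("the fused training loss agrees with the standalone losses", {
  set.seed(27)
  logits <- matrix(rnorm(128 * 2), 128, 2)
  target <- as.numeric(runif(128) < 0.3)
  tape <- cbctseg:::nn_tape()
  node <- cbctseg:::tp_leaf(tape, logits)
  fused <- cbctseg:::tp_dice_ce(tape, node, target, lambda_dice = 0.5,
                                lambda_ce = 0.5, eps = 1e-5)$value[1]
  p <- exp(logits) / rowSums(exp(logits))
  expect_equal(fused,
               combined_loss(dice_loss(p[, 2], target, eps = 1e-5),
                             ce_loss(logits, target), 0.5, 0.5),
               tolerance = 1e-10)
})

test_that("a short training run keeps its books and reduces the loss", {
  data <- phantom_records(4, 1, grid = 32L, seed = 31)
  recs <- data$records
  dataset <- list(train = recs[1:3], val = recs[4])
  cfg <- unetr_config(window_edge = 16L, patch_edge = 8L, hidden_dim = 16L,
                      mlp_dim = 32L, num_heads = 2L, num_layers = 2L,
                      feature_size = 4L, dropout_rate = 0)
  tconf <- train_config(n_images_per_batch = 1L, n_crops_per_image = 2L,
                        crop_edge = 16L, learning_rate = 1e-3,
                        epochs = 8L, seed = 7, val_augment = FALSE,
                        early_stop_dice = 2)
  fit <- train_model(dataset, cfg, tconf)
  expect_equal(nrow(fit$history), 8L)
  expect_equal(fit$batch_size, 2L)
  expect_lt(mean(tail(fit$history$train_loss, 2)),
            mean(head(fit$history$train_loss, 2)))
  expect_error(train_model(list(train = list(), val = recs[4]), cfg, tconf),
               class = "cbctseg_config_error")
})
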