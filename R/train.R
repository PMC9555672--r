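#' Training configuration
#'
#' Optimization settings for crop-based training. Defaults follow the
#' published runs: batches of `n_images_per_batch` scans with
#' `n_crops_per_image` random crops each (published runs: 10 x 10 = batch 100),
#' learning rate 1e-4, weight decay 1e-5, equal Dice/cross-entropy loss
#' weights, and a 70/10/20 train/validation/test split.
#'
#' @param n_images_per_batch scans drawn per batch (N_i).
#' @param n_crops_per_image random crops per scan (N_s).
#' @param crop_edge cubic crop edge, voxels; must equal the network's
#'   `window_edge`.
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled weight decay coefficient.
#' @param lambda_dice,lambda_ce nonnegative loss weights (not both zero).
#' @param epochs maximum training epochs.
#' @param seed master seed; all training randomness (split, crops,
#'   augmentation, weights, dropout) fans out from it.
#' @param split_fractions train/validation/test fractions, summing to 1.
#' @param val_overlap sliding-window overlap used for validation
#'   predictions.
#' @param val_augment apply the (non-crop) augmentations to validation
#'   scans as well, as in the published training loop.
#' @param early_stop_dice stop early once validation Dice reaches this
#'   value (set above 1 to disable).
#' @param early_stop_patience stop after this many epochs without a new
#'   best validation Dice (`Inf` to disable).
#' @param val_every validate every k-th epoch (default 1, i.e. every
#'   epoch); skipped epochs record `NA` validation Dice.
#' @return A `train_config` list.
#' @export
train_config <- function(n_images_per_batch = 10L, n_crops_per_image = 10L,
                         crop_edge = 128L, learning_rate = 1e-4,
                         weight_decay = 1e-5, lambda_dice = 0.5,
                         lambda_ce = 0.5, epochs = 30L, seed = 1L,
                         split_fractions = c(0.7, 0.1, 0.2),
                         val_overlap = 0.2, val_augment = TRUE,
                         early_stop_dice = 0.95, early_stop_patience = Inf,
                         val_every = 1L) {
  if (n_images_per_batch < 1L || n_crops_per_image < 1L)
    abort_cbctseg("batch composition counts must be >= 1",
                  "cbctseg_config_error")
  if (lambda_dice < 0 || lambda_ce < 0 || lambda_dice + lambda_ce <= 0)
    abort_cbctseg("loss weights must be nonnegative and not both zero",
                  "cbctseg_config_error")
  if (abs(sum(split_fractions) - 1) > 1e-9)
    abort_cbctseg("split_fractions must sum to 1", "cbctseg_config_error")
  structure(list(
    n_images_per_batch = as.integer(n_images_per_batch),
    n_crops_per_image = as.integer(n_crops_per_image),
    crop_edge = as.integer(crop_edge), learning_rate = learning_rate,
    weight_decay = weight_decay, lambda_dice = lambda_dice,
    lambda_ce = lambda_ce, epochs = as.integer(epochs),
    seed = as.integer(seed), split_fractions = as.numeric(split_fractions),
    val_overlap = val_overlap, val_augment = isTRUE(val_augment),
    early_stop_dice = early_stop_dice,
    early_stop_patience = early_stop_patience,
    val_every = as.integer(val_every)), class = "train_config")
}

#' Data augmentation specification
#'
#' Event probabilities and magnitudes of the training augmentations:
#' per-axis random flip and 90-degree rotation (25% each, applied
#' identically to image and label), a signed intensity shift of 0.1 with
#' 50% probability, and a gamma (contrast) change drawn uniformly from
#' \[0.5, 2\] with 80% probability. Intensity operations touch the image
#' only; the image is re-clamped to \[0, 1\] afterwards.
#'
#' @param flip_rot_prob_per_axis per-axis probability of a flip, and
#'   independently of a 90-degree rotation.
#' @param intensity_shift_prob probability of the intensity shift.
#' @param intensity_shift_magnitude absolute shift size.
#' @param gamma_prob probability of the gamma change.
#' @param gamma_range positive interval for the gamma exponent.
#' @return An `augmentation_spec` list.
#' @export
augmentation_spec <- function(flip_rot_prob_per_axis = 0.25,
                              intensity_shift_prob = 0.5,
                              intensity_shift_magnitude = 0.1,
                              gamma_prob = 0.8, gamma_range = c(0.5, 2)) {
  probs <- c(flip_rot_prob_per_axis, intensity_shift_prob, gamma_prob)
  if (any(probs < 0) || any(probs > 1))
    abort_cbctseg("probabilities must lie in [0, 1]", "cbctseg_config_error")
  if (any(gamma_range <= 0) || gamma_range[1] >= gamma_range[2])
    abort_cbctseg("gamma_range must be positive with lower < upper",
                  "cbctseg_config_error")
  structure(list(flip_rot_prob_per_axis = flip_rot_prob_per_axis,
                 intensity_shift_prob = intensity_shift_prob,
                 intensity_shift_magnitude = intensity_shift_magnitude,
                 gamma_prob = gamma_prob, gamma_range = as.numeric(gamma_range)),
            class = "augmentation_spec")
}

#' Split a multi-centre dataset into train/validation/test
#'
#' Files are shuffled and sliced *within each centre* so that every centre
#' contributes the same proportions to each partition — the guard against
#' over-fitting any single centre's acquisition protocol. Slicing uses
#' largest-remainder rounding, so per-centre counts deviate from the exact
#' fractions by at most one file.
#'
#' @param centers named list mapping centre id to a character vector of
#'   files (or any identifiers); every centre must be non-empty.
#' @param fractions train/validation/test fractions, summing to 1.
#' @param seed shuffle seed; the split is deterministic given it.
#' @return A `dataset_split` list with `train`, `val`, `test` character
#'   vectors and the per-centre assignment.
#' @export
split_dataset <- function(centers, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    abort_cbctseg("fractions must sum to 1", "cbctseg_config_error")
  if (length(centers) == 0L || any(lengths(centers) == 0L))
    abort_cbctseg("every centre must contribute at least one file",
                  "cbctseg_config_error")
  parts <- list(train = character(), val = character(), test = character())
  by_center <- list()
  for (ci in seq_along(centers)) {
    files <- centers[[ci]]
    files <- with_seed(derive_seed(seed, paste0("split", ci)),
                       sample(files, length(files)))
    n <- length(files)
    counts <- largest_remainder(n, fractions)
    idx <- rep(1:3, counts)
    assignment <- split(files, factor(idx, levels = 1:3,
                                      labels = c("train", "val", "test")))
    by_center[[names(centers)[ci] %||% as.character(ci)]] <- assignment
    for (p in names(parts)) parts[[p]] <- c(parts[[p]], assignment[[p]])
  }
  structure(c(parts, list(by_center = by_center, fractions = fractions)),
            class = "dataset_split")
}

`%||%` <- function(a, b) if (is.null(a) || identical(a, "")) b else a

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Randomly crop aligned image/label cube pairs
#'
#' Draws `n_crops` cubic crops with corners uniform over all valid
#' positions ("anywhere in the scan"); the image and label crops are taken
#' from the same location. Volumes smaller than the crop are zero-padded
#' symmetrically first.
#'
#' @param img a [volume_image()].
#' @param label the aligned [label_map()].
#' @param n_crops number of crops (N_s).
#' @param crop_edge cubic crop edge, voxels.
#' @return List of `n_crops` lists with elements `image` and `label`
#'   (plain 3D arrays).
#' @export
sample_crops <- function(img, label, n_crops, crop_edge) {
  if (!identical(dim(img$voxels), dim(label$voxels)))
    abort_cbctseg("image and label grids differ", "cbctseg_shape_error")
  iv <- pad_to_min(img$voxels, crop_edge, 0)
  lv <- pad_to_min(label$voxels, crop_edge, 0)
  d <- dim(iv)
  lapply(seq_len(n_crops), function(s) {
    corner <- vapply(1:3, function(a)
      sample.int(d[a] - crop_edge + 1L, 1L), 0L)
    ix <- lapply(1:3, function(a) corner[a]:(corner[a] + crop_edge - 1L))
    list(image = iv[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
         label = lv[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
  })
}

pad_to_min <- function(arr, edge, fill) {
  d <- dim(arr)
  if (all(d >= edge)) return(arr)
  nd <- pmax(d, edge)
  out <- array(fill, nd)
  lo <- pmax((nd - d) %/% 2, 0) + 1L
  out[lo[1]:(lo[1] + d[1] - 1L), lo[2]:(lo[2] + d[2] - 1L),
      lo[3]:(lo[3] + d[3] - 1L)] <- arr
  out
}

#' Augment one image/label crop pair
#'
#' Applies, per axis, a flip with probability
#' `spec$flip_rot_prob_per_axis` and, independently with the same
#' probability, a 90-degree rotation about that axis — identically to image
#' and label. Then, image only: a signed intensity shift (sign chosen
#' uniformly) and a gamma change, after which the image is clamped back to
#' \[0, 1\]. Label values are never touched by intensity operations.
#'
#' @param pair list with `image` and `label` cubic 3D arrays.
#' @param spec an [augmentation_spec()].
#' @return The augmented pair; an `"ops"` attribute records which events
#'   fired (`flips`, `rotations`, `shift`, `gamma`).
#' @export
augment_pair <- function(pair, spec = augmentation_spec()) {
  img <- pair$image; lab <- pair$label
  flips <- logical(3); rots <- logical(3)
  for (a in 1:3) {
    if (stats::runif(1) < spec$flip_rot_prob_per_axis) {
      flips[a] <- TRUE
      img <- flip_axis(img, a)
      lab <- flip_axis(lab, a)
    }
    if (stats::runif(1) < spec$flip_rot_prob_per_axis) {
      rots[a] <- TRUE
      img <- rot90_about(img, a)
      lab <- rot90_about(lab, a)
    }
  }
  shift <- 0
  if (stats::runif(1) < spec$intensity_shift_prob) {
    shift <- sample(c(-1, 1), 1) * spec$intensity_shift_magnitude
    img <- img + shift
  }
  gma <- NA_real_
  if (stats::runif(1) < spec$gamma_prob) {
    gma <- stats::runif(1, spec$gamma_range[1], spec$gamma_range[2])
    img <- pmax(img, 0)^gma
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, label = lab),
            ops = list(flips = flips, rotations = rots, shift = shift,
                       gamma = gma))
}

flip_axis <- function(arr, axis) {
  d <- dim(arr)
  switch(axis,
         arr[d[1]:1, , , drop = FALSE],
         arr[, d[2]:1, , drop = FALSE],
         arr[, , d[3]:1, drop = FALSE])
}

# 90-degree rotation about `axis` (the other two axes must be equal-sized).
rot90_about <- function(arr, axis) {
  d <- dim(arr)
  switch(axis,
         aperm(arr, c(1, 3, 2))[, d[3]:1, , drop = FALSE],
         aperm(arr, c(3, 2, 1))[, , d[1]:1, drop = FALSE],
         aperm(arr, c(2, 1, 3))[d[2]:1, , , drop = FALSE])
}

#' Dice loss
#'
#' `1 - (2 sum(p g) + eps) / (sum(p^2) + sum(g^2) + eps)` over all voxels.
#' Zero for a perfect binary prediction; the smoothing term `eps` keeps the
#' ratio defined on all-background crops (with `eps = 0` the formula is the
#' plain soft Dice loss and is undefined when both arguments are empty).
#'
#' @param p predicted foreground probabilities, any numeric array.
#' @param g binary ground truth, same shape.
#' @param eps smoothing added to numerator and denominator.
#' @return Scalar loss in \[0, 1\] (up to `eps` rounding).
#' @export
dice_loss <- function(p, g, eps = 1e-5) {
  if (!identical(dim(p) %||% length(p), dim(g) %||% length(g)))
    abort_cbctseg("p and g shapes differ", "cbctseg_shape_error")
  p <- as.numeric(p); g <- as.numeric(g)
  1 - (2 * sum(p * g) + eps) / (sum(p^2) + sum(g^2) + eps)
}

#' Cross-entropy loss on raw class scores
#'
#' Mean over voxels of the weighted negative log of the softmax-normalized
#' true-class score: `l_n = -w_{y_n} log(exp(x_{n,y_n}) / sum_c
#' exp(x_{n,c}))`.
#'
#' @param scores numeric matrix, one row per voxel, one column per class.
#' @param target integer class indices in `0..C-1`, one per voxel.
#' @param class_weights per-class nonnegative weights (default all 1).
#' @return Scalar nonnegative loss.
#' @export
ce_loss <- function(scores, target, class_weights = NULL) {
  scores <- as.matrix(scores)
  target <- as.integer(target)
  if (nrow(scores) != length(target))
    abort_cbctseg("scores and target lengths differ", "cbctseg_shape_error")
  C <- ncol(scores)
  if (any(target < 0L) || any(target >= C))
    abort_cbctseg("target classes out of range", "cbctseg_shape_error")
  if (is.null(class_weights)) class_weights <- rep(1, C)
  m <- scores - apply(scores, 1, max)
  logp <- m - log(rowSums(exp(m)))
  yi <- cbind(seq_along(target), target + 1L)
  mean(-class_weights[target + 1L] * logp[yi])
}

#' Weighted average of Dice and cross-entropy losses
#'
#' `(lambda_dice * DL + lambda_ce * CE) / (lambda_dice + lambda_ce)`.
#'
#' @param dl Dice loss value.
#' @param ce cross-entropy loss value.
#' @param lambda_dice,lambda_ce nonnegative weights, not both zero.
#' @return Scalar combined loss.
#' @export
combined_loss <- function(dl, ce, lambda_dice = 0.5, lambda_ce = 0.5) {
  if (lambda_dice < 0 || lambda_ce < 0 || lambda_dice + lambda_ce <= 0)
    abort_cbctseg("loss weights must be nonnegative and not both zero",
                  "cbctseg_config_error")
  (lambda_dice * dl + lambda_ce * ce) / (lambda_dice + lambda_ce)
}

# One Adam step with decoupled weight decay over a named gradient list.
adam_step <- function(state, params, grads, lr, wd, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] * (1 - lr * wd) - step
  }
  list(state = state, params = params)
}

adam_init <- function(params) {
  z <- lapply(params, function(p) p * 0)
  state <- new.env(parent = emptyenv())
  state$m <- z; state$v <- z; state$t <- 0L
  state
}

#' Train a UNETR model on a dataset split
#'
#' Per epoch: cycle through the training scans in groups of
#' `n_images_per_batch`, draw `n_crops_per_image` augmented random crops
#' from each (batch size N_i x N_s), and take one Adam step per batch on
#' the averaged combined Dice + cross-entropy loss. After each epoch the
#' model predicts every validation scan with sliding-window inference (no
#' cropping) and the mean validation Dice is logged; the weights with the
#' best validation Dice are returned. All randomness derives from
#' `train_config$seed`.
#'
#' @param dataset named list with `train` and `val`, each a list of
#'   records `list(image = volume_image, label = label_map)` (intensities
#'   already contrast-adjusted to \[0, 1\]).
#' @param config a [unetr_config()]; `window_edge` must equal
#'   `train_config$crop_edge`.
#' @param tconf a [train_config()].
#' @param aug an [augmentation_spec()].
#' @param verbose print per-epoch progress.
#' @return List with `model` (best-validation weights), `history`
#'   (data.frame: epoch, train_loss, val_dice), and `batch_size`.
#' @export
train_model <- function(dataset, config, tconf = train_config(),
                        aug = augmentation_spec(), verbose = FALSE) {
  if (length(dataset$train) == 0L || length(dataset$val) == 0L)
    abort_cbctseg("train and validation partitions must be non-empty",
                  "cbctseg_config_error")
  if (config$window_edge != tconf$crop_edge)
    abort_cbctseg("crop_edge must match the network window_edge",
                  "cbctseg_config_error")
  model <- unetr_init(config, seed = derive_seed(tconf$seed, "init"))
  opt <- adam_init(model$params)
  best <- list(dice = -Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_dice = numeric())
  n_train <- length(dataset$train)
  sw_spec <- sliding_window_spec(window_edge = config$window_edge,
                                 overlap = tconf$val_overlap)

  for (epoch in seq_len(tconf$epochs)) {
    eseed <- derive_seed(tconf$seed, paste0("epoch", epoch))
    losses <- with_seed(eseed, {
      ord <- sample.int(n_train)
      batch_starts <- seq(1L, n_train, by = tconf$n_images_per_batch)
      vapply(batch_starts, function(b) {
        ids <- ord[b:min(b + tconf$n_images_per_batch - 1L, n_train)]
        crops <- list()
        for (id in ids) {
          rec <- dataset$train[[id]]
          cs <- sample_crops(rec$image, rec$label, tconf$n_crops_per_image,
                             tconf$crop_edge)
          crops <- c(crops, lapply(cs, augment_pair, spec = aug))
        }
        grads <- NULL
        loss_sum <- 0
        for (cr in crops) {
          fw <- unetr_forward_tape(model, cr$image, train = TRUE)
          loss_node <- tp_dice_ce(fw$tape, fw$logits,
                                  as.numeric(cr$label > 0),
                                  lambda_dice = tconf$lambda_dice,
                                  lambda_ce = tconf$lambda_ce)
          tape_backward(fw$tape, loss_node)
          loss_sum <- loss_sum + loss_node$value[1]
          g1 <- mapply(function(nd, p) if (is.null(nd$grad)) p * 0
                       else nd$grad, fw$leaves, model$params,
                       SIMPLIFY = FALSE)
          grads <- if (is.null(grads)) g1
                   else mapply(`+`, grads, g1, SIMPLIFY = FALSE)
        }
        grads <- lapply(grads, function(g) g / length(crops))
        upd <- adam_step(opt, model$params, grads, tconf$learning_rate,
                         tconf$weight_decay)
        model$params <<- upd$params
        loss_sum / length(crops)
      }, 0)
    })

    do_val <- epoch %% (tconf$val_every %||% 1L) == 0L ||
      epoch == tconf$epochs
    val_dice <- if (!do_val) NA_real_ else
      with_seed(derive_seed(tconf$seed, paste0("val", epoch)), {
      mean(vapply(dataset$val, function(rec) {
        iv <- rec$image; lv <- rec$label
        if (tconf$val_augment) {
          pr <- augment_pair(list(image = iv$voxels, label = lv$voxels), aug)
          iv <- volume_image(pr$image, iv$spacing, iv$origin, iv$direction)
          lv <- label_map(pr$label, lv$spacing, lv$origin, lv$direction)
        }
        probs <- sliding_window_predict(model, iv, sw_spec)
        pred <- argmax_segment(probs)
        dice_coefficient(pred, lv)
      }, 0))
    })

    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_dice = val_dice))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f, val dice %s",
                      epoch, mean(losses),
                      ifelse(is.na(val_dice), "-", sprintf("%.4f", val_dice))))
    if (!is.na(val_dice) && val_dice > best$dice)
      best <- list(dice = val_dice, params = model$params, epoch = epoch)
    if (!is.na(val_dice) && val_dice >= tconf$early_stop_dice) break
    if (epoch - best$epoch >= (tconf$early_stop_patience %||% Inf)) break
  }
  model$params <- best$params
  list(model = model, history = history,
       batch_size = tconf$n_images_per_batch * tconf$n_crops_per_image)
}
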