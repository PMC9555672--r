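# Shared fixtures: tiny network configurations, geometric masks, and a
# minimal DICOM writer used to exercise the series reader.

# Micro configuration: fast enough for property tests and gradient checks.
micro_config <- function(dropout = 0) {
  unetr_config(window_edge = 8L, patch_edge = 4L, hidden_dim = 12L,
               mlp_dim = 24L, num_heads = 2L, num_layers = 2L,
               feature_size = 4L, dropout_rate = dropout)
}

# The small-scale experiment configuration.
tiny_config <- function(dropout = 0.05) {
  unetr_config(window_edge = 32L, patch_edge = 16L, hidden_dim = 64L,
               mlp_dim = 128L, num_heads = 4L, num_layers = 2L,
               feature_size = 16L, dropout_rate = dropout)
}

# Binary sphere mask as a label_map.
sphere_label <- function(n, centre = rep((n + 1) / 2, 3), radius = n / 4,
                         spacing = c(1, 1, 1)) {
  ax <- seq_len(n)
  r2 <- outer(outer((ax - centre[1])^2, (ax - centre[2])^2, `+`),
              (ax - centre[3])^2, `+`)
  label_map(array(as.numeric(r2 <= radius^2), c(n, n, n)), spacing)
}

random_binary_label <- function(n, p = 0.3, spacing = c(1, 1, 1)) {
  label_map(array(as.numeric(stats::runif(n^3) < p), c(n, n, n)), spacing)
}

# In-memory phantom dataset records for training tests: contrast-adjusted
# images paired with ground-truth labels, organized by pseudo-centre.
phantom_records <- function(n_per_center, n_centers, grid = 64L, seed = 1L,
                            ...) {
  recs <- list()
  centers <- list()
  for (ci in seq_len(n_centers)) {
    ids <- character()
    for (k in seq_len(n_per_center)) {
      sp <- phantom_spec(grid_size = grid,
                         seed = cbctseg:::derive_seed(seed,
                                                      sprintf("c%dp%d", ci, k)),
                         intensity_offset = (ci - 1) * 0.08, ...)
      ph <- generate_phantom(sp)
      id <- sprintf("c%d_%d", ci, k)
      recs[[id]] <- list(image = contrast_adjust(ph$image),
                         label = ph$label)
      ids <- c(ids, id)
    }
    centers[[sprintf("center%d", ci)]] <- ids
  }
  list(records = recs, centers = centers)
}

# ---- independent oracles ----------------------------------------------------

# Queue-based flood fill labeling of a logical mask; independent of the
# package's graph-based implementation.
oracle_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18L)
    offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  labels <- array(0L, d)
  cur <- 0L
  seeds <- which(mask)
  stack <- integer(prod(d))
  for (s in seeds) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    stack[1] <- s; top <- 1L
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      v0 <- v - 1L
      vx <- v0 %% d[1] + 1L
      vy <- (v0 %/% d[1]) %% d[2] + 1L
      vz <- v0 %/% (d[1] * d[2]) + 1L
      for (o in seq_len(nrow(offs))) {
        wx <- vx + offs[o, 1]; wy <- vy + offs[o, 2]; wz <- vz + offs[o, 3]
        if (wx < 1 || wy < 1 || wz < 1 || wx > d[1] || wy > d[2] ||
            wz > d[3]) next
        w <- wx + d[1] * (wy - 1L) + d[1] * d[2] * (wz - 1L)
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- cur
          top <- top + 1L; stack[top] <- w
        }
      }
    }
  }
  labels
}

# Fill-hole oracle: background components (6-connectivity) not touching
# the border become foreground.
oracle_fill_holes <- function(fg) {
  labels <- oracle_components(!fg, connectivity = 6L)
  d <- dim(fg)
  border_labels <- unique(c(labels[c(1, d[1]), , ], labels[, c(1, d[2]), ],
                            labels[, , c(1, d[3])]))
  border_labels <- setdiff(border_labels, 0L)
  fg | (labels != 0L & !(labels %in% border_labels))
}

# Naive per-voxel confusion loop (the counting oracle).
oracle_confusion <- function(pred, gt) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] > 0 && gt[i] > 0) tp <- tp + 1L
    else if (pred[i] > 0) fp <- fp + 1L
    else if (gt[i] > 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# All-thresholds trapezoidal AUPRC oracle.
oracle_auprc <- function(probs, gt) {
  thr <- sort(unique(as.numeric(probs)), decreasing = TRUE)
  npos <- sum(gt > 0)
  rec <- numeric(0); prec <- numeric(0)
  for (t in thr) {
    pred <- as.numeric(probs) >= t
    tp <- sum(pred & gt > 0)
    rec <- c(rec, tp / npos)
    prec <- c(prec, tp / sum(pred))
  }
  if (rec[1] > 0) { rec <- c(0, rec); prec <- c(prec[1], prec) }
  if (rec[length(rec)] < 1) {
    rec <- c(rec, 1); prec <- c(prec, npos / length(gt))
  }
  sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
}

# ---- minimal DICOM writer (explicit VR little endian) -----------------------
# Writes one single-frame 16-bit slice per file: just enough of the
# standard to round-trip the series reader.

write_test_dicom_series <- function(dir, arr, spacing, origin = c(0, 0, 0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(arr)
  for (k in seq_len(d[3])) {
    slice <- arr[, , k]
    path <- file.path(dir, sprintf("slice_%03d.dcm", k))
    con <- file(path, "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    el <- function(group, element, vr, bytes) {
      if (length(bytes) %% 2 == 1) bytes <- c(bytes, as.raw(0))
      writeBin(writeBin(c(group, element), raw(), size = 2,
                        endian = "little"), con)
      writeBin(charToRaw(vr), con)
      if (vr %in% c("OB", "OW")) {
        writeBin(raw(2), con)
        writeBin(length(bytes), con, size = 4, endian = "little")
      } else {
        writeBin(length(bytes), con, size = 2, endian = "little")
      }
      writeBin(bytes, con)
    }
    str_el <- function(group, element, vr, s)
      el(group, element, vr, charToRaw(s))
    ts <- "1.2.840.10008.1.2.1"
    str_el(0x0002L, 0x0010L, "UI", ts)
    el(0x0028L, 0x0010L, "US",
       writeBin(d[2], raw(), size = 2, endian = "little"))   # rows (y)
    el(0x0028L, 0x0011L, "US",
       writeBin(d[1], raw(), size = 2, endian = "little"))   # cols (x)
    el(0x0028L, 0x0100L, "US",
       writeBin(16L, raw(), size = 2, endian = "little"))
    el(0x0028L, 0x0103L, "US",
       writeBin(0L, raw(), size = 2, endian = "little"))
    str_el(0x0028L, 0x0030L, "DS",
           sprintf("%g\\%g", spacing[2], spacing[1]))
    str_el(0x0020L, 0x0032L, "DS",
           sprintf("%g\\%g\\%g", origin[1], origin[2],
                   origin[3] + (k - 1) * spacing[3]))
    str_el(0x0020L, 0x0037L, "DS", "1\\0\\0\\0\\1\\0")
    # pixel data: row-major (y rows with x fastest), unsigned 16-bit
    px <- as.integer(slice)
    el(0x7FE0L, 0x0010L, "OW",
       writeBin(px, raw(), size = 2, endian = "little"))
    close(con)
  }
  dir
}
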