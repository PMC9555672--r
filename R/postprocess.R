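#' Keep only the largest connected component
#'
#' Labels the foreground of a binary segmentation into connected components
#' (26-connectivity by default, the dual of the 6-connected background used
#' for hole filling) and keeps the component with the most voxels, removing
#' stray artifacts such as disconnected satellite blobs. On a tie, the
#' component whose lexicographically smallest (x, y, z) corner is smallest
#' wins. An empty input passes through empty.
#'
#' @param label a binary [label_map()].
#' @param connectivity 6, 18 or 26.
#' @return A binary [label_map()] with at most one connected component.
#' @export
largest_component <- function(label, connectivity = 26L) {
  validate_geometry(label)
  fg <- label$voxels > 0
  if (!any(fg)) return(label)
  comp <- connected_components_mask(fg, connectivity)
  sizes <- tabulate(comp$membership)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: smallest lexicographic (x,y,z) minimal corner
    d <- dim(fg)
    v0 <- comp$voxel_ids - 1L
    key <- (v0 %% d[1]) * d[2] * d[3] + ((v0 %/% d[1]) %% d[2]) * d[3] +
      v0 %/% (d[1] * d[2])
    corner <- vapply(best, function(b)
      min(key[comp$membership == b]), 0)
    best <- best[which.min(corner)]
  }
  keep <- comp$voxel_ids[comp$membership == best]
  out <- array(0, dim(fg))
  out[keep] <- 1
  label_map(out, label$spacing, label$origin, label$direction,
            n_classes = 2L)
}

#' Count connected components of a binary label map
#'
#' @param label a binary [label_map()].
#' @param connectivity 6, 18 or 26.
#' @return List with `count` and sorted decreasing `sizes` (voxel counts).
#' @export
component_report <- function(label, connectivity = 26L) {
  fg <- label$voxels > 0
  if (!any(fg)) return(list(count = 0L, sizes = integer()))
  comp <- connected_components_mask(fg, connectivity)
  sizes <- sort(tabulate(comp$membership), decreasing = TRUE)
  list(count = length(sizes), sizes = sizes)
}

# Connected components of a logical 3D mask. Builds the voxel adjacency
# edge list for the requested connectivity and labels components via
# breadth-first search over the compacted foreground graph.
connected_components_mask <- function(mask, connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    abort_cbctseg("connectivity must be 6, 18 or 26",
                  "cbctseg_config_error")
  d <- dim(mask)
  ids <- which(mask)
  n <- length(ids)
  rank <- integer(prod(d))
  rank[ids] <- seq_len(n)

  offs <- half_neighborhood(connectivity)
  lin <- array(seq_len(prod(d)), d)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    rx <- seq_len(d[1] - abs(o[1])); ry <- seq_len(d[2] - abs(o[2]))
    rz <- seq_len(d[3] - abs(o[3]))
    sx <- rx + max(o[1], 0); sy <- ry + max(o[2], 0); sz <- rz + max(o[3], 0)
    tx <- rx + max(-o[1], 0); ty <- ry + max(-o[2], 0); tz <- rz + max(-o[3], 0)
    src <- mask[sx, sy, sz, drop = FALSE] & mask[tx, ty, tz, drop = FALSE]
    if (!any(src)) next
    a <- lin[sx, sy, sz, drop = FALSE][src]
    b <- lin[tx, ty, tz, drop = FALSE][src]
    from <- c(from, rank[a]); to <- c(to, rank[b])
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  membership <- as.integer(igraph::components(g)$membership)
  list(voxel_ids = ids, membership = membership)
}

half_neighborhood <- function(connectivity) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  # keep one direction per offset pair
  keep <- offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
    (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0)
  offs[keep, , drop = FALSE]
}

#' Clean a raw segmentation and restore the original geometry
#'
#' The post-processing pipeline applied to the raw argmax output: keep the
#' largest connected component, fill internal holes (on the working grid,
#' where the operation is scale-consistent), and resample the result onto
#' the original scan geometry with nearest-neighbour interpolation.
#'
#' @param raw binary [label_map()] on the working (e.g. 0.4 mm) grid.
#' @param original a [volume_image()] or geometry list giving the target
#'   geometry.
#' @param connectivity component connectivity (default 26).
#' @return A binary [label_map()] with geometry equal to `original`.
#' @export
postprocess_segmentation <- function(raw, original, connectivity = 26L) {
  cleaned <- largest_component(raw, connectivity)
  if (any(cleaned$voxels > 0))
    cleaned <- canonicalize_label(cleaned)
  resample_to_reference(cleaned, original)
}

#' End-to-end prediction pipeline for one scan
#'
#' Mirrors the full deployment path: the input scan is preserved; a working
#' copy is resampled to the working spacing (0.4 mm by default) if needed,
#' contrast-adjusted, segmented by sliding-window inference plus argmax,
#' cleaned (largest component, fill holes) and resampled back onto the
#' input scan's exact geometry.
#'
#' @param model a `unetr_model` or prediction function (see
#'   [sliding_window_predict()]).
#' @param raw_scan the unprocessed [volume_image()].
#' @param contrast a [contrast_params()].
#' @param spec a [sliding_window_spec()].
#' @param working_spacing working grid spacing in mm (scalar or length 3).
#' @param keep_probs also return the working-grid probability volume.
#' @return A binary [label_map()] overlaying `raw_scan` voxel-for-voxel;
#'   with `keep_probs = TRUE`, a list with `segmentation` and `probs`.
#' @export
predict_pipeline <- function(model, raw_scan, contrast = contrast_params(),
                             spec = sliding_window_spec(),
                             working_spacing = 0.4, keep_probs = FALSE) {
  validate_geometry(raw_scan)
  work <- raw_scan
  if (max(abs(work$spacing - rep(working_spacing, length.out = 3))) > 1e-9)
    work <- resample_to_spacing(work, working_spacing, mode = "linear")
  work <- contrast_adjust(work, contrast)
  probs <- sliding_window_predict(model, work, spec)
  raw_seg <- argmax_segment(probs)
  seg <- postprocess_segmentation(raw_seg, raw_scan)
  if (keep_probs) list(segmentation = seg, probs = probs) else seg
}
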