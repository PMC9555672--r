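#' Contrast-adjustment percentile parameters
#'
#' Bounds, as percentages on the cumulative intensity histogram, between
#' which the scan intensities are kept before rescaling to \[0, 1\]. The
#' pipeline defaults are 1% and 99%.
#'
#' @param x_min_pct lower percentile in \[0, 100).
#' @param x_max_pct upper percentile in (0, 100\].
#' @param n_bins histogram bin count used when the image has more distinct
#'   intensities than bins.
#' @return A `contrast_params` list.
#' @export
contrast_params <- function(x_min_pct = 1, x_max_pct = 99, n_bins = 1024L) {
  if (!is.finite(x_min_pct) || !is.finite(x_max_pct) ||
      x_min_pct < 0 || x_max_pct > 100 || x_min_pct >= x_max_pct)
    abort_cbctseg("need 0 <= x_min_pct < x_max_pct <= 100",
                  "cbctseg_config_error")
  structure(list(x_min_pct = x_min_pct, x_max_pct = x_max_pct,
                 n_bins = as.integer(n_bins)),
            class = "contrast_params")
}

#' Percentile-based contrast adjustment to \[0, 1\]
#'
#' Builds the cumulative intensity distribution of the scan *ignoring the
#' background*, picks new minimum and maximum intensities at the
#' `x_min_pct` / `x_max_pct` points of that cumulative curve, clamps the
#' image between them and rescales affinely to \[0, 1\]. The background is
#' taken to be the modal intensity (in CBCT the air outside the field of
#' view dominates the histogram and is near-constant). When the image has
#' few distinct values the cumulative curve is exact; otherwise it is
#' binned (`params$n_bins` uniform bins) and percentiles are read off bin
#' right edges. The endpoint percentiles 0 and 100 fall back to the global
#' minimum/maximum so that `(0, 100)` is a plain min-max rescale and the
#' operation is idempotent on its own output.
#'
#' @param img a [volume_image()] with at least two distinct intensities.
#' @param params a [contrast_params()].
#' @return A [volume_image()] with intensities in \[0, 1\], geometry
#'   unchanged.
#' @export
contrast_adjust <- function(img, params = contrast_params()) {
  validate_geometry(img)
  v <- as.numeric(img$voxels)
  rng <- range(v)
  if (rng[1] == rng[2])
    abort_cbctseg("constant image has no contrast to adjust",
                  "cbctseg_degenerate_contrast_error")

  bounds <- contrast_bounds(v, params)
  new_min <- bounds[1]; new_max <- bounds[2]
  if (!(new_max > new_min))
    abort_cbctseg("degenerate contrast window (new_min == new_max)",
                  "cbctseg_degenerate_contrast_error")
  out <- (pmin(pmax(v, new_min), new_max) - new_min) / (new_max - new_min)
  volume_image(array(out, dim(img$voxels)), img$spacing, img$origin,
               img$direction)
}

# New (min, max) intensities from the background-excluded cumulative curve.
contrast_bounds <- function(v, params) {
  uniq <- unique(v)
  if (length(uniq) <= params$n_bins) {
    tab <- table(v)
    vals <- as.numeric(names(tab))
    counts <- as.numeric(tab)
  } else {
    brk <- seq(min(v), max(v), length.out = params$n_bins + 1L)
    counts <- tabulate(findInterval(v, brk, rightmost.closed = TRUE,
                                    all.inside = TRUE), params$n_bins)
    vals <- brk[-1]                       # bin right edges
    keep <- counts > 0
    vals <- vals[keep]; counts <- counts[keep]
  }
  mode_i <- which.max(counts)             # background = modal intensity
  vals_fg <- vals[-mode_i]; counts_fg <- counts[-mode_i]
  if (length(vals_fg) == 0L)
    abort_cbctseg("image is background-only",
                  "cbctseg_degenerate_contrast_error")
  cum <- cumsum(counts_fg) / sum(counts_fg)
  new_min <- if (params$x_min_pct <= 0) min(v)
             else vals_fg[which(cum >= params$x_min_pct / 100)[1]]
  new_max <- if (params$x_max_pct >= 100) max(v)
             else vals_fg[which(cum >= params$x_max_pct / 100)[1]]
  c(new_min, new_max)
}

#' Canonicalize a ground-truth label map
#'
#' Collapses all nonzero labels to 1 and fills internal holes: background
#' regions with no 6-connected (face-adjacent) path to the grid border
#' become foreground. This canonical form — a solid binary mask — is what
#' the models train against, regardless of how a centre's manual
#' segmentation was labelled or whether structures were left hollow.
#'
#' @param label a [label_map()] with at least one nonzero voxel.
#' @return A binary [label_map()], same geometry.
#' @export
canonicalize_label <- function(label) {
  validate_geometry(label)
  fg <- label$voxels > 0
  if (!any(fg))
    abort_cbctseg("label map is empty (all zero)", "cbctseg_empty_label_error")
  filled <- fill_holes_mask(fg)
  label_map(array(as.numeric(filled), dim(label$voxels)), label$spacing,
            label$origin, label$direction, n_classes = 2L)
}

# Fill internal cavities of a logical mask: background components with no
# 6-connected path to the grid border become foreground.
fill_holes_mask <- function(fg) {
  d <- dim(fg)
  bg <- !fg
  if (!any(bg)) return(fg)
  comp <- connected_components_mask(bg, connectivity = 6L)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- unique(comp$membership[border[comp$voxel_ids]])
  cavity_ids <- comp$voxel_ids[!comp$membership %in% outside]
  out <- fg
  out[cavity_ids] <- TRUE
  out
}
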