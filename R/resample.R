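#' Resample a volume to a target voxel spacing
#'
#' Interpolates the volume onto a grid with the requested spacing (the
#' pipeline standard is 0.4 mm isotropic). The output grid size per axis is
#' `ceil(input_size * input_spacing / target_spacing)` so the physical
#' extent is never cropped; origin and direction are preserved. Images use
#' linear interpolation, label maps nearest-neighbour (`mode = "nearest"` is
#' mandatory for labels). Voxels that fall outside the input domain are
#' filled with the input minimum (images) or 0 (labels), mimicking the air
#' background.
#'
#' @param img a [volume_image()] or [label_map()].
#' @param target_spacing numeric length-3 (or scalar, recycled), mm; all > 0.
#' @param mode `"linear"` or `"nearest"`.
#' @return Same type as `img`, on the new grid.
#' @export
resample_to_spacing <- function(img, target_spacing,
                                mode = if (inherits(img, "label_map"))
                                  "nearest" else "linear") {
  validate_geometry(img)
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    abort_cbctseg("target_spacing must be positive per axis",
                  "cbctseg_geometry_error")
  mode <- match.arg(mode, c("linear", "nearest"))
  if (inherits(img, "label_map") && mode != "nearest")
    abort_cbctseg("label maps must be resampled with mode = \"nearest\"",
                  "cbctseg_contract_error")
  in_size <- dim(img$voxels)
  out_size <- as.integer(ceiling(in_size * img$spacing / target_spacing -
                                   1e-9))
  out_size <- pmax(out_size, 1L)
  out_geom <- list(size = out_size, spacing = target_spacing,
                   origin = img$origin, direction = img$direction)
  resample_onto(img, out_geom, mode)
}

#' Resample a label map onto a reference geometry
#'
#' Maps a label map onto the exact grid (size, spacing, origin, direction)
#' of a reference volume using nearest-neighbour interpolation — the final
#' pipeline step that returns a segmentation computed on the working grid to
#' the original scan geometry. The output label value set is a subset of the
#' input's.
#'
#' @param label a [label_map()].
#' @param reference a [volume_image()], [label_map()], or a geometry list
#'   with fields `size`, `spacing`, `origin`, `direction`.
#' @return A [label_map()] with geometry identical to `reference`.
#' @export
resample_to_reference <- function(label, reference) {
  validate_geometry(label)
  geom <- if (inherits(reference, "volume_image")) geometry_of(reference)
          else reference
  if (any(!is.finite(geom$spacing)) || any(geom$spacing <= 0) ||
      any(geom$size < 1))
    abort_cbctseg("reference geometry is degenerate",
                  "cbctseg_geometry_error")
  if (!inherits(label, "label_map"))
    label <- label_map(label$voxels, label$spacing, label$origin,
                       label$direction,
                       n_classes = max(2, max(label$voxels) + 1))
  resample_onto(label, geom, "nearest")
}

# Shared physical-space resampler. Builds the world position of every output
# voxel, converts to continuous input indices, and interpolates.
resample_onto <- function(img, out_geom, mode) {
  in_size <- dim(img$voxels)
  out_size <- as.integer(out_geom$size)
  fill <- if (inherits(img, "label_map")) 0 else min(img$voxels)

  idx <- cbind(
    rep.int(seq_len(out_size[1]) - 1L, out_size[2] * out_size[3]),
    rep.int(rep(seq_len(out_size[2]) - 1L, each = out_size[1]), out_size[3]),
    rep(seq_len(out_size[3]) - 1L, each = out_size[1] * out_size[2]))
  world <- index_to_world(out_geom, idx)
  cont <- world_to_index(geometry_of(img), world)

  vals <- if (mode == "nearest") {
    interp_nearest(img$voxels, cont, fill)
  } else {
    interp_trilinear(img$voxels, cont, fill)
  }
  arr <- array(vals, out_size)
  if (inherits(img, "label_map"))
    label_map(arr, out_geom$spacing, out_geom$origin, out_geom$direction,
              n_classes = img$n_classes)
  else
    volume_image(arr, out_geom$spacing, out_geom$origin, out_geom$direction)
}

interp_nearest <- function(vox, cont, fill) {
  d <- dim(vox)
  i <- round(cont)
  inside <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
            i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
            i[, 3] >= 0 & i[, 3] <= d[3] - 1
  out <- rep(fill, nrow(cont))
  if (any(inside)) {
    lin <- 1 + i[inside, 1] + d[1] * (i[inside, 2] + d[2] * i[inside, 3])
    out[inside] <- vox[lin]
  }
  out
}

interp_trilinear <- function(vox, cont, fill) {
  d <- dim(vox)
  inside <- cont[, 1] >= -0.5 & cont[, 1] <= d[1] - 0.5 &
            cont[, 2] >= -0.5 & cont[, 2] <= d[2] - 0.5 &
            cont[, 3] >= -0.5 & cont[, 3] <= d[3] - 0.5
  out <- rep(fill, nrow(cont))
  if (!any(inside)) return(out)
  p <- cont[inside, , drop = FALSE]
  f0 <- floor(p)
  w <- p - f0
  acc <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- pmin(pmax(f0[, 1] + cx, 0), d[1] - 1)
    iy <- pmin(pmax(f0[, 2] + cy, 0), d[2] - 1)
    iz <- pmin(pmax(f0[, 3] + cz, 0), d[3] - 1)
    wt <- (if (cx == 1) w[, 1] else 1 - w[, 1]) *
          (if (cy == 1) w[, 2] else 1 - w[, 2]) *
          (if (cz == 1) w[, 3] else 1 - w[, 3])
    acc <- acc + wt * vox[1 + ix + d[1] * (iy + d[2] * iz)]
  }
  out[inside] <- acc
  out
}
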