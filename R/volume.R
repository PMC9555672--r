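#' Construct a geometry-aware 3D volume
#'
#' A `volume_image` couples a 3D voxel grid with its physical geometry:
#' per-axis spacing in millimetres, the world position of the centre of
#' voxel (0,0,0), and a 3x3 orthonormal direction matrix whose columns give
#' the world direction of each voxel axis. World coordinates follow the LPS
#' (left-posterior-superior) convention of the ITK/DICOM ecosystem; voxel
#' indices are 0-based in all index/world conversions.
#'
#' @param voxels numeric 3D array of scalar intensities (arbitrary scanner
#'   units).
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm; world position of the first voxel
#'   centre.
#' @param direction 3x3 orthonormal matrix (columns are axis directions).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  obj <- structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         direction = matrix(as.numeric(direction), 3, 3)),
    class = "volume_image")
  validate_geometry(obj)
  obj
}

#' Construct an integer label map sharing volume geometry
#'
#' A `label_map` is a `volume_image` whose voxels are nonnegative integer
#' class labels (0 = background). With a declared class count `n_classes`,
#' values must lie in `{0, ..., n_classes - 1}`.
#'
#' @inheritParams volume_image
#' @param n_classes declared number of classes (default 2: background and
#'   one structure).
#' @return An object of class `c("label_map", "volume_image")`.
#' @export
label_map <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3), n_classes = 2L) {
  v <- as.numeric(voxels)
  if (any(v < 0) || any(v != round(v)))
    abort_cbctseg("label_map voxels must be nonnegative integers",
                  "cbctseg_label_error")
  if (any(v > n_classes - 1))
    abort_cbctseg(sprintf("label values exceed declared class count %d",
                          n_classes), "cbctseg_label_error")
  obj <- structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin),
         direction = matrix(as.numeric(direction), 3, 3),
         n_classes = as.integer(n_classes)),
    class = c("label_map", "volume_image"))
  validate_geometry(obj)
  obj
}

#' @export
print.volume_image <- function(x, ...) {
  kind <- if (inherits(x, "label_map")) "label_map" else "volume_image"
  cat(sprintf("<%s> %s voxels, spacing (%s) mm\n", kind,
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", ")))
  cat(sprintf("  origin (%s) mm, direction %s\n",
              paste(signif(x$origin, 4), collapse = ", "),
              if (isTRUE(all.equal(x$direction, diag(3)))) "identity"
              else "non-identity"))
  invisible(x)
}

# Shared geometry invariants: positive spacing, orthonormal direction,
# non-degenerate 3D grid.
validate_geometry <- function(img) {
  d <- dim(img$voxels)
  if (is.null(d) || length(d) != 3L)
    abort_cbctseg("volume payload must be a 3D array",
                  "cbctseg_dimension_error")
  if (any(d < 1L))
    abort_cbctseg("volume must have at least one voxel per axis",
                  "cbctseg_geometry_error")
  if (length(img$spacing) != 3L || any(!is.finite(img$spacing)) ||
      any(img$spacing <= 0))
    abort_cbctseg("spacing must be three positive finite values",
                  "cbctseg_geometry_error")
  if (length(img$origin) != 3L || any(!is.finite(img$origin)))
    abort_cbctseg("origin must be three finite values",
                  "cbctseg_geometry_error")
  D <- img$direction
  if (!is.matrix(D) || any(dim(D) != c(3L, 3L)) ||
      max(abs(crossprod(D) - diag(3))) > 1e-6)
    abort_cbctseg("direction must be a 3x3 orthonormal matrix",
                  "cbctseg_geometry_error")
  invisible(img)
}

# Same voxel grid + geometry within tolerance.
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

# Extract just the geometry fields (for resample_to_reference and friends).
geometry_of <- function(img) {
  list(size = dim(img$voxels), spacing = img$spacing, origin = img$origin,
       direction = img$direction)
}

# World position of 0-based voxel indices (n x 3 matrix) under LPS.
index_to_world <- function(geom, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(idx %*% (t(geom$direction) * geom$spacing), 2, geom$origin, `+`)
}

# Continuous 0-based voxel index of world points (n x 3 matrix).
world_to_index <- function(geom, pts) {
  pts <- sweep(matrix(pts, ncol = 3), 2, geom$origin, `-`)
  (pts %*% geom$direction) / rep(geom$spacing, each = nrow(pts))
}

# Classed error helper used across the package.
abort_cbctseg <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cbctseg_error")))
}
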