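#' Synthetic CBCT-like phantom specification
#'
#' Parameters of the procedural skull-like phantom generator. A phantom is
#' an ellipsoidal bright shell ("cortical bone") with an optional internal
#' cavity (air/soft-tissue interior, for fill-hole testing) and optional
#' small disconnected satellite blobs (imaging artifacts, for
#' largest-component testing), on a dominant near-constant air background,
#' with additive Gaussian noise and a per-phantom gamma emulating
#' centre-to-centre contrast variation. Anisotropic voxel spacing is drawn
#' from `spacing_range` (default 0.16-0.5 mm, the scanner range the
#' pipeline must absorb). The ground truth is the *solid* (cavity-filled)
#' shell without satellites; at the defaults it occupies roughly 3-11% of
#' the volume, matching the class imbalance of real bone masks.
#'
#' @param grid_size voxels per axis (scalar, >= 16).
#' @param spacing_range mm interval the per-axis spacings are drawn from.
#' @param shell_thickness shell wall thickness, voxels.
#' @param cavity carve an internal cavity (fill-hole test case).
#' @param n_satellites number of disconnected bright blobs excluded from
#'   the ground truth.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; bone is 1.0).
#' @param intensity_gamma_range interval for the per-phantom gamma.
#' @param background_level air background intensity.
#' @param intensity_offset additive intensity offset (used for per-centre
#'   contrast differences).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_size = 64L, spacing_range = c(0.16, 0.5),
                         shell_thickness = 3, cavity = TRUE,
                         n_satellites = 2L, noise_sd = 0.05,
                         intensity_gamma_range = c(0.85, 1.2),
                         background_level = 0.02, intensity_offset = 0,
                         seed = 1L) {
  if (grid_size < 16L)
    abort_cbctseg("grid_size must be >= 16", "cbctseg_spec_error")
  if (any(spacing_range <= 0) || any(spacing_range > 1) ||
      spacing_range[1] > spacing_range[2])
    abort_cbctseg("spacing_range must lie within (0, 1] mm",
                  "cbctseg_spec_error")
  if (noise_sd < 0)
    abort_cbctseg("noise_sd must be nonnegative", "cbctseg_spec_error")
  structure(list(grid_size = as.integer(grid_size),
                 spacing_range = as.numeric(spacing_range),
                 shell_thickness = shell_thickness, cavity = isTRUE(cavity),
                 n_satellites = as.integer(n_satellites),
                 noise_sd = noise_sd,
                 intensity_gamma_range = as.numeric(intensity_gamma_range),
                 background_level = background_level,
                 intensity_offset = intensity_offset,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom scan with its ground truth
#'
#' @param spec a [phantom_spec()].
#' @return List with `image` (a [volume_image()]) and `label` (the solid
#'   ground-truth [label_map()], same geometry).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  n <- spec$grid_size
  with_seed(spec$seed, {
    spacing <- stats::runif(3, spec$spacing_range[1], spec$spacing_range[2])
    origin <- stats::runif(3, -10, 10)
    semi <- stats::runif(3, 0.22, 0.30) * n
    if (2 * max(semi) > n - 2)
      abort_cbctseg("shell does not fit in the grid", "cbctseg_spec_error")
    centre <- n / 2 + stats::runif(3, -0.04, 0.04) * n

    ax <- (seq_len(n) - centre[1]) / semi[1]
    ay <- (seq_len(n) - centre[2]) / semi[2]
    az <- (seq_len(n) - centre[3]) / semi[3]
    r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
    r <- sqrt(r2)
    solid <- r <= 1
    t_rel <- spec$shell_thickness / mean(semi)
    bone <- if (spec$cavity) solid & (r > 1 - t_rel) else solid

    img <- array(spec$background_level, c(n, n, n))
    if (spec$cavity) img[solid & !bone] <- 0.2     # soft-tissue interior
    img[bone] <- 1.0

    if (spec$n_satellites > 0L) {
      placed <- 0L
      guard <- 0L
      while (placed < spec$n_satellites && guard < 1000L) {
        guard <- guard + 1L
        rad <- stats::runif(1, 2, 4)
        pos <- stats::runif(3, rad + 1, n - rad - 1)
        rr <- sqrt(sum(((pos - centre) / semi)^2))
        if (rr < 1.25) next                        # keep off the shell
        placed <- placed + 1L
        xs <- pmax(1, floor(pos[1] - rad)):pmin(n, ceiling(pos[1] + rad))
        ys <- pmax(1, floor(pos[2] - rad)):pmin(n, ceiling(pos[2] + rad))
        zs <- pmax(1, floor(pos[3] - rad)):pmin(n, ceiling(pos[3] + rad))
        sub <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
        hit <- sub[rowSums(sweep(sub, 2, pos)^2) <= rad^2, , drop = FALSE]
        img[hit] <- 1.0
      }
    }

    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    gma <- stats::runif(1, spec$intensity_gamma_range[1],
                        spec$intensity_gamma_range[2])
    img <- pmax(img, 0)^gma + spec$intensity_offset

    list(image = volume_image(img, spacing, origin),
         label = label_map(array(as.numeric(solid), c(n, n, n)),
                           spacing, origin))
  })
}

#' Generate a multi-centre phantom dataset on disk
#'
#' Emulates a dataset pooled from several clinical centres: one folder per
#' pseudo-centre, each with a centre-specific additive intensity offset on
#' top of the per-phantom contrast variation, paired image/label NIfTI
#' files, and a manifest listing every pair.
#'
#' @param n_per_center phantoms per centre (>= 1).
#' @param n_centers number of pseudo-centres (>= 1).
#' @param spec base [phantom_spec()]; per-phantom seeds and per-centre
#'   offsets are derived from it and `seed`.
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param center_offset_step additive intensity offset between consecutive
#'   centres.
#' @return Data frame manifest (`center`, `image`, `label`), invisibly;
#'   also written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_per_center, n_centers, spec = phantom_spec(),
                             out_dir, seed = 1L, center_offset_step = 0.08) {
  if (n_per_center < 1L || n_centers < 1L)
    abort_cbctseg("counts must be >= 1", "cbctseg_spec_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    abort_cbctseg(sprintf("cannot create output directory '%s'", out_dir),
                  "cbctseg_io_error")
  rows <- list()
  for (ci in seq_len(n_centers)) {
    cdir <- file.path(out_dir, sprintf("center_%02d", ci))
    dir.create(cdir, showWarnings = FALSE)
    for (k in seq_len(n_per_center)) {
      pspec <- spec
      pspec$seed <- derive_seed(seed, sprintf("c%dp%d", ci, k))
      pspec$intensity_offset <- spec$intensity_offset +
        (ci - 1) * center_offset_step
      ph <- generate_phantom(pspec)
      ipath <- file.path(cdir, sprintf("image_%03d.nii.gz", k))
      lpath <- file.path(cdir, sprintf("label_%03d.nii.gz", k))
      write_volume(ph$image, ipath)
      write_volume(ph$label, lpath)
      rows[[length(rows) + 1L]] <- data.frame(
        center = sprintf("center_%02d", ci), image = ipath, label = lpath,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
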