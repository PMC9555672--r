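#' Read a 3D volume with its physical geometry
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`), NRRD (`.nrrd`) or a DICOM series
#' directory into a [volume_image()]. Geometry (spacing, origin, direction)
#' is taken from the standard header fields and expressed in LPS world
#' coordinates; NIfTI xforms (RAS) are converted on the fly. Intensities are
#' returned unmodified.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.nrrd`) or a directory
#'   containing a single-series uncompressed DICOM stack.
#' @param as_label read as a [label_map()] (integer values) instead of a
#'   `volume_image`.
#' @param n_classes declared class count when `as_label = TRUE`; defaults to
#'   `max(value) + 1`.
#' @return A [volume_image()] or [label_map()].
#' @export
read_volume <- function(path, as_label = FALSE, n_classes = NULL) {
  if (dir.exists(path)) {
    vol <- read_dicom_series(path)
  } else {
    if (!file.exists(path))
      abort_cbctseg(sprintf("cannot read volume: '%s' does not exist", path),
                    "cbctseg_format_error")
    ext <- volume_format(path)
    vol <- switch(ext,
      nifti = read_nifti_volume(path),
      nrrd  = read_nrrd_volume(path),
      abort_cbctseg(sprintf("unsupported volume format for '%s'", path),
                    "cbctseg_format_error"))
  }
  if (as_label) {
    v <- round(vol$voxels)
    nc <- if (is.null(n_classes)) as.integer(max(v) + 1) else n_classes
    vol <- label_map(v, vol$spacing, vol$origin, vol$direction,
                     n_classes = max(nc, 2L))
  }
  vol
}

#' Write a volume or label map
#'
#' Writes NIfTI-1 or NRRD depending on the file extension. Voxels survive a
#' round-trip bit-exactly and geometry within 1e-6.
#'
#' @param img a [volume_image()] or [label_map()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  validate_geometry(img)
  if (!dir.exists(dirname(path)))
    abort_cbctseg(sprintf("parent directory of '%s' does not exist", path),
                  "cbctseg_format_error")
  switch(volume_format(path),
    nifti = write_nifti_volume(img, path),
    nrrd  = write_nrrd_volume(img, path),
    abort_cbctseg(sprintf("unsupported output extension for '%s'", path),
                  "cbctseg_format_error"))
  invisible(path)
}

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.nrrd$", low)) return("nrrd")
  "unknown"
}

# ---- NIfTI ------------------------------------------------------------------

# NIfTI stores xforms in RAS; flip L and P axes to express them in LPS.
ras_to_lps <- diag(c(-1, -1, 1))

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))    # drop niftiImage attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    abort_cbctseg(sprintf("'%s' is not a 3D volume (found %dD payload)",
                          path, length(dim(arr))), "cbctseg_dimension_error")
  x <- RNifti::xform(img, useQuaternionFirst = FALSE)  # 4x4 RAS affine
  M <- ras_to_lps %*% x[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0))
    abort_cbctseg(sprintf("degenerate spacing in '%s'", path),
                  "cbctseg_geometry_error")
  direction <- sweep(M, 2, spacing, `/`)
  origin <- as.numeric(ras_to_lps %*% x[1:3, 4])
  volume_image(arr, spacing, origin, direction)
}

write_nifti_volume <- function(img, path) {
  M <- ras_to_lps %*% sweep(img$direction, 2, img$spacing, `*`)
  aff <- diag(4)
  aff[1:3, 1:3] <- M
  aff[1:3, 4] <- as.numeric(ras_to_lps %*% img$origin)
  nif <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(nif) <- img$spacing
  RNifti::sform(nif) <- structure(aff, code = 2L)
  RNifti::writeNifti(nif, path)
}

# ---- NRRD -------------------------------------------------------------------
# Minimal NRRD0004 support: 3D scalar volumes, raw or gzip encoding, little
# endian, with `space directions` / `space origin` geometry in LPS.

read_nrrd_volume <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # Header is text terminated by a blank line; payload is binary after it.
  nl <- which(bytes == as.raw(10L))
  split_at <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L ||
        (p == prev + 2L && bytes[prev + 1L] == as.raw(13L))) {
      split_at <- p
      break
    }
    prev <- p
  }
  if (is.na(split_at))
    abort_cbctseg(sprintf("truncated NRRD header in '%s'", path),
                  "cbctseg_format_error")
  header <- strsplit(rawToChar(bytes[seq_len(split_at)]), "\r?\n")[[1]]
  if (!grepl("^NRRD000[0-9]$", header[1]))
    abort_cbctseg(sprintf("'%s' is not an NRRD file", path),
                  "cbctseg_format_error")
  fields <- list()
  for (line in header[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- strsplit(line, ": ?", fixed = FALSE)[[1]]
    fields[[tolower(kv[1])]] <- paste(kv[-1], collapse = ": ")
  }
  dimension <- as.integer(fields[["dimension"]])
  if (!identical(dimension, 3L))
    abort_cbctseg(sprintf("'%s' is %dD; only 3D volumes are supported",
                          path, dimension), "cbctseg_dimension_error")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- fields[["type"]]
  encoding <- fields[["encoding"]]
  n <- prod(sizes)
  payload <- bytes[(split_at + 1L):length(bytes)]
  if (identical(encoding, "gzip") || identical(encoding, "gz"))
    payload <- memDecompress(payload, type = "gzip")
  else if (!identical(encoding, "raw"))
    abort_cbctseg(sprintf("unsupported NRRD encoding '%s'", encoding),
                  "cbctseg_format_error")
  vals <- decode_nrrd_type(payload, type, n, path)
  arr <- array(vals, sizes)

  spacing <- c(1, 1, 1); origin <- c(0, 0, 0); direction <- diag(3)
  if (!is.null(fields[["space directions"]])) {
    cols <- parse_nrrd_vectors(fields[["space directions"]])
    M <- do.call(cbind, cols)
    spacing <- sqrt(colSums(M^2))
    direction <- sweep(M, 2, spacing, `/`)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  sp <- fields[["space"]]
  if (!is.null(sp) && grepl("right-anterior-superior", sp)) {
    direction <- ras_to_lps %*% direction
    origin <- as.numeric(ras_to_lps %*% origin)
  }
  volume_image(arr, spacing, origin, direction)
}

decode_nrrd_type <- function(payload, type, n, path) {
  switch(type,
    "double" = readBin(payload, "double", n = n, size = 8, endian = "little"),
    "float"  = readBin(payload, "double", n = n, size = 4, endian = "little"),
    "int" = , "int32" = , "signed int" =
      readBin(payload, "integer", n = n, size = 4, endian = "little"),
    "short" = , "int16" = , "signed short" =
      readBin(payload, "integer", n = n, size = 2, signed = TRUE,
              endian = "little"),
    "ushort" = , "uint16" = , "unsigned short" =
      readBin(payload, "integer", n = n, size = 2, signed = FALSE,
              endian = "little"),
    "uchar" = , "uint8" = , "unsigned char" =
      as.integer(payload[seq_len(n)]),
    abort_cbctseg(sprintf("unsupported NRRD type '%s' in '%s'", type, path),
                  "cbctseg_format_error"))
}

parse_nrrd_vectors <- function(txt) {
  m <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]]
  lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

write_nrrd_volume <- function(img, path) {
  M <- sweep(img$direction, 2, img$spacing, `*`)
  dirs <- paste(vapply(1:3, function(j)
    sprintf("(%.17g,%.17g,%.17g)", M[1, j], M[2, j], M[3, j]), ""),
    collapse = " ")
  header <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(dim(img$voxels), collapse = " ")),
    sprintf("space directions: %s", dirs),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            img$origin[1], img$origin[2], img$origin[3]),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  raw_data <- writeBin(as.numeric(img$voxels), raw(), size = 8,
                       endian = "little")
  writeBin(memCompress(raw_data, type = "gzip"), con)
}

# ---- DICOM series -----------------------------------------------------------
# Read-only support for the common CBCT export: one uncompressed
# single-frame image per file, little-endian transfer syntax (explicit or
# implicit VR). Slices are sorted along the slice normal; geometry follows
# the DICOM LPS convention directly.

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    s <- tryCatch(read_dicom_file(f), error = function(e) NULL)
    if (!is.null(s)) slices[[length(slices) + 1L]] <- s
  }
  if (length(slices) == 0L)
    abort_cbctseg(sprintf("no readable DICOM slices in '%s'", dir),
                  "cbctseg_format_error")
  iop <- slices[[1]]$orientation
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  pos <- vapply(slices, function(s) sum(s$position * normal), 0)
  ord <- order(pos)
  slices <- slices[ord]; pos <- pos[ord]
  nz <- length(slices)
  zsp <- if (nz > 1) mean(diff(pos)) else slices[[1]]$pixel_spacing[1]
  if (nz > 1 && (zsp <= 0 || max(abs(diff(pos) - zsp)) > 0.25 * abs(zsp)))
    abort_cbctseg(sprintf("inconsistent slice positions in '%s'", dir),
                  "cbctseg_geometry_error")
  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows
  arr <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    if (s$cols != nx || s$rows != ny)
      abort_cbctseg(sprintf("mixed slice sizes in '%s'", dir),
                    "cbctseg_format_error")
    # DICOM pixel data is row-major (row = y); transpose to x-fastest.
    arr[, , k] <- t(matrix(s$pixels, nrow = ny, ncol = nx, byrow = TRUE)) *
      s$slope + s$intercept
  }
  spacing <- c(slices[[1]]$pixel_spacing[2], slices[[1]]$pixel_spacing[1],
               abs(zsp))
  direction <- cbind(iop[1:3], iop[4:6], normal * sign(zsp))
  volume_image(arr, spacing, slices[[1]]$position, direction)
}

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

read_dicom_file <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 132)
  if (length(pre) < 132 || rawToChar(pre[129:132]) != "DICM")
    stop("not DICOM")
  explicit <- TRUE
  tags <- new.env(parent = emptyenv())
  repeat {
    hdr <- readBin(con, "raw", 8)
    if (length(hdr) < 8) break
    group <- readBin(hdr[1:2], "integer", size = 2, signed = FALSE,
                     endian = "little")
    element <- readBin(hdr[3:4], "integer", size = 2, signed = FALSE,
                       endian = "little")
    in_meta <- group == 2L
    if (explicit || in_meta) {
      vr <- rawToChar(hdr[5:6])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- readBin(readBin(con, "raw", 4), "integer", size = 4,
                       endian = "little")
      } else if (grepl("^[A-Z]{2}$", vr)) {
        len <- readBin(hdr[7:8], "integer", size = 2, signed = FALSE,
                       endian = "little")
      } else {            # implicit VR dataset after explicit meta group
        explicit <- FALSE
        len <- readBin(hdr[5:8], "integer", size = 4, endian = "little")
        vr <- ""
      }
    } else {
      len <- readBin(hdr[5:8], "integer", size = 4, endian = "little")
      vr <- ""
    }
    if (len < 0 || len > sz) stop("bad element length")
    val <- readBin(con, "raw", len)
    key <- dcm_tag(group, element)
    tags[[key]] <- list(vr = vr, bytes = val)
    if (key == dcm_tag(0x0002, 0x0010)) {
      ts <- trimws(rawToChar(val[val != as.raw(0)]))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (!ts %in% c("1.2.840.10008.1.2.1")) stop("unsupported syntax")
    }
    if (key == dcm_tag(0x7FE0, 0x0010)) break
  }
  g <- function(grp, el) tags[[dcm_tag(grp, el)]]
  num <- function(grp, el, default = NULL) {
    t <- g(grp, el)
    if (is.null(t)) return(default)
    as.numeric(strsplit(trimws(rawToChar(t$bytes)), "\\\\")[[1]])
  }
  us <- function(grp, el) {
    t <- g(grp, el)
    if (is.null(t)) stop("missing tag")
    readBin(t$bytes, "integer", size = 2, signed = FALSE, endian = "little")
  }
  rows <- us(0x0028, 0x0010); cols <- us(0x0028, 0x0011)
  bits <- us(0x0028, 0x0100)
  signed <- isTRUE(num(0x0028, 0x0103, 0) == 1)
  pix <- g(0x7FE0, 0x0010)
  if (is.null(pix)) stop("no pixel data")
  pixels <- if (bits == 16)
    readBin(pix$bytes, "integer", n = rows * cols, size = 2,
            signed = signed, endian = "little")
  else as.integer(pix$bytes[seq_len(rows * cols)])
  list(rows = rows, cols = cols, pixels = pixels,
       pixel_spacing = num(0x0028, 0x0030, c(1, 1)),
       position = num(0x0020, 0x0032, c(0, 0, 0)),
       orientation = num(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
       slope = num(0x0028, 0x1053, 1), intercept = num(0x0028, 0x1052, 0))
}
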