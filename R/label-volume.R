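#' Construct a LabelVolume
#'
#' @param voxels 3D array coercible to binary 0/1.
#' @param spacing numeric(3), voxel size in mm along the array axes.
#' @param origin numeric(3), anatomical position (mm) of the centre of voxel
#'   `[1, 1, 1]`.
#' @param orientation 3 x 3 direction matrix (columns = anatomical unit
#'   vectors of the array axes); identity means array axes already follow
#'   the LR/AP/CC anatomical axes.
#' @return a \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        orientation = diag(3)) {
  voxels <- array(as.integer(voxels != 0), dim = dim(voxels))
  new("LabelVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelVolume: %d x %d x %d voxels, spacing [%g, %g, %g] mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  labeled voxels: %d (%.3f cm^3)\n", sum(object@voxels),
              voxelCountVolume(object)))
})

#' Labeled-voxel volume
#'
#' Number of labeled voxels times the voxel volume, in cm^3. Serves as the
#' voxel-counting oracle against which iso-surface volumes are checked.
#'
#' @param vol a \linkS4class{LabelVolume}.
#' @return volume in cm^3.
#' @export
voxelCountVolume <- function(vol) {
  stopifnot(is(vol, "LabelVolume"))
  sum(vol@voxels) * prod(vol@spacing) / 1000
}

.binarizeLabels <- function(arr, path) {
  vals <- sort(unique(as.vector(arr)))
  if (length(vals) > 2)
    stop("label volume is multi-label, expected binary; labels found: ",
         paste(signif(vals, 6), collapse = ", "), " (", path, ")")
  array(as.integer(arr > 0.5), dim = dim(arr))
}

#' Load a binary segmentation from NIfTI or NRRD
#'
#' Values are binarized (> 0.5 -> 1); a volume with more than two distinct
#' labels is refused with the label list. Orientation metadata (NIfTI
#' qform/sform, NRRD `space`/`space directions`) is converted into the
#' package's anatomical frame (left/posterior/cranial positive), so identical
#' masks stored in either format load to identical objects.
#'
#' @param path file path (`.nii`, `.nii.gz`, `.nrrd`).
#' @param fmt `"auto"` (by extension), `"nifti"` or `"nrrd"`.
#' @return a \linkS4class{LabelVolume}.
#' @export
loadLabelVolume <- function(path, fmt = c("auto", "nifti", "nrrd")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "auto")
    fmt <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  if (fmt == "nifti") .loadNifti(path) else .loadNrrd(path)
}

.loadNifti <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0 && hdr$sform_code == 0)
    stop("NIfTI file has no orientation metadata (qform and sform unset): ",
         path)
  aff <- RNifti::xform(img) # voxel (0-based) -> RAS mm
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop("expected a 3D volume: ", path)
  # RAS -> anatomical frame (left/posterior/cranial positive): negate x, y
  aff[1:2, ] <- -aff[1:2, ]
  A <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  D <- sweep(A, 2, spacing, "/")
  origin <- as.numeric(aff[1:3, 4])
  LabelVolume(.binarizeLabels(arr, path), spacing, origin, D)
}

#' Write a binary segmentation to NIfTI or NRRD
#'
#' @param vol a \linkS4class{LabelVolume}.
#' @param path output path (`.nii`, `.nii.gz`, `.nrrd`).
#' @param fmt `"auto"` (by extension), `"nifti"` or `"nrrd"`.
#' @return `path`, invisibly.
#' @export
saveLabelVolume <- function(vol, path, fmt = c("auto", "nifti", "nrrd")) {
  stopifnot(is(vol, "LabelVolume"))
  fmt <- match.arg(fmt)
  if (fmt == "auto")
    fmt <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd" else "nifti"
  if (fmt == "nifti") .saveNifti(vol, path) else .saveNrrd(vol, path)
  invisible(path)
}

.saveNifti <- function(vol, path) {
  aff <- rbind(cbind(sweep(vol@orientation, 2, vol@spacing, "*"),
                     vol@origin),
               c(0, 0, 0, 1))
  aff[1:2, ] <- -aff[1:2, ] # anatomical (LPS-like) -> RAS
  img <- RNifti::asNifti(array(as.double(vol@voxels), dim = dim(vol@voxels)))
  img <- RNifti::`pixdim<-`(img, vol@spacing)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
}

# --- NRRD ------------------------------------------------------------------
# Minimal NRRD0004 codec: attached data, encodings raw / gzip / ascii,
# space either LPS (native for this package) or RAS.

.loadNrrd <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  nl <- which(bytes == as.raw(10))
  # header ends at the first blank line
  blank <- NULL
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { blank <- p; break }
    prev <- p
  }
  if (is.null(blank)) stop("malformed NRRD (no blank line after header): ",
                           path)
  header <- strsplit(rawToChar(bytes[1:blank]), "\n")[[1]]
  payload <- bytes[seq.int(blank + 1L, length(bytes))]
  if (!grepl("^NRRD", header[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (ln in header[-1]) {
    if (ln == "" || grepl("^#", ln)) next
    kv <- regmatches(ln, regexpr(":=?", ln), invert = TRUE)[[1]]
    if (length(kv) == 2)
      fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  need <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss)) stop("NRRD header missing fields: ",
                         paste(miss, collapse = ", "))
  if (as.integer(fields$dimension) != 3)
    stop("expected a 3D NRRD volume: ", path)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (!is.null(fields[["data file"]]) || !is.null(fields$datafile))
    stop("detached NRRD data files are not supported")

  typ <- fields$type
  rdr <- switch(typ,
    "uint8" = , "uchar" = , "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
    "int8" = , "signed char" = list(what = "integer", size = 1, signed = TRUE),
    "uint16" = , "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
    "int16" = , "short" = list(what = "integer", size = 2, signed = TRUE),
    "int32" = , "int" = list(what = "integer", size = 4, signed = TRUE),
    "uint32" = , "unsigned int" = list(what = "integer", size = 4, signed = TRUE),
    "float" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = list(what = "numeric", size = 8, signed = TRUE),
    stop("unsupported NRRD type: ", typ))
  endian <- if (!is.null(fields$endian)) fields$endian else "little"
  n <- prod(sizes)
  enc <- fields$encoding
  vals <- if (enc %in% c("raw")) {
    readBin(payload, rdr$what, n, size = rdr$size, signed = rdr$signed,
            endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    readBin(memDecompress(payload, "gzip"), rdr$what, n, size = rdr$size,
            signed = rdr$signed, endian = endian)
  } else if (enc %in% c("ascii", "txt", "text")) {
    as.numeric(strsplit(trimws(rawToChar(payload)), "\\s+")[[1]])
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) < n) stop("truncated NRRD payload: ", path)
  arr <- array(vals[seq_len(n)], dim = sizes)

  space <- if (!is.null(fields$space)) fields$space else
    stop("NRRD file has no 'space' orientation field: ", path)
  flip <- if (space %in% c("left-posterior-superior", "LPS")) c(1, 1, 1)
          else if (space %in% c("right-anterior-superior", "RAS")) c(-1, -1, 1)
          else stop("unsupported NRRD space: ", space)
  if (is.null(fields[["space directions"]]))
    stop("NRRD file has no 'space directions' field: ", path)
  dirs <- .parseNrrdVectors(fields[["space directions"]])
  if (length(dirs) != 3) stop("need 3 space direction vectors")
  A <- do.call(cbind, dirs) * flip
  spacing <- sqrt(colSums(A^2))
  D <- sweep(A, 2, spacing, "/")
  origin <- if (!is.null(fields[["space origin"]]))
    .parseNrrdVectors(fields[["space origin"]])[[1]] * flip else c(0, 0, 0)
  LabelVolume(.binarizeLabels(arr, path), spacing, origin, D)
}

.parseNrrdVectors <- function(txt) {
  m <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]]
  lapply(m, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

.saveNrrd <- function(vol, path) {
  A <- sweep(vol@orientation, 2, vol@spacing, "*")
  vec <- function(v) sprintf("(%.9g,%.9g,%.9g)", v[1], v[2], v[3])
  d <- dim(vol@voxels)
  header <- c(
    "NRRD0004",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "space: left-posterior-superior",
    sprintf("space directions: %s %s %s", vec(A[, 1]), vec(A[, 2]),
            vec(A[, 3])),
    sprintf("space origin: %s", vec(vol@origin)),
    "kinds: domain domain domain",
    "encoding: gzip",
    "endian: little",
    "", "")
  payload <- memCompress(as.raw(as.vector(vol@voxels)), "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste(header, collapse = "\n")), con)
  writeBin(payload, con)
}

# --- iso-surfacing ---------------------------------------------------------

.gaussSmooth <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(v) c(rep(0, r), v, rep(0, r))
  sm1 <- function(v) {
    out <- stats::filter(pad(v), k, sides = 2)
    as.numeric(out[(r + 1):(r + length(v))])
  }
  for (ax in 1:3) {
    p <- c(ax, setdiff(1:3, ax))
    a2 <- aperm(arr, p)
    a2 <- array(apply(a2, c(2, 3), sm1), dim(a2))
    arr <- aperm(a2, order(p))
  }
  arr
}

#' Iso-surface a binary MRI segmentation into a mesh
#'
#' Extracts the 0.5-level surface of the (optionally Gaussian-smoothed)
#' binary field by marching tetrahedra over the voxel-center grid, scales by
#' the anisotropic voxel spacing and places the result in the anatomical
#' frame using the volume's origin and orientation. Disconnected components
#' are preserved and the output is watertight.
#'
#' @param vol a \linkS4class{LabelVolume} with at least one labeled voxel.
#' @param iso iso level on the binary field (default 0.5).
#' @param smoothSigma Gaussian pre-smoothing in voxel units (default 0 =
#'   off; reproducibility is preferred over cosmetics).
#' @param name label for the output mesh.
#' @return a watertight \linkS4class{TriangleMesh}.
#' @export
maskToMesh <- function(vol, iso = 0.5, smoothSigma = 0, name = "tumor_mri") {
  stopifnot(is(vol, "LabelVolume"))
  if (sum(vol@voxels) == 0) stop("mask is empty: no labeled voxels")
  d <- dim(vol@voxels)
  field <- array(0, d + 2L)
  field[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol@voxels
  if (smoothSigma > 0) field <- .gaussSmooth(field, smoothSigma)
  # voxel centers of the original array sit at (index - 1) * spacing
  xs <- (seq_len(d[1] + 2L) - 2) * vol@spacing[1]
  ys <- (seq_len(d[2] + 2L) - 2) * vol@spacing[2]
  zs <- (seq_len(d[3] + 2L) - 2) * vol@spacing[3]
  # inside is field > iso: extract {-field < -iso}
  surf <- .mt_isosurface(-as.numeric(field), xs, ys, zs, -iso)
  if (nrow(surf$vertices) == 0)
    stop("iso level ", iso, " produced an empty surface")
  V <- surf$vertices %*% t(vol@orientation)
  V <- sweep(V, 2, vol@origin, "+")
  f <- surf$faces
  if (det(vol@orientation) < 0) f <- f[, c(1, 3, 2)]
  mesh <- TriangleMesh(V, f, name)
  if (!isWatertight(mesh))
    stop("internal error: extracted iso-surface is not watertight")
  mesh
}
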