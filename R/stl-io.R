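# STL stores bare triangle soup (no vertex indexing), so loading deduplicates
# vertices by exact coordinate match to restore topology and make
# watertightness checkable. Units are taken to be mm.

.dedupVertices <- function(tri, name) {
  # tri: (3*nfacet) x 3 matrix, rows grouped per facet
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "|")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  v <- tri[uk, , drop = FALSE]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  TriangleMesh(v, f[keep, , drop = FALSE], name)
}

#' Load a triangle mesh from an STL file
#'
#' Reads binary or ASCII STL (auto-detected by default), deduplicates
#' vertices by exact coordinate match, and drops zero-area degenerate facets.
#' Coordinates are assumed to be mm in the anatomical frame.
#'
#' @param path STL file path.
#' @param fmt `"auto"`, `"stl_binary"` or `"stl_ascii"`.
#' @param name mesh label (defaults to the file name without extension).
#' @return a \linkS4class{TriangleMesh}.
#' @seealso [saveMesh()]
#' @export
loadMesh <- function(path, fmt = c("auto", "stl_binary", "stl_ascii"),
                     name = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (fmt == "auto") {
    size <- file.info(path)$size
    con <- file(path, "rb")
    head <- readBin(con, "raw", 84)
    close(con)
    fmt <- "stl_ascii"
    if (length(head) == 84) {
      n <- readBin(head[81:84], "integer", 1, size = 4, endian = "little")
      if (!is.na(n) && n >= 0 && size == 84 + 50 * as.numeric(n))
        fmt <- "stl_binary"
    }
  }
  tri <- if (fmt == "stl_binary") .readSTLBinary(path) else .readSTLAscii(path)
  if (nrow(tri) == 0) stop("STL file contains no facets: ", path)
  .dedupVertices(tri, name)
}

.readSTLBinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(n) || n < 0) stop("malformed binary STL: ", path)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  rec <- readBin(con, "raw", 50 * as.numeric(n))
  if (length(rec) < 50 * n) stop("truncated binary STL: ", path)
  rec <- matrix(rec, nrow = 50)
  flo <- readBin(as.vector(rec[1:48, ]), "numeric", 12 * n, size = 4,
                 endian = "little")
  flo <- matrix(flo, nrow = 12) # cols = facets; rows 4:12 are the 3 vertices
  tri <- matrix(as.vector(flo[4:12, ]), ncol = 3, byrow = TRUE)
  if (!all(is.finite(tri))) stop("non-finite coordinates in STL: ", path)
  tri
}

.readSTLAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0) return(matrix(numeric(0), 0, 3))
  if (length(vl) %% 3 != 0) stop("malformed ASCII STL (vertex count): ", path)
  toks <- strsplit(trimws(vl), "\\s+")
  co <- vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))
  tri <- t(co)
  if (!all(is.finite(tri))) stop("malformed ASCII STL coordinates: ", path)
  # STL is a float32 format: quantize so ASCII and binary encodings of the
  # same mesh load identically
  matrix(readBin(writeBin(as.numeric(tri), raw(), size = 4), "numeric",
                 length(tri), size = 4), nrow = nrow(tri))
}

#' Save a triangle mesh as STL
#'
#' Binary STL stores float32 coordinates; a round-trip load reproduces
#' vertices to float32 precision. ASCII output prints 9 significant digits
#' (enough to round-trip float32 exactly).
#'
#' @param mesh a non-empty \linkS4class{TriangleMesh}.
#' @param path output file path.
#' @param fmt `"stl_binary"` or `"stl_ascii"`.
#' @return `path`, invisibly.
#' @export
saveMesh <- function(mesh, path, fmt = c("stl_binary", "stl_ascii")) {
  stopifnot(is(mesh, "TriangleMesh"))
  fmt <- match.arg(fmt)
  .stopIfEmpty(mesh)
  # quantize to float32 up front so binary and ASCII encodings agree exactly
  v <- mesh@vertices
  v <- matrix(readBin(writeBin(as.numeric(v), raw(), size = 4), "numeric",
                      length(v), size = 4), nrow = nrow(v))
  f <- mesh@faces
  # facet normals
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (fmt == "stl_binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, a, b, cc)) # 12 floats per facet
    raw12 <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
    raw12 <- matrix(raw12, nrow = 48)
    attr2 <- as.raw(c(0, 0))
    rec <- rbind(raw12, matrix(rep(attr2, ncol(raw12)), nrow = 2))
    writeBin(as.vector(rec), con)
  } else {
    fmtv <- function(m) sprintf("      vertex %.9g %.9g %.9g",
                                m[, 1], m[, 2], m[, 3])
    lines <- c(sprintf("solid %s", mesh@name),
               as.vector(rbind(
                 sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[, 1], nrm[, 2], nrm[, 3]),
                 "    outer loop",
                 fmtv(a), fmtv(b), fmtv(cc),
                 "    endloop",
                 "  endfacet")),
               sprintf("endsolid %s", mesh@name))
    writeLines(lines, path)
  }
  invisible(path)
}
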