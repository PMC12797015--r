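#' Construct a ContourStack
#'
#' @param slices list of slices; each slice is a list with `position` (mm
#'   along the grossing axis), `thickness` (slab thickness, mm; defaults to
#'   4 mm when missing) and `contours`, a list of contours from
#'   [Contour()].
#' @param grossingAxis numeric(3) unit vector (default: anterior-posterior
#'   cuts).
#' @param inSliceBasis 2 x 3 matrix of in-slice unit vectors (default: u =
#'   left-right, v = cranial-caudal).
#' @return a \linkS4class{ContourStack}.
#' @export
ContourStack <- function(slices, grossingAxis = c(0, 1, 0),
                         inSliceBasis = rbind(c(1, 0, 0), c(0, 0, 1))) {
  slices <- lapply(slices, function(s) {
    if (is.null(s$thickness)) s$thickness <- 4
    s$position <- as.numeric(s$position)
    s$thickness <- as.numeric(s$thickness)
    s
  })
  new("ContourStack", grossingAxis = as.numeric(grossingAxis),
      inSliceBasis = inSliceBasis, slices = slices)
}

#' Construct a single planar contour
#'
#' @param points n x 2 matrix (mm, in-slice u/v coordinates) of an ordered
#'   closed polygon; the closing vertex is implicit and must not be repeated.
#' @param hole logical: is this polygon a negative (lumen/ulcer) region?
#' @return a contour list (`points`, `hole`).
#' @export
Contour <- function(points, hole = FALSE) {
  points <- matrix(as.numeric(points), ncol = 2, nrow = NROW(points))
  if (nrow(points) >= 2 &&
      isTRUE(all.equal(points[1, ], points[nrow(points), ])))
    points <- points[-nrow(points), , drop = FALSE]
  list(points = points, hole = isTRUE(hole))
}

setMethod("show", "ContourStack", function(object) {
  n <- length(object@slices)
  nc <- sum(vapply(object@slices, function(s) length(s$contours), 0L))
  cat(sprintf("ContourStack: %d slices, %d contours\n", n, nc))
  cat(sprintf("  grossing axis: [%.3f, %.3f, %.3f]\n",
              object@grossingAxis[1], object@grossingAxis[2],
              object@grossingAxis[3]))
  if (n > 0) {
    pos <- vapply(object@slices, function(s) s$position, 0)
    cat(sprintf("  positions mm: %s\n",
                paste(sprintf("%.1f", pos), collapse = ", ")))
  }
})

# segment-pair intersection test for polygon simplicity
.polygonIsSimple <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  a <- p
  b <- p[nxt, , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    # segments strictly after i, skipping the two adjacent ones
    j <- setdiff(seq.int(i + 2, n), if (i == 1) n else integer(0))
    if (!length(j)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    hit <- (d1 * d2 < 0 & d3 * d4 < 0)
    if (any(hit)) return(FALSE)
    # collinear overlap
    col <- d1 == 0 & d2 == 0
    if (any(col)) {
      for (jj in j[col]) {
        r1 <- range(a[i, 1], b[i, 1]); r2 <- range(a[jj, 1], b[jj, 1])
        q1 <- range(a[i, 2], b[i, 2]); q2 <- range(a[jj, 2], b[jj, 2])
        if (r1[1] <= r2[2] && r2[1] <= r1[2] &&
            q1[1] <= q2[2] && q2[1] <= q1[2]) return(FALSE)
      }
    }
  }
  TRUE
}

.shoelaceArea <- function(p) {
  n <- nrow(p)
  nxt <- c(seq_len(n)[-1], 1L)
  abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])) / 2
}

#' Validate a contour stack
#'
#' Reports findings as a data frame: empty slices (warning), polygons with
#' fewer than 3 points or self-intersections (fatal), non-positive slab
#' thickness (fatal), non-monotone slice positions (fatal), and a slide count
#' outside the usual 7-21 grossing range (note). Fatal findings block
#' [interpolateSurface()].
#'
#' @param stack a \linkS4class{ContourStack}.
#' @return data.frame with columns `severity` (`"fatal"`, `"warning"`,
#'   `"note"`), `slice` (index or `NA`) and `message`; zero rows when clean.
#' @export
validateStack <- function(stack) {
  stopifnot(is(stack, "ContourStack"))
  out <- list()
  add <- function(severity, slice, message)
    out[[length(out) + 1]] <<- data.frame(severity = severity,
                                          slice = slice, message = message)
  pos <- vapply(stack@slices, function(s) s$position, 0)
  if (length(pos) > 1 && any(diff(pos) <= 0))
    add("fatal", NA_integer_,
        "slice positions are not strictly increasing along the grossing axis")
  n <- length(stack@slices)
  if (n > 0 && (n < 7 || n > 21))
    add("note", NA_integer_,
        sprintf("%d slices is outside the usual 7-21 grossing range", n))
  for (i in seq_along(stack@slices)) {
    s <- stack@slices[[i]]
    if (s$thickness <= 0)
      add("fatal", i, "slab thickness must be positive")
    if (length(s$contours) == 0) {
      add("warning", i, "slice has no contours (treated as unsampled)")
      next
    }
    outer <- 0L
    for (ct in s$contours) {
      if (nrow(ct$points) < 3) {
        add("fatal", i, "contour with fewer than 3 points")
        next
      }
      if (!.polygonIsSimple(ct$points))
        add("fatal", i, "self-intersecting contour polygon")
      if (!isTRUE(ct$hole)) outer <- outer + 1L
    }
    if (outer == 0L)
      add("fatal", i, "slice has only hole contours")
  }
  if (length(out) == 0)
    return(data.frame(severity = character(0), slice = integer(0),
                      message = character(0)))
  do.call(rbind, out)
}

# composite signed distance of one slice's contour set on a grid:
# union of outer polygons, holes subtracted (CSG min/max combination)
.sliceField <- function(contours, gx, gy) {
  field <- matrix(Inf, length(gx), length(gy))
  holes <- NULL
  for (ct in contours) {
    d <- .polygon_sdf(ct$points, gx, gy)
    if (isTRUE(ct$hole)) holes <- c(holes, list(d)) else field <- pmin(field, d)
  }
  for (d in holes) field <- pmax(field, -d)
  field
}

#' 2D signed-distance field of one slice's contours
#'
#' Rasterizes the contour set of a single grossing slice to a signed-distance
#' field (negative inside tumor, positive outside; holes flip the sign).
#' The zero level set lies within one grid cell of the polygon boundary.
#'
#' @param contours list of contours ([Contour()]).
#' @param spacing grid spacing in mm.
#' @param bounds optional `list(u = c(min, max), v = c(min, max))`; computed
#'   from the contours (with a margin) when omitted.
#' @return list with grid coordinate vectors `u`, `v` and the `field` matrix
#'   (`length(u)` x `length(v)`).
#' @export
contourSDF <- function(contours, spacing = 0.5, bounds = NULL) {
  stopifnot(length(contours) > 0)
  pts <- do.call(rbind, lapply(contours, `[[`, "points"))
  for (ct in contours) {
    feat <- min(diff(range(ct$points[, 1])), diff(range(ct$points[, 2])))
    if (feat < 2 * spacing)
      stop(sprintf(paste0("grid spacing %.3g mm too coarse for smallest ",
                          "contour feature %.3g mm (need feature >= 2x ",
                          "spacing)"), spacing, feat))
  }
  if (is.null(bounds)) {
    pad <- 3 * spacing
    bounds <- list(u = range(pts[, 1]) + c(-1, 1) * pad,
                   v = range(pts[, 2]) + c(-1, 1) * pad)
  }
  gu <- seq(bounds$u[1], bounds$u[2], by = spacing)
  gv <- seq(bounds$v[1], bounds$v[2], by = spacing)
  list(u = gu, v = gv, field = .sliceField(contours, gu, gv))
}

#' Cavalieri (planimetric) volume of a contour stack
#'
#' Sum over slices of polygon area times slab thickness, holes subtracted.
#' Used as a stereological oracle for the interpolated surface.
#'
#' @param stack a \linkS4class{ContourStack}.
#' @return volume in cm^3 (0 for an empty stack).
#' @export
planimetricVolume <- function(stack) {
  stopifnot(is(stack, "ContourStack"))
  total <- 0
  for (s in stack@slices) {
    area <- 0
    for (ct in s$contours) {
      a <- .shoelaceArea(ct$points)
      area <- area + if (isTRUE(ct$hole)) -a else a
    }
    total <- total + area * s$thickness
  }
  total / 1000
}

#' Reconstruct a 3D tumor surface from grossing outlines
#'
#' Shape-based interpolation: each slice's contour set is rasterized to a 2D
#' signed-distance field, fields are interpolated linearly along the grossing
#' axis between adjacent slice planes (bridging unsampled gaps), and the
#' terminal slices are closed by a tapered end cap extending half a slab
#' thickness beyond the first/last plane (the field is inflated linearly with
#' distance past the terminal plane and capped by a far positive plane). The
#' zero iso-surface is extracted by marching tetrahedra and returned as a
#' watertight mesh in the anatomical frame.
#'
#' @param stack a \linkS4class{ContourStack} with at least one non-empty
#'   slice and no fatal [validateStack()] findings.
#' @param spacing grid spacing in mm, used in-plane and along the grossing
#'   axis (default 0.5 mm).
#' @param name label for the output mesh.
#' @return a watertight \linkS4class{TriangleMesh}.
#' @export
interpolateSurface <- function(stack, spacing = 0.5, name = "tumor_histo") {
  stopifnot(is(stack, "ContourStack"))
  findings <- validateStack(stack)
  fatal <- findings[findings$severity == "fatal", , drop = FALSE]
  if (nrow(fatal) > 0)
    stop("contour stack has fatal findings: ",
         paste(unique(fatal$message), collapse = "; "))
  keep <- vapply(stack@slices, function(s) length(s$contours) > 0, TRUE)
  slices <- stack@slices[keep]
  if (length(slices) == 0) stop("all slices are empty")

  pts <- do.call(rbind, lapply(slices, function(s)
    do.call(rbind, lapply(s$contours, `[[`, "points"))))
  pad <- 3 * spacing + 1
  gu <- seq(min(pts[, 1]) - pad, max(pts[, 1]) + pad, by = spacing)
  gv <- seq(min(pts[, 2]) - pad, max(pts[, 2]) + pad, by = spacing)

  fields <- lapply(slices, function(s) .sliceField(s$contours, gu, gv))
  pos <- vapply(slices, function(s) s$position, 0)
  th <- vapply(slices, function(s) s$thickness, 0)
  ns <- length(slices)
  big <- max(diff(range(gu)), diff(range(gv))) + max(th)

  capSamples <- function(p0, t0, dir) {
    # sample offsets within the end cap (0, t0/2]
    d <- if (t0 / 2 >= spacing) seq(spacing, t0 / 2, by = spacing)
         else numeric(0)
    if (!length(d) || max(d) < t0 / 2 - 1e-12) d <- c(d, t0 / 2)
    p0 + dir * d
  }
  zIn <- sort(unique(c(pos, if (ns > 1)
    unlist(lapply(seq_len(ns - 1), function(i)
      seq(pos[i], pos[i + 1], by = spacing))))))
  zLow <- sort(capSamples(pos[1], th[1], -1))
  zHigh <- capSamples(pos[ns], th[ns], +1)
  zs <- c(min(zLow) - spacing, zLow, zIn, zHigh, max(zHigh) + spacing)

  nx <- length(gu); ny <- length(gv); nz <- length(zs)
  arr <- array(big, dim = c(nx, ny, nz))
  capSlope <- 0.5 # mm of boundary inset per mm past the terminal plane
  for (k in seq_len(nz)) {
    z <- zs[k]
    if (z < pos[1]) {
      d <- pos[1] - z
      if (d <= th[1] / 2 + 1e-9) arr[, , k] <- fields[[1]] + capSlope * d
    } else if (z > pos[ns]) {
      d <- z - pos[ns]
      if (d <= th[ns] / 2 + 1e-9) arr[, , k] <- fields[[ns]] + capSlope * d
    } else {
      i <- max(1L, findInterval(z, pos, rightmost.closed = TRUE))
      if (i >= ns) { arr[, , k] <- fields[[ns]]; next }
      w <- (z - pos[i]) / (pos[i + 1] - pos[i])
      arr[, , k] <- (1 - w) * fields[[i]] + w * fields[[i + 1]]
    }
  }

  surf <- .mt_isosurface(as.numeric(arr), gu, gv, zs, 0)
  if (nrow(surf$vertices) == 0)
    stop("reconstruction produced an empty surface")
  M <- rbind(stack@inSliceBasis, stack@grossingAxis)
  V <- surf$vertices %*% M
  f <- surf$faces
  if (det(M) < 0) f <- f[, c(1, 3, 2)]
  mesh <- TriangleMesh(V, f, name)
  if (!isWatertight(mesh))
    stop("internal error: extracted surface is not watertight")
  mesh
}

# --- file formats ----------------------------------------------------------

#' Read a contour stack from JSON
#'
#' Schema (versioned, mm units):
#' `{"schema": "contour-stack-1", "grossing_axis": [x,y,z],`
#' `"in_slice_basis": [[..],[..]],`
#' `"slices": [{"position_mm": p, "thickness_mm": t,`
#' `"contours": [{"hole": false, "points_mm": [[u,v], ...]}]}]}`
#'
#' @param path JSON file path.
#' @return a \linkS4class{ContourStack}.
#' @export
readContourStack <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                           simplifyDataFrame = FALSE)
  if (is.null(j$slices)) stop("not a contour-stack file: ", path)
  slices <- lapply(j$slices, function(s) {
    list(position = as.numeric(s$position_mm),
         thickness = as.numeric(s$thickness_mm),
         contours = lapply(s$contours, function(ct)
           Contour(matrix(unlist(ct$points_mm), ncol = 2, byrow = !is.matrix(ct$points_mm)),
                   hole = isTRUE(ct$hole))))
  })
  basis <- j$in_slice_basis
  if (!is.matrix(basis)) basis <- do.call(rbind, basis)
  ContourStack(slices, grossingAxis = as.numeric(j$grossing_axis),
               inSliceBasis = basis)
}

#' Write a contour stack to JSON
#'
#' @param stack a \linkS4class{ContourStack}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeContourStack <- function(stack, path) {
  stopifnot(is(stack, "ContourStack"))
  j <- list(
    schema = "contour-stack-1",
    grossing_axis = as.numeric(stack@grossingAxis),
    in_slice_basis = apply(stack@inSliceBasis, 1, as.numeric,
                           simplify = FALSE),
    slices = lapply(stack@slices, function(s) list(
      position_mm = s$position,
      thickness_mm = s$thickness,
      contours = lapply(s$contours, function(ct) list(
        hole = isTRUE(ct$hole),
        points_mm = apply(ct$points, 1, as.numeric, simplify = FALSE))))))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import contours from delimited text
#'
#' One polygon per block, blocks separated by blank lines. Each block starts
#' with a header line `slice <position_mm> <thickness_mm> [hole]` followed by
#' one `u v` coordinate pair (mm) per line. Polygons sharing a position are
#' grouped onto one slice.
#'
#' @param path text file path.
#' @param grossingAxis,inSliceBasis frame placement, as in [ContourStack()].
#' @return a \linkS4class{ContourStack}.
#' @export
readContourText <- function(path, grossingAxis = c(0, 1, 0),
                            inSliceBasis = rbind(c(1, 0, 0), c(0, 0, 1))) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^#", lines)]
  blocks <- split(lines, cumsum(lines == ""))
  slices <- list()
  for (b in blocks) {
    b <- b[b != ""]
    if (!length(b)) next
    hd <- strsplit(b[1], "\\s+")[[1]]
    if (hd[1] != "slice" || length(hd) < 3)
      stop("block header must be 'slice <position_mm> <thickness_mm> [hole]'")
    posn <- as.numeric(hd[2]); thick <- as.numeric(hd[3])
    hole <- length(hd) >= 4 && hd[4] == "hole"
    co <- do.call(rbind, lapply(strsplit(b[-1], "[,[:space:]]+"),
                                function(t) as.numeric(t[1:2])))
    key <- sprintf("%.9g", posn)
    if (is.null(slices[[key]]))
      slices[[key]] <- list(position = posn, thickness = thick,
                            contours = list())
    slices[[key]]$contours <- c(slices[[key]]$contours,
                                list(Contour(co, hole = hole)))
  }
  ord <- order(vapply(slices, function(s) s$position, 0))
  ContourStack(unname(slices[ord]), grossingAxis = grossingAxis,
               inSliceBasis = inSliceBasis)
}
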