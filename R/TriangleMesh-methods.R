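#' Construct a TriangleMesh
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm, anatomical
#'   frame).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param name text label for the body.
#' @return a \linkS4class{TriangleMesh}.
#' @export
TriangleMesh <- function(vertices, faces, name = "mesh") {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     nrow = NROW(vertices), dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3, nrow = NROW(faces),
                  dimnames = NULL)
  new("TriangleMesh", vertices = vertices, faces = faces, name = name)
}

#' @rdname TriangleMesh-class
#' @export
setMethod("vertices", "TriangleMesh", function(x) x@vertices)

#' @rdname TriangleMesh-class
#' @export
setMethod("faces", "TriangleMesh", function(x) x@faces)

#' @rdname TriangleMesh-class
#' @export
setMethod("meshName", "TriangleMesh", function(x) x@name)

setMethod("show", "TriangleMesh", function(object) {
  wt <- if (nrow(object@faces) > 0) {
    if (isWatertight(object)) "watertight" else "NOT watertight"
  } else "empty"
  cat(sprintf("TriangleMesh '%s': %d vertices, %d faces (%s)\n",
              object@name, nrow(object@vertices), nrow(object@faces), wt))
  if (nrow(object@vertices) > 0) {
    rng <- apply(object@vertices, 2, range)
    cat(sprintf("  bbox mm: LR [%.1f, %.1f]  AP [%.1f, %.1f]  CC [%.1f, %.1f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
})

.stopIfEmpty <- function(mesh) {
  if (nrow(mesh@vertices) == 0 || nrow(mesh@faces) == 0)
    stop("mesh '", mesh@name, "' is empty")
}

#' @rdname isWatertight
setMethod("isWatertight", "TriangleMesh", function(x) {
  f <- x@faces
  if (nrow(f) == 0) return(FALSE)
  nv <- nrow(x@vertices)
  # directed edges; closed + consistently oriented <=> every directed edge
  # unique and matched by its exact reverse
  from <- c(f[, 1], f[, 2], f[, 3])
  to   <- c(f[, 2], f[, 3], f[, 1])
  fwd <- (from - 1) * nv + to
  rev <- (to - 1) * nv + from
  !anyDuplicated(fwd) && length(fwd) == sum(fwd %in% rev)
})

#' @rdname meshVolume
setMethod("meshVolume", "TriangleMesh", function(x) {
  .stopIfEmpty(x)
  if (!isWatertight(x))
    stop("mesh '", x@name, "' is not watertight; refusing volume computation")
  v <- x@vertices; f <- x@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  # signed tetrahedron volumes against the origin: det([a b c]) / 6
  s <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
       a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
       a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(s)) / 6 / 1000
})

#' @rdname directionalExtent
setMethod("directionalExtent", "TriangleMesh", function(x, axis) {
  .stopIfEmpty(x)
  axis <- match.arg(axis, names(.AXES))
  co <- x@vertices[, .AXES[[axis]]]
  (max(co) - min(co)) / 10
})

#' @rdname maxDiameter
setMethod("maxDiameter", "TriangleMesh", function(x) {
  .stopIfEmpty(x)
  v <- x@vertices
  if (nrow(v) > 600) {
    hull <- .convex_hull_vertices(v)
    v <- v[hull, , drop = FALSE]
  }
  .max_pairwise_distance(v) / 10
})

#' Plain-list summary of a mesh
#'
#' Collects the standard per-body measurements into a list suitable for JSON
#' serialization: vertex/face counts, watertightness, volume (cm^3),
#' LR/AP/CC extents (cm) and the greatest surface diameter (cm).
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return named list.
#' @export
meshSummary <- function(mesh) {
  stopifnot(is(mesh, "TriangleMesh"))
  wt <- isWatertight(mesh)
  list(
    name = mesh@name,
    n_vertices = nrow(mesh@vertices),
    n_faces = nrow(mesh@faces),
    watertight = wt,
    volume_cm3 = if (wt) meshVolume(mesh) else NA_real_,
    extents_cm = list(LR = directionalExtent(mesh, "LR"),
                      AP = directionalExtent(mesh, "AP"),
                      CC = directionalExtent(mesh, "CC")),
    max_diameter_cm = maxDiameter(mesh)
  )
}

#' Number of connected surface components
#'
#' Components are counted over face connectivity (faces sharing a vertex are
#' connected); multifocal tumors reconstruct to more than one component.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return integer component count.
#' @export
meshComponents <- function(mesh) {
  stopifnot(is(mesh, "TriangleMesh"))
  n <- nrow(mesh@vertices)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh@faces
  for (col in 2:3) {
    for (r in seq_len(nrow(f))) {
      a <- find(f[r, 1]); b <- find(f[r, col])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(unique(as.vector(f)), find, 0L)
  length(unique(roots))
}

# --- simple analytic primitives (examples, tests, phantoms) ----------------

#' Axis-aligned cube mesh
#'
#' @param side edge length in mm.
#' @param center numeric(3) centre, mm.
#' @param name mesh label.
#' @return watertight \linkS4class{TriangleMesh} with 8 vertices, 12 faces.
#' @export
cubeMesh <- function(side = 10, center = c(0, 0, 0), name = "cube") {
  h <- side / 2
  v <- as.matrix(expand.grid(c(-h, h), c(-h, h), c(-h, h)))
  v <- sweep(v, 2, center, "+")
  # 12 triangles, outward orientation
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z-
    c(5, 6, 7), c(6, 8, 7),   # z+
    c(1, 2, 5), c(2, 6, 5),   # y-
    c(3, 7, 4), c(4, 7, 8),   # y+
    c(1, 5, 3), c(3, 5, 7),   # x-
    c(2, 4, 6), c(4, 8, 6))   # x+
  TriangleMesh(v, f, name)
}

#' Subdivided icosahedron sphere mesh
#'
#' @param radius mm.
#' @param center numeric(3) centre, mm.
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 = plain
#'   icosahedron; 4 gives 5120 faces).
#' @param name mesh label.
#' @return watertight \linkS4class{TriangleMesh}.
#' @export
icosphereMesh <- function(radius = 10, center = c(0, 0, 0), subdivisions = 3,
                          name = "sphere") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      p <- vlist[[a]] + vlist[[b]]
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1]] <<- p
      id <- length(vlist)
      mid[[key]] <- id
      id
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * i - 3, ] <- c(a, ab, ca)
      nf[4 * i - 2, ] <- c(b, bc, ab)
      nf[4 * i - 1, ] <- c(cc, ca, bc)
      nf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  v <- sweep(v * radius, 2, center, "+")
  TriangleMesh(v, f, name)
}

#' Axis-aligned ellipsoid mesh
#'
#' @param semiAxes numeric(3), semi-axis lengths (mm) along LR, AP, CC.
#' @param center numeric(3) centre, mm.
#' @param subdivisions icosphere subdivisions.
#' @param name mesh label.
#' @return watertight \linkS4class{TriangleMesh}.
#' @export
ellipsoidMesh <- function(semiAxes, center = c(0, 0, 0), subdivisions = 3,
                          name = "ellipsoid") {
  m <- icosphereMesh(1, c(0, 0, 0), subdivisions, name)
  v <- sweep(m@vertices, 2, semiAxes, "*")
  TriangleMesh(sweep(v, 2, center, "+"), m@faces, name)
}
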