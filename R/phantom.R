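# Seeded synthetic specimen/tumor cases: every pipeline stage is testable
# without patient data. Truth values come from the ground-truth mesh (or
# analytically), never from pipeline outputs.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.randomRotation <- function() {
  # uniform random rotation via normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Specify a synthetic phantom case
#'
#' Parameter ranges mirror the target cohort: tumor volumes 0.4-12.6 cm^3,
#' 7-21 grossing slabs, MRI slice dimension 3-4 mm, optional 4\%-6\%
#' isotropic histology-side shrinkage. Unset parameters are drawn per seed
#' at generation time (volume log-uniform over its range; slab count chosen
#' so slabs are at most ~2.5 mm).
#'
#' @param seed integer; identical seeds give identical phantoms.
#' @param targetVolume tumor volume in cm^3, in `[0.4, 12.6]`, or `NULL` to
#'   draw per seed.
#' @param semiAxes optional numeric(3) base-ellipsoid semi-axes in mm
#'   (otherwise axis ratios are drawn per seed). When combined with
#'   `targetVolume`, the axes are rescaled uniformly to hit the target; a
#'   target more than 25\% away in linear scale is refused as unreachable.
#' @param perturbAmplitude smooth radial perturbation amplitude (fraction of
#'   the ellipsoid radius, at most 0.3 so bodies stay star-shaped).
#' @param specimenMargin specimen offset around the tumor, mm.
#' @param nSlices grossing slab count in `[7, 21]`, or `NULL` to derive from
#'   the tumor extent.
#' @param mriSpacing numeric(3) MRI voxel size, mm; slice dimension (third
#'   axis) in `[3, 4]`.
#' @param shrinkage histology-side isotropic scale in `[0.94, 1]` (1 = no
#'   shrinkage correction scenario).
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(seed, targetVolume = NULL, semiAxes = NULL,
                        perturbAmplitude = 0.15,
                        specimenMargin = 8, nSlices = NULL,
                        mriSpacing = c(1, 1, 3), shrinkage = 1.0) {
  stopifnot(length(seed) == 1, is.finite(seed))
  if (!is.null(targetVolume) &&
      (targetVolume < 0.4 || targetVolume > 12.6))
    stop("targetVolume must lie in the cohort range [0.4, 12.6] cm^3")
  if (!is.null(semiAxes)) {
    stopifnot(length(semiAxes) == 3, all(semiAxes > 0))
    if (!is.null(targetVolume)) {
      s <- (targetVolume * 1000 / (4 / 3 * pi * prod(semiAxes)))^(1 / 3)
      if (s < 0.75 || s > 1.25)
        stop("targetVolume unreachable with the given semi-axes ",
             "(would need a ", sprintf("%.2f", s), "x rescale)")
    }
  }
  if (perturbAmplitude < 0 || perturbAmplitude > 0.3)
    stop("perturbAmplitude must lie in [0, 0.3] to keep bodies star-shaped")
  if (!is.null(nSlices) && (nSlices < 7 || nSlices > 21))
    stop("nSlices must lie in the cohort range [7, 21]")
  if (length(mriSpacing) != 3 || any(mriSpacing <= 0) ||
      mriSpacing[3] < 3 || mriSpacing[3] > 4)
    stop("mriSpacing slice dimension must lie in [3, 4] mm")
  if (shrinkage < 0.94 || shrinkage > 1)
    stop("shrinkage must lie in [0.94, 1]")
  structure(list(seed = as.integer(seed), targetVolume = targetVolume,
                 semiAxes = semiAxes,
                 perturbAmplitude = perturbAmplitude,
                 specimenMargin = specimenMargin, nSlices = nSlices,
                 mriSpacing = as.numeric(mriSpacing), shrinkage = shrinkage),
            class = "PhantomSpec")
}

# smooth low-order radial modulation (degree-1/2 harmonic mix), normalized
# to max |P| = 1 over the given directions
.radialPerturbation <- function(dirs, coef) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  basis <- cbind(x, y, z, x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1)
  p <- as.numeric(basis %*% coef)
  m <- max(abs(p))
  if (m == 0) p else p / m
}

.starMesh <- function(dirs, radii, faces, name) {
  TriangleMesh(dirs * radii, faces, name)
}

# unit-sphere prototype shared by all phantoms (subdivision 4: 10242
# vertices, fine enough that mesh faceting contributes < 1% volume error)
.phantomProtoEnv <- new.env(parent = emptyenv())
.phantomProto <- function(subdivisions = 4) {
  key <- as.character(subdivisions)
  if (is.null(.phantomProtoEnv[[key]]))
    .phantomProtoEnv[[key]] <- icosphereMesh(1, subdivisions = subdivisions)
  .phantomProtoEnv[[key]]
}

#' Generate a fully synthetic specimen/tumor case
#'
#' Builds, deterministically from the seed: a star-shaped perturbed-ellipsoid
#' tumor mesh and an offset specimen mesh in the specimen frame; the tumor
#' rasterized as an MRI-style binary mask in a randomly rotated/translated
#' MRI frame; grossing contours of the (optionally shrunk) tumor; named
#' landmark pairs on the specimen surface in both frames; and the ground
#' truth (volumes, extents, diameter, true MRI-to-specimen transform).
#'
#' @param spec a [phantomSpec()].
#' @return a \linkS4class{PhantomCase}.
#' @examples
#' ph <- generatePhantom(phantomSpec(1, targetVolume = 4))
#' ph@truth$volume_cm3
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  .withSeed(spec$seed, {
    targetVolume <- spec$targetVolume
    if (is.null(targetVolume) && is.null(spec$semiAxes))
      targetVolume <- exp(stats::runif(1, log(0.4), log(12.6)))

    if (!is.null(spec$semiAxes)) {
      semi <- spec$semiAxes
      if (!is.null(targetVolume))
        semi <- semi * (targetVolume * 1000 /
                          (4 / 3 * pi * prod(semi)))^(1 / 3)
    } else {
      # base ellipsoid with randomized axis ratios hitting the target volume
      ratios <- c(1, stats::runif(2, 0.55, 0.9))[sample.int(3)]
      s3 <- targetVolume * 1000 / (4 / 3 * pi * prod(ratios))
      semi <- ratios * s3^(1 / 3)
    }

    proto <- .phantomProto(4)
    dirs <- proto@vertices
    rEll <- 1 / sqrt(rowSums(sweep(dirs, 2, semi, "/")^2))
    coef <- stats::rnorm(8)
    p <- .radialPerturbation(dirs, coef)
    radii <- rEll * (1 + spec$perturbAmplitude * p)
    tumor <- .starMesh(dirs, radii, proto@faces, "tumor_truth")
    specimen <- .starMesh(dirs, radii + spec$specimenMargin, proto@faces,
                          "specimen")

    # landmarks: pins at named anatomy on the specimen surface
    lmNames <- c("tongue_midline_ant", "tongue_midline_post",
                 "sublingual_gland", "palatine_tonsil", "palatal_arch")
    lmDirs <- rbind(c(0, -1, 0), c(0, 1, 0), c(0.3, 0.2, -1),
                    c(1, 0.4, 0.3), c(-0.6, 0.8, 0.6))
    lmDirs <- lmDirs + matrix(stats::rnorm(15, sd = 0.08), 5, 3)
    lmDirs <- lmDirs / sqrt(rowSums(lmDirs^2))
    rScale <- mean(radii) + spec$specimenMargin
    lmSpec <- lmDirs * rScale
    rownames(lmSpec) <- lmNames
    landmarksSpecimen <- new("LandmarkSet", points = lmSpec,
                             frame = "specimen")

    # true MRI -> specimen transform
    trueT <- RigidTransform(.randomRotation(),
                            stats::runif(3, -25, 25), 1)
    invT <- invertTransform(trueT)
    landmarksMRI <- applyTransform(landmarksSpecimen, invT)
    landmarksMRI@frame <- "mri"

    # MRI-side mask: rasterize the tumor as seen in the MRI frame
    tumorMri <- applyTransform(tumor, invT)
    tumorMri@name <- "tumor_mri"
    mask <- rasterizeMesh(tumorMri, spacing = spec$mriSpacing)

    # histology side: shrink about the centroid, then gross into slabs
    shrunk <- tumor
    if (spec$shrinkage < 1) {
      ctr <- colMeans(tumor@vertices)
      v <- sweep(tumor@vertices, 2, ctr) * spec$shrinkage
      shrunk <- TriangleMesh(sweep(v, 2, ctr, "+"), tumor@faces,
                             "tumor_histo_truth")
    }
    axis <- c(0, 1, 0) # grossing along anterior-posterior
    w <- shrunk@vertices %*% axis
    ext <- max(w) - min(w)
    nSlices <- spec$nSlices
    if (is.null(nSlices))
      nSlices <- max(7L, min(21L, as.integer(ceiling(ext / 2.5))))
    sp <- ext / nSlices
    positions <- min(w) + sp * (seq_len(nSlices) - 0.5)
    stack <- sliceMeshToContours(shrunk, positions, axis = axis,
                                 thickness = sp)

    truth <- list(
      seed = spec$seed,
      volume_cm3 = meshVolume(tumor),
      histo_volume_cm3 = meshVolume(tumor) * spec$shrinkage^3,
      extents_cm = c(LR = directionalExtent(tumor, "LR"),
                     AP = directionalExtent(tumor, "AP"),
                     CC = directionalExtent(tumor, "CC")),
      diameter_cm = maxDiameter(tumor),
      shrinkage = spec$shrinkage,
      transform = trueT)

    new("PhantomCase", specimenMesh = specimen, tumorMesh = tumor,
        mriMask = mask, contourStack = stack, landmarksMRI = landmarksMRI,
        landmarksSpecimen = landmarksSpecimen, truth = truth)
  })
}

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase (seed %d):\n", object@truth$seed))
  cat(sprintf("  truth volume %.3f cm^3, diameter %.2f cm, shrinkage %.2f\n",
              object@truth$volume_cm3, object@truth$diameter_cm,
              object@truth$shrinkage))
  cat(sprintf("  %d grossing slices, mask %s voxels\n",
              length(object@contourStack@slices),
              paste(dim(object@mriMask@voxels), collapse = "x")))
})

#' Cross-section a watertight mesh into grossing contours
#'
#' Cuts the mesh at the given plane positions along a grossing axis and
#' chains the triangle/plane intersection segments into simple closed
#' polygons (several per plane for multifocal cross-sections, none where the
#' plane misses the body). Chaining is topological (via shared mesh edges),
#' so polygons close exactly. Nested polygons are flagged as holes by
#' nesting parity.
#'
#' @param mesh a watertight \linkS4class{TriangleMesh}.
#' @param positions plane positions in mm along `axis`, strictly increasing.
#' @param axis unit grossing direction (default anterior-posterior).
#' @param thickness slab thickness in mm: one value recycled, or one per
#'   plane.
#' @param inSliceBasis optional 2 x 3 in-plane basis; a right-handed
#'   complement of `axis` is chosen when omitted.
#' @return a \linkS4class{ContourStack}.
#' @export
sliceMeshToContours <- function(mesh, positions, axis = c(0, 1, 0),
                                thickness = 4, inSliceBasis = NULL) {
  stopifnot(is(mesh, "TriangleMesh"))
  .stopIfEmpty(mesh)
  if (!isWatertight(mesh))
    stop("mesh '", mesh@name, "' is not watertight; cannot take clean ",
         "cross-sections")
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(inSliceBasis)) {
    seedv <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- seedv - sum(seedv * axis) * axis
    u <- u / sqrt(sum(u^2))
    v <- c(axis[2] * u[3] - axis[3] * u[2],
           axis[3] * u[1] - axis[1] * u[3],
           axis[1] * u[2] - axis[2] * u[1])
    # (u, v, axis) right-handed
    inSliceBasis <- rbind(v, u)
    if (det(rbind(inSliceBasis, axis)) < 0) inSliceBasis <- rbind(u, v)
  }
  thickness <- rep(thickness, length.out = length(positions))
  W <- as.numeric(mesh@vertices %*% axis)
  U <- as.numeric(mesh@vertices %*% inSliceBasis[1, ])
  V <- as.numeric(mesh@vertices %*% inSliceBasis[2, ])
  f <- mesh@faces
  slices <- vector("list", length(positions))
  for (si in seq_along(positions)) {
    p <- positions[si]
    while (any(abs(W - p) < 1e-9)) p <- p + 1e-6
    contours <- .sectionPolygons(U, V, W, f, p)
    slices[[si]] <- list(position = positions[si],
                         thickness = thickness[si], contours = contours)
  }
  ContourStack(slices, grossingAxis = axis, inSliceBasis = inSliceBasis)
}

.sectionPolygons <- function(U, V, W, f, p) {
  side <- W > p
  s1 <- side[f[, 1]]; s2 <- side[f[, 2]]; s3 <- side[f[, 3]]
  crossing <- which(s1 != s2 | s2 != s3)
  if (!length(crossing)) return(list())
  edgeKey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  pointOnEdge <- new.env(parent = emptyenv())
  edgePoint <- function(a, b) {
    k <- edgeKey(a, b)
    pt <- pointOnEdge[[k]]
    if (is.null(pt)) {
      lo <- min(a, b); hi <- max(a, b)
      t <- (p - W[lo]) / (W[hi] - W[lo])
      pt <- c(U[lo] + t * (U[hi] - U[lo]), V[lo] + t * (V[hi] - V[lo]))
      pointOnEdge[[k]] <- pt
    }
    pt
  }
  adj <- new.env(parent = emptyenv())
  addLink <- function(k1, k2) {
    adj[[k1]] <- c(adj[[k1]], k2)
    adj[[k2]] <- c(adj[[k2]], k1)
  }
  for (fi in crossing) {
    vv <- f[fi, ]
    cs <- combn(3, 2)
    keys <- character(0)
    for (e in 1:3) {
      a <- vv[cs[1, e]]; b <- vv[cs[2, e]]
      if (side[a] != side[b]) {
        edgePoint(a, b)
        keys <- c(keys, edgeKey(a, b))
      }
    }
    if (length(keys) == 2) addLink(keys[1], keys[2])
  }
  # walk closed loops (every node has degree 2 on a watertight mesh)
  visited <- new.env(parent = emptyenv())
  polys <- list()
  for (k in ls(adj)) {
    if (!is.null(visited[[k]])) next
    loop <- character(0)
    cur <- k
    prev <- ""
    repeat {
      loop <- c(loop, cur)
      visited[[cur]] <- TRUE
      nbrs <- adj[[cur]]
      nxt <- nbrs[nbrs != prev]
      if (!length(nxt)) break
      prev <- cur
      cur <- nxt[1]
      if (cur == k) break
    }
    if (length(loop) >= 3) {
      pts <- t(vapply(loop, function(kk) pointOnEdge[[kk]], numeric(2)))
      rownames(pts) <- NULL
      polys <- c(polys, list(pts))
    }
  }
  if (!length(polys)) return(list())
  # hole flags by nesting parity
  inPoly <- function(pt, poly) {
    n <- nrow(poly)
    j <- n
    inside <- FALSE
    for (i in seq_len(n)) {
      if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) {
        xi <- poly[j, 1] + (pt[2] - poly[j, 2]) /
          (poly[i, 2] - poly[j, 2]) * (poly[i, 1] - poly[j, 1])
        if (pt[1] < xi) inside <- !inside
      }
      j <- i
    }
    inside
  }
  lapply(seq_along(polys), function(i) {
    depth <- sum(vapply(seq_along(polys)[-i], function(j)
      inPoly(polys[[i]][1, ], polys[[j]]), TRUE))
    Contour(polys[[i]], hole = depth %% 2 == 1)
  })
}

#' Rasterize a watertight mesh into a binary label volume
#'
#' A voxel is labeled 1 iff its centre lies inside the mesh (parity of ray
#' crossings). The grid covers the mesh bounding box with a one-voxel
#' margin; orientation is the identity (array axes = anatomical axes).
#'
#' @param mesh a watertight \linkS4class{TriangleMesh}.
#' @param spacing numeric(3) voxel size, mm.
#' @param origin optional numeric(3) centre of voxel `[1,1,1]`; derived from
#'   the bounding box when omitted.
#' @param dims optional integer(3) voxel counts (required if `origin` is
#'   given).
#' @return a \linkS4class{LabelVolume}.
#' @export
rasterizeMesh <- function(mesh, spacing = c(1, 1, 3), origin = NULL,
                          dims = NULL) {
  stopifnot(is(mesh, "TriangleMesh"))
  .stopIfEmpty(mesh)
  if (!isWatertight(mesh))
    stop("mesh '", mesh@name, "' is not watertight; cannot voxelize")
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (is.null(origin)) {
    lo <- apply(mesh@vertices, 2, min)
    hi <- apply(mesh@vertices, 2, max)
    origin <- lo - spacing
    dims <- as.integer(ceiling((hi - origin) / spacing) + 2)
  } else if (is.null(dims)) {
    stop("dims must be supplied together with origin")
  }
  vox <- .voxelize_mesh(mesh@vertices, mesh@faces, as.numeric(origin),
                        spacing, as.integer(dims))
  LabelVolume(array(vox, dim = dims), spacing, origin, diag(3))
}
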