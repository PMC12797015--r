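#' Construct a LandmarkSet
#'
#' @param points named list of numeric(3) coordinates (mm), or an n x 3
#'   matrix with rownames.
#' @param frame `"mri"` or `"specimen"`.
#' @return a \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(points, frame = c("specimen", "mri")) {
  frame <- match.arg(frame)
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nm
  }
  new("LandmarkSet", points = points, frame = frame)
}

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet (%s frame): %d landmarks\n",
              object@frame, nrow(object@points)))
  for (i in seq_len(nrow(object@points)))
    cat(sprintf("  %-22s [%8.2f, %8.2f, %8.2f] mm\n",
                rownames(object@points)[i], object@points[i, 1],
                object@points[i, 2], object@points[i, 3]))
})

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation numeric(3), mm.
#' @param scale positive scalar (1 = rigid).
#' @return a \linkS4class{RigidTransform}.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation), scale = as.numeric(scale))
}

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform:\n  rotation:\n")
  print(round(object@rotation, 6))
  cat(sprintf("  translation: [%.3f, %.3f, %.3f] mm\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
  cat(sprintf("  scale: %.6f\n", object@scale))
})

#' Invert a rigid/similarity transform
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @return the inverse \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  stopifnot(is(transform, "RigidTransform"))
  Rt <- t(transform@rotation)
  s <- transform@scale
  RigidTransform(Rt, -Rt %*% transform@translation / s, 1 / s)
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying `second` after `first`.
#'
#' @param first,second \linkS4class{RigidTransform} objects.
#' @return a \linkS4class{RigidTransform}.
#' @export
composeTransforms <- function(second, first) {
  stopifnot(is(first, "RigidTransform"), is(second, "RigidTransform"))
  RigidTransform(second@rotation %*% first@rotation,
                 second@scale * second@rotation %*% first@translation +
                   second@translation,
                 second@scale * first@scale)
}

.matchedPoints <- function(moving, fixed) {
  mn <- rownames(moving@points)
  fn <- rownames(fixed@points)
  common <- intersect(mn, fn)
  onlyM <- setdiff(mn, fn)
  onlyF <- setdiff(fn, mn)
  if (length(common) < 3) {
    extra <- c(
      if (length(onlyM)) paste0("unmatched in moving: ",
                                paste(onlyM, collapse = ", ")),
      if (length(onlyF)) paste0("unmatched in fixed: ",
                                paste(onlyF, collapse = ", ")))
    stop("need >= 3 common landmark names, found ", length(common),
         if (length(common)) paste0(" (", paste(common, collapse = ", "), ")"),
         if (length(extra)) paste0("; ", paste(extra, collapse = "; ")))
  }
  list(moving = moving@points[common, , drop = FALSE],
       fixed = fixed@points[common, , drop = FALSE])
}

#' Closed-form least-squares landmark transform (Kabsch/Umeyama)
#'
#' Finds the rigid (or, with `allowScale`, similarity) transform `T`
#' minimizing `sum || T(m_i) - f_i ||^2` over landmarks matched by name.
#' The rotation comes from the SVD of the cross-covariance of the centered
#' point sets; reflection solutions are excluded by forcing `det = +1`.
#' With `allowScale = TRUE` the isotropic scale follows Umeyama's estimator,
#' which recovers e.g. formalin-fixation shrinkage (about 4\%-6\%) exactly in
#' the noiseless case.
#'
#' @param moving,fixed \linkS4class{LandmarkSet} objects; the fit maps
#'   `moving` onto `fixed`.
#' @param allowScale fit a similarity transform instead of a rigid one.
#' @return a \linkS4class{RigidTransform}.
#' @seealso [fiducialRegistrationError()], [applyTransform()]
#' @export
fitLandmarkTransform <- function(moving, fixed, allowScale = FALSE) {
  stopifnot(is(moving, "LandmarkSet"), is(fixed, "LandmarkSet"))
  mp <- .matchedPoints(moving, fixed)
  M <- mp$moving; F <- mp$fixed
  muM <- colMeans(M); muF <- colMeans(F)
  Mc <- sweep(M, 2, muM); Fc <- sweep(F, 2, muF)
  scaleRef <- max(sqrt(rowSums(Mc^2)))
  sv <- svd(Mc)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1))
    stop("landmarks are collinear; the rotation about their axis is ",
         "under-determined - add a non-collinear landmark")
  H <- t(Mc) %*% Fc
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  S <- diag(c(1, 1, d))
  R <- dec$v %*% S %*% t(dec$u)
  s <- 1
  if (allowScale) {
    varM <- sum(Mc^2)
    s <- sum(dec$d * c(1, 1, d)) / varM
    if (s <= 0) stop("degenerate configuration: non-positive scale estimate")
  }
  tr <- muF - s * R %*% muM
  RigidTransform(R, tr, s)
}

#' Fiducial registration error (FRE)
#'
#' Root-mean-square residual distance of the name-matched landmarks after
#' applying the transform to the moving set. With fewer than 3 common names
#' the residual is still reported (unlike fitting, which requires >= 3).
#'
#' @param moving,fixed \linkS4class{LandmarkSet} objects.
#' @param transform a \linkS4class{RigidTransform} mapping `moving` to
#'   `fixed`.
#' @return RMS residual in mm.
#' @export
fiducialRegistrationError <- function(moving, fixed, transform) {
  stopifnot(is(moving, "LandmarkSet"), is(fixed, "LandmarkSet"),
            is(transform, "RigidTransform"))
  common <- intersect(rownames(moving@points), rownames(fixed@points))
  if (length(common) < 1) stop("no common landmark names")
  M <- moving@points[common, , drop = FALSE]
  F <- fixed@points[common, , drop = FALSE]
  Mt <- applyTransform(M, transform)
  sqrt(mean(rowSums((Mt - F)^2)))
}

#' @rdname applyTransform
setMethod("applyTransform", "matrix", function(x, transform) {
  stopifnot(is(transform, "RigidTransform"), ncol(x) == 3)
  out <- transform@scale * x %*% t(transform@rotation)
  sweep(out, 2, as.numeric(transform@translation), "+")
})

#' @rdname applyTransform
setMethod("applyTransform", "TriangleMesh", function(x, transform) {
  v <- applyTransform(x@vertices, transform)
  TriangleMesh(v, x@faces, x@name)
})

#' @rdname applyTransform
setMethod("applyTransform", "LandmarkSet", function(x, transform) {
  p <- applyTransform(x@points, transform)
  rownames(p) <- rownames(x@points)
  new("LandmarkSet", points = p, frame = x@frame)
})

# --- JSON I/O --------------------------------------------------------------

#' Read landmarks from JSON
#'
#' Schema: `{"frame": "mri"|"specimen", "points": {"name": [x, y, z], ...}}`,
#' coordinates in mm.
#'
#' @param path JSON file path.
#' @return a \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$frame) || is.null(j$points))
    stop("landmark file must contain 'frame' and 'points': ", path)
  pts <- lapply(j$points, as.numeric)
  LandmarkSet(pts, frame = j$frame)
}

#' Write landmarks to JSON
#'
#' @param landmarks a \linkS4class{LandmarkSet}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  pts <- lapply(seq_len(nrow(landmarks@points)),
                function(i) as.numeric(landmarks@points[i, ]))
  names(pts) <- rownames(landmarks@points)
  jsonlite::write_json(list(frame = landmarks@frame, points = pts), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform from its JSON audit form
#'
#' @param path JSON file path with fields `rotation` (3 x 3), `translation`
#'   and `scale`.
#' @return a \linkS4class{RigidTransform}.
#' @export
readTransform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  RigidTransform(matrix(as.numeric(t(j$rotation)), 3, 3, byrow = TRUE),
                 as.numeric(j$translation), as.numeric(j$scale))
}

#' Write a transform to JSON for audit
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTransform <- function(transform, path) {
  stopifnot(is(transform, "RigidTransform"))
  jsonlite::write_json(
    list(rotation = apply(transform@rotation, 1, as.numeric,
                          simplify = FALSE),
         translation = as.numeric(transform@translation),
         scale = transform@scale),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
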