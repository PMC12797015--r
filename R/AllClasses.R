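#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib TumorFusion3D, .registration = TRUE
NULL

# Anatomical frame used throughout (LPS-like, mm):
#   axis 1 = left(+)/right(-), axis 2 = posterior(+)/anterior(-),
#   axis 3 = cranial(+)/caudal(-). Right-handed.
.AXES <- c(LR = 1L, AP = 2L, CC = 3L)

#' Watertight triangulated surface in the anatomical frame
#'
#' A triangle mesh with vertices in millimetres, expressed in the package's
#' fixed anatomical frame: axis 1 left(+)/right(-), axis 2
#' posterior(+)/anterior(-), axis 3 cranial(+)/caudal(-) (an LPS convention).
#' All measurement primitives ([meshVolume()], [directionalExtent()],
#' [maxDiameter()]) operate on this class.
#'
#' @slot vertices numeric matrix (n x 3), vertex coordinates in mm.
#' @slot faces integer matrix (m x 3), 1-based vertex indices per triangle.
#' @slot name character label, e.g. `"specimen"`, `"tumor_histo"`,
#'   `"tumor_mri"`.
#'
#' @seealso [TriangleMesh()], [loadMesh()], [meshVolume()]
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix", name = "character"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3), name = "mesh"))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (ncol(f) != 3) return("faces must have 3 columns")
  if (!all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f) > 0) {
    if (!is.numeric(f)) return("faces must be numeric indices")
    if (any(f < 1 | f > nrow(v))) return("face indices out of range")
    if (any(f != round(f))) return("face indices must be integers")
    dup <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(dup)) return("degenerate faces (repeated vertex index)")
  }
  TRUE
})

#' Ordered grossing-plane tumor outlines
#'
#' The raw representation of the histopathological tumor: for each grossing
#' slab, one or more closed 2D polygons drawn by the pathologist, together
#' with the slab's position along the grossing axis and its thickness.
#' Polygons live in in-slice (u, v) coordinates; placement into 3D uses
#' `grossingAxis` and `inSliceBasis`.
#'
#' @slot grossingAxis numeric(3) unit vector, direction of the pathologist's
#'   cuts in the anatomical frame.
#' @slot inSliceBasis 2 x 3 numeric matrix; rows are the unit vectors that
#'   carry in-slice u and v to the anatomical frame.
#' @slot slices list of slices, each a list with elements `position` (mm along
#'   the grossing axis), `thickness` (mm) and `contours` (list of contours,
#'   each a list with `points`, an n x 2 matrix in mm without a repeated
#'   closing vertex, and logical `hole`).
#'
#' @seealso [ContourStack()], [interpolateSurface()], [validateStack()]
#' @export
setClass("ContourStack",
  representation(grossingAxis = "numeric", inSliceBasis = "matrix",
                 slices = "list"))

setValidity("ContourStack", function(object) {
  a <- object@grossingAxis
  if (length(a) != 3 || abs(sqrt(sum(a^2)) - 1) > 1e-8)
    return("grossingAxis must be a 3D unit vector")
  B <- object@inSliceBasis
  if (!all(dim(B) == c(2, 3))) return("inSliceBasis must be 2 x 3")
  if (max(abs(B %*% t(B) - diag(2))) > 1e-8)
    return("inSliceBasis rows must be orthonormal")
  if (max(abs(B %*% a)) > 1e-8)
    return("inSliceBasis must be orthogonal to grossingAxis")
  for (s in object@slices) {
    if (!is.list(s) || is.null(s$position) || is.null(s$thickness) ||
        is.null(s$contours))
      return("each slice needs position, thickness and contours")
  }
  # ordering/simplicity problems are reported by validateStack(), not blocked
  # here, so that defective stacks can be inspected
  TRUE
})

#' Binary MRI segmentation on an anisotropic voxel grid
#'
#' @slot voxels 3D array of 0/1 integers; index order follows the array axes.
#' @slot spacing numeric(3), voxel edge lengths in mm along the array axes
#'   (slice dimension typically 3-4 mm).
#' @slot origin numeric(3), anatomical-frame position (mm) of the centre of
#'   voxel (1, 1, 1).
#' @slot orientation 3 x 3 direction matrix; column j is the anatomical-frame
#'   unit vector along array axis j. `abs(det) == 1`.
#'
#' @seealso [LabelVolume()], [loadLabelVolume()], [maskToMesh()]
#' @export
setClass("LabelVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 orientation = "matrix"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@voxels)) != 3) return("voxels must be a 3D array")
  if (!all(object@voxels %in% c(0L, 1L))) return("voxels must be binary 0/1")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3 || !all(is.finite(object@origin)))
    return("origin must be a finite 3-vector (mm)")
  D <- object@orientation
  if (!all(dim(D) == c(3, 3))) return("orientation must be 3 x 3")
  if (abs(abs(det(D)) - 1) > 1e-6)
    return("orientation must have |det| = 1 (unit direction columns)")
  if (max(abs(t(D) %*% D - diag(3))) > 1e-6)
    return("orientation columns must be orthonormal")
  TRUE
})

#' Named anatomical fiducials in one frame
#'
#' Landmarks such as the tongue midline (supplied as two endpoint landmarks),
#' sublingual gland, palatal arch or palatine tonsil, marked with pins on the
#' specimen and with corresponding fiducials on the MRI model.
#' Correspondence between frames is by name only.
#'
#' @slot points numeric matrix (n x 3, mm) with unique rownames (the landmark
#'   names).
#' @slot frame character, `"mri"` or `"specimen"`.
#'
#' @seealso [LandmarkSet()], [fitLandmarkTransform()]
#' @export
setClass("LandmarkSet",
  representation(points = "matrix", frame = "character"))

setValidity("LandmarkSet", function(object) {
  p <- object@points
  if (ncol(p) != 3) return("points must have 3 columns")
  if (nrow(p) < 1) return("at least one landmark required")
  if (!all(is.finite(p))) return("landmark coordinates must be finite")
  nm <- rownames(p)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    return("points must have unique non-empty rownames")
  if (!object@frame %in% c("mri", "specimen"))
    return("frame must be 'mri' or 'specimen'")
  TRUE
})

#' Rigid (optionally similarity) transform between frames
#'
#' `x -> scale * rotation %*% x + translation`. The rotation is a proper
#' rotation (no reflection); scale is 1 unless shrinkage-style similarity
#' fitting was requested.
#'
#' @slot rotation 3 x 3 orthonormal matrix with det = +1.
#' @slot translation numeric(3), mm.
#' @slot scale positive scalar.
#'
#' @seealso [RigidTransform()], [fitLandmarkTransform()], [applyTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 scale = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
  if (max(abs(t(R) %*% R - diag(3))) > 1e-10)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-10)
    return("rotation must be proper (det = +1, no reflection)")
  if (length(object@translation) != 3) return("translation must be length 3")
  if (length(object@scale) != 1 || object@scale <= 0)
    return("scale must be a positive scalar")
  TRUE
})

#' Per-case and cohort fusion measurement report
#'
#' One row per case with the measured MRI and histopathological volumes,
#' directional extents, greatest MRI surface diameter, and the derived
#' comparison columns (difference, ratio, percent change), plus a summary
#' block with median and average of the volume-related columns.
#'
#' @slot rows data.frame, one row per case.
#' @slot summary data.frame with rows `"median"` and `"average"`.
#'
#' @seealso [buildReport()], [summarizeCohort()]
#' @export
setClass("FusionReport",
  representation(rows = "data.frame", summary = "data.frame"))

#' Fully synthetic specimen/tumor case with known ground truth
#'
#' All inputs the fusion pipeline consumes, generated from a seed, plus the
#' analytic/mesh-level truth the pipeline is judged against. Truth values are
#' computed from the ground-truth mesh, never from pipeline outputs.
#'
#' @slot specimenMesh,tumorMesh [TriangleMesh-class] bodies in the specimen
#'   frame; `tumorMesh` is the unshrunk ground-truth tumor.
#' @slot mriMask [LabelVolume-class], the tumor rasterized in the MRI frame.
#' @slot contourStack [ContourStack-class], grossing outlines of the (possibly
#'   shrunk) tumor in the specimen frame.
#' @slot landmarksMRI,landmarksSpecimen [LandmarkSet-class] fiducial pairs.
#' @slot truth list: volumes (cm^3), extents (cm), diameter (cm), the true
#'   MRI-to-specimen transform, shrinkage, and the seed.
#'
#' @seealso [generatePhantom()]
#' @export
setClass("PhantomCase",
  representation(specimenMesh = "TriangleMesh", tumorMesh = "TriangleMesh",
                 mriMask = "LabelVolume", contourStack = "ContourStack",
                 landmarksMRI = "LandmarkSet",
                 landmarksSpecimen = "LandmarkSet", truth = "list"))
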