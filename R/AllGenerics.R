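#' @rdname TriangleMesh-class
#' @param x,object a \linkS4class{TriangleMesh} (or other object).
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshName", function(x) standardGeneric("meshName"))

#' Watertightness of a triangulated surface
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces with consistent (opposite directed) orientation. Watertightness is a
#' precondition for divergence-theorem volume computation.
#'
#' @param x a \linkS4class{TriangleMesh}.
#' @return logical scalar.
#' @export
setGeneric("isWatertight", function(x) standardGeneric("isWatertight"))

#' Enclosed volume of a watertight mesh
#'
#' Signed-tetrahedron (divergence theorem) sum over faces, reported as an
#' absolute volume in cm^3 (vertices are mm, so mm^3 / 1000). Non-watertight
#' meshes are refused: the integral is meaningless on an open surface.
#'
#' @param x a watertight \linkS4class{TriangleMesh}.
#' @return volume in cm^3.
#' @examples
#' cube <- cubeMesh(10)
#' meshVolume(cube) # 1 cm^3
#' @export
setGeneric("meshVolume", function(x) standardGeneric("meshVolume"))

#' Extent of a mesh along an anatomical measurement axis
#'
#' Max minus min vertex coordinate along the named axis, in cm. Axes follow
#' the fixed anatomical frame: `"LR"` left-right, `"AP"`
#' anterior-posterior, `"CC"` cranial-caudal.
#'
#' @param x a non-empty \linkS4class{TriangleMesh}.
#' @param axis one of `"LR"`, `"AP"`, `"CC"`.
#' @return length in cm.
#' @export
setGeneric("directionalExtent",
           function(x, axis) standardGeneric("directionalExtent"))

#' Greatest distance between two points on a surface
#'
#' The largest tumor dimension: the maximum pairwise Euclidean distance over
#' surface points. The maximum is attained at convex-hull vertices, so it is
#' computed exactly on the hull (with an O(n^2) scan for small or degenerate
#' point sets).
#'
#' @param x a non-empty \linkS4class{TriangleMesh}.
#' @return length in cm.
#' @export
setGeneric("maxDiameter", function(x) standardGeneric("maxDiameter"))

#' Apply a rigid/similarity transform to an object
#'
#' Maps vertices (or points) by `scale * rotation %*% v + translation`.
#' Faces are unchanged; enclosed volume scales by `scale^3`.
#'
#' @param x a \linkS4class{TriangleMesh}, \linkS4class{LandmarkSet} or
#'   n x 3 point matrix.
#' @param transform a \linkS4class{RigidTransform}.
#' @return the transformed object, same class as `x`.
#' @export
setGeneric("applyTransform",
           function(x, transform) standardGeneric("applyTransform"))
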