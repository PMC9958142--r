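#' Accessors for shape objects
#'
#' \code{shapePoints} returns the n x 3 coordinate matrix, \code{meshFaces}
#' the 0-based face matrix, \code{regionLabels} the per-point tags (or NULL),
#' \code{shapeID} the identifier, \code{nPoints} the point count.
#'
#' @param x a \linkS4class{PointSet}, \linkS4class{TriMesh} or compatible
#'   object.
#' @return the requested component.
#' @aliases shapePoints meshFaces regionLabels shapeID nPoints
#' @export
setGeneric("shapePoints", function(x) standardGeneric("shapePoints"))

#' @rdname shapePoints
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname shapePoints
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname shapePoints
#' @export
setGeneric("shapeID", function(x) standardGeneric("shapeID"))

#' @rdname shapePoints
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' Apply a rigid transform to a shape
#'
#' Maps every point p to \code{scale * R p + t}; labels, faces and id are
#' preserved.
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @param shape a \linkS4class{PointSet}, \linkS4class{TriMesh}, numeric
#'   matrix, or \linkS4class{PedicleLandmarks}.
#' @return an object of the same class as \code{shape}.
#' @export
setGeneric("applyTransform",
           function(transform, shape) standardGeneric("applyTransform"))

setMethod("shapePoints", "PointSet", function(x) x@points)
setMethod("meshFaces", "TriMesh", function(x) x@faces)
setMethod("regionLabels", "PointSet",
          function(x) if (length(x@labels)) x@labels else NULL)
setMethod("shapeID", "PointSet", function(x) x@id)
setMethod("nPoints", "PointSet", function(x) nrow(x@points))

setMethod("show", "PointSet", function(object) {
  cat(sprintf("PointSet '%s': %d points (mm)%s\n",
              ifelse(is.na(object@id), "<unnamed>", object@id),
              nrow(object@points),
              if (length(object@labels)) ", labelled" else ""))
})

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh '%s': %d points, %d faces%s\n",
              ifelse(is.na(object@id), "<unnamed>", object@id),
              nrow(object@points), nrow(object@faces),
              if (length(object@labels)) ", labelled" else ""))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform: rotation %.3f deg, |t| = %.3f mm, scale %.6g\n",
              ang, sqrt(sum(object@translation^2)), object@scale))
})

setMethod("show", "CorrespondedPopulation", function(object) {
  cat(sprintf("CorrespondedPopulation: %d shapes x %d corresponded points\n",
              nrow(object@shapes), ncol(object@shapes) / 3L))
})

setMethod("show", "ShapeModel", function(object) {
  cat(sprintf("ShapeModel (%s, index=%s): %d points, %d modes, n_train=%d\n",
              object@method, object@index, length(object@mean) / 3L,
              ncol(object@modes), object@nTrain))
  k <- min(5L, ncol(object@modes))
  if (k)
    cat("  leading variance fractions:",
        paste(sprintf("%.3f", object@varianceFractions[seq_len(k)]),
              collapse = " "), "\n")
})

setMethod("show", "PedicleMeasurement", function(object) {
  cat(sprintf(paste0("PedicleMeasurement: width %.2f mm, height %.2f mm, ",
                     "transverse %.1f deg, sagittal %.1f deg\n"),
              object@width, object@height, object@transverseAngle,
              object@sagittalAngle))
})
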