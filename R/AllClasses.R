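#' @import methods
#' @importFrom stats rnorm runif sd mad var prcomp qnorm pnorm median
#' @importFrom utils read.csv write.csv head tail
NULL

REGION_LEVELS <- c("body", "pedicle_L", "pedicle_R", "lamina",
                   "transverse_process_L", "transverse_process_R",
                   "spinous_process", "other")

.checkPoints <- function(pts) {
  if (!is.matrix(pts) || ncol(pts) != 3L)
    return("points must be an n x 3 matrix")
  if (!all(is.finite(pts)))
    return("all coordinates must be finite")
  if (nrow(pts) < 4L)
    return("at least 4 points are required")
  ctr <- sweep(pts, 2L, colMeans(pts))
  s <- svd(ctr, nu = 0L, nv = 0L)$d
  if (s[2L] <= 1e-12 * max(s[1L], 1))
    return("points must not be collinear")
  TRUE
}

#' PointSet: an ordered 3D point cloud in millimetres
#'
#' The elementary shape representation: an ordered n x 3 coordinate matrix
#' (mm, right-handed axes), optionally carrying one anatomical region tag per
#' point and a free-text identifier. Point order is meaningful — index i names
#' the same location on every shape once dense correspondence is established.
#'
#' @slot points n x 3 numeric matrix of coordinates (mm).
#' @slot labels character vector of per-point region tags (length n), or
#'   length 0 when absent. Recognised tags: body, pedicle_L, pedicle_R,
#'   lamina, transverse_process_L, transverse_process_R, spinous_process,
#'   other.
#' @slot id free-text shape identifier.
#' @export
setClass("PointSet",
  representation(points = "matrix", labels = "character", id = "character"),
  prototype(labels = character(0), id = NA_character_),
  validity = function(object) {
    msg <- .checkPoints(object@points)
    if (!isTRUE(msg)) return(msg)
    if (length(object@labels) &&
        length(object@labels) != nrow(object@points))
      return("labels must have exactly one tag per point")
    TRUE
  })

#' TriMesh: a triangulated surface
#'
#' A \linkS4class{PointSet} plus triangle connectivity. Face indices are
#' 0-based internally regardless of file-format dialect. Faces may cover only
#' part of the vertex set (e.g. a template whose body is a faceless point
#' cloud while the posterior elements carry a grid triangulation).
#'
#' @slot faces f x 3 integer matrix of 0-based vertex indices.
#' @export
setClass("TriMesh", contains = "PointSet",
  representation(faces = "matrix"),
  prototype(faces = matrix(integer(0), 0L, 3L)),
  validity = function(object) {
    f <- object@faces
    if (ncol(f) != 3L) return("faces must be an f x 3 matrix")
    if (nrow(f)) {
      if (any(f < 0L) || any(f >= nrow(object@points)))
        return("face indices must be in [0, n_points)")
      if (any(f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]))
        return("degenerate faces (repeated vertex) are not allowed")
    }
    TRUE
  })

#' RigidTransform: a proper rigid-body (+ optional uniform scale) transform
#'
#' Maps a point p to \code{scale * R p + t}. Rotation is proper orthogonal
#' (det +1). Composition and inversion stay within the class.
#'
#' @slot rotation 3 x 3 proper orthogonal matrix.
#' @slot translation length-3 numeric (mm).
#' @slot scale positive scalar; 1 when scaling is disabled.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 scale = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0), scale = 1),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      return("rotation must be orthogonal (tol 1e-9)")
    if (abs(det(R) - 1) > 1e-9)
      return("rotation must be proper (det +1)")
    if (length(object@translation) != 3L)
      return("translation must have length 3")
    if (length(object@scale) != 1L || object@scale <= 0)
      return("scale must be a positive scalar")
    TRUE
  })

#' DeformationField: a Gaussian-kernel displacement field
#'
#' Displacement at x is \code{sum_j exp(-|x - c_j|^2 / (2 beta^2)) w_j} over
#' control points c_j — the coherent-motion parameterisation used by
#' non-rigid coherent point drift.
#'
#' @slot controlPoints k x 3 matrix of control-point coordinates (mm).
#' @slot coefficients k x 3 matrix of kernel coefficients.
#' @slot beta Gaussian kernel width (mm).
#' @export
setClass("DeformationField",
  representation(controlPoints = "matrix", coefficients = "matrix",
                 beta = "numeric"),
  validity = function(object) {
    if (nrow(object@controlPoints) != nrow(object@coefficients))
      return("coefficient count must equal control point count")
    if (!all(is.finite(object@coefficients)))
      return("coefficients must be finite")
    if (object@beta <= 0) return("beta must be positive")
    TRUE
  })

#' CorrespondenceMap: dense template-to-sample correspondence for one shape
#'
#' For each template point, the coordinates of its corresponding location on
#' or near the sample, with the per-point residual distance to the sample.
#'
#' @slot coordinates m x 3 matrix: image of template point i on the sample.
#' @slot residuals length-m non-negative distances (mm).
#' @export
setClass("CorrespondenceMap",
  representation(coordinates = "matrix", residuals = "numeric"),
  validity = function(object) {
    if (nrow(object@coordinates) != length(object@residuals))
      return("one residual per template point is required")
    if (any(object@residuals < 0)) return("residuals must be non-negative")
    TRUE
  })

#' CorrespondedPopulation: n shapes in dense correspondence
#'
#' The data matrix behind the shape model: one row per shape, flattened as
#' (x1, y1, z1, ..., xm, ym, zm).
#'
#' @slot shapes n x 3m numeric matrix of shape-vectors (mm).
#' @slot ids per-shape identifiers (length n).
#' @slot templatePoints m x 3 template coordinates (may be 0-row when the
#'   population was assembled without an explicit template).
#' @slot templateFaces optional template faces (0-based).
#' @slot labels optional per-point region tags (length m or 0).
#' @export
setClass("CorrespondedPopulation",
  representation(shapes = "matrix", ids = "character",
                 templatePoints = "matrix", templateFaces = "matrix",
                 labels = "character"),
  prototype(templatePoints = matrix(numeric(0), 0L, 3L),
            templateFaces = matrix(integer(0), 0L, 3L),
            labels = character(0)),
  validity = function(object) {
    if (ncol(object@shapes) %% 3L != 0L)
      return("shape-vector length must be a multiple of 3")
    if (length(object@ids) != nrow(object@shapes))
      return("one id per shape is required")
    m <- ncol(object@shapes) / 3L
    if (nrow(object@templatePoints) && nrow(object@templatePoints) != m)
      return("template point count must match shape-vector length")
    if (length(object@labels) && length(object@labels) != m)
      return("labels must have one tag per corresponded point")
    TRUE
  })

#' ShapeModel: mean shape plus orthonormal modes of variation
#'
#' A linear statistical shape model: shapes are synthesised as
#' \code{mean + sum_k b_k sd_k mode_k} with b in SD units. Modes are
#' orthonormal columns, sorted by non-increasing scale.
#'
#' @slot mean length-3m mean shape-vector (mm).
#' @slot modes 3m x K matrix with orthonormal columns.
#' @slot sd K per-mode scales (mm along the unit mode), non-increasing.
#' @slot varianceFractions K fractions of total (index-dependent) variance,
#'   summing to 1.
#' @slot nTrain number of training shapes.
#' @slot method "pp_pca" or "classical_pca".
#' @slot index projection index used by ppPCA ("variance", "mad", "qn").
#' @slot templateFaces optional faces for surface rendering.
#' @slot labels optional per-point region tags.
#' @slot degenerate TRUE when the training data had zero variance.
#' @export
setClass("ShapeModel",
  representation(mean = "numeric", modes = "matrix", sd = "numeric",
                 varianceFractions = "numeric", nTrain = "integer",
                 method = "character", index = "character",
                 templateFaces = "matrix", labels = "character",
                 degenerate = "logical"),
  prototype(templateFaces = matrix(integer(0), 0L, 3L),
            labels = character(0), degenerate = FALSE,
            method = "pp_pca", index = "variance"),
  validity = function(object) {
    K <- ncol(object@modes)
    if (length(object@sd) != K || length(object@varianceFractions) != K)
      return("sd and varianceFractions must have one entry per mode")
    if (K) {
      if (nrow(object@modes) != length(object@mean))
        return("mode rows must match mean length")
      if (max(abs(crossprod(object@modes) - diag(K))) > 1e-8)
        return("modes must be orthonormal (tol 1e-8)")
      if (any(diff(object@sd) > 1e-12))
        return("sd must be sorted non-increasing")
      if (any(object@sd < 0)) return("sd must be non-negative")
      if (any(object@varianceFractions < -1e-12))
        return("variance fractions must be non-negative")
      if (abs(sum(object@varianceFractions) - 1) > 1e-8 &&
          !object@degenerate)
        return("variance fractions must sum to 1 (tol 1e-8)")
      if (K > object@nTrain - 1L)
        return("number of modes must not exceed n_train - 1")
    }
    if (length(object@mean) %% 3L != 0L)
      return("mean length must be a multiple of 3")
    TRUE
  })

#' DistanceMap: per-vertex distances between a synthesised shape and the mean
#'
#' @slot values one scalar per template point (mm); non-negative when
#'   unsigned.
#' @slot signed whether values carry an outward/inward sign.
#' @slot pcIndex principal component the map belongs to (NA for ad hoc maps).
#' @slot sdOffset offset along the component in SD units.
#' @export
setClass("DistanceMap",
  representation(values = "numeric", signed = "logical",
                 pcIndex = "integer", sdOffset = "numeric"),
  prototype(signed = FALSE, pcIndex = NA_integer_, sdOffset = NA_real_),
  validity = function(object) {
    if (!object@signed && any(object@values < 0))
      return("unsigned map values must be non-negative")
    TRUE
  })

#' PedicleLandmarks: the landmark set of the screw-trajectory protocol
#'
#' Margins of the pedicle cross-section, three points on the superior
#' endplate, the anterior body / posterior spinous extremes defining the
#' midline, and a target point anterior to the pedicle along its canal axis.
#'
#' @slot superior,inferior,lateral,medial pedicle margin points (mm).
#' @slot endplate 3 x 3 matrix; rows are the three endplate surface points.
#' @slot anteriorBody most anterior point of the vertebral body.
#' @slot posteriorSpinous most posterior point of the spinous process.
#' @slot axisTarget point anterior to the pedicle along its canal axis.
#' @slot side "left" or "right".
#' @export
setClass("PedicleLandmarks",
  representation(superior = "numeric", inferior = "numeric",
                 lateral = "numeric", medial = "numeric",
                 endplate = "matrix", anteriorBody = "numeric",
                 posteriorSpinous = "numeric", axisTarget = "numeric",
                 side = "character"),
  validity = function(object) {
    p3 <- function(x) length(x) == 3L && all(is.finite(x))
    for (s in c("superior", "inferior", "lateral", "medial",
                "anteriorBody", "posteriorSpinous", "axisTarget"))
      if (!p3(slot(object, s))) return(sprintf("%s must be a finite 3-vector", s))
    marg <- rbind(object@superior, object@inferior, object@lateral,
                  object@medial)
    if (anyDuplicated(marg)) return("pedicle margins must be distinct")
    if (.collinear(marg)) return("pedicle margins must not be collinear")
    if (!all(dim(object@endplate) == c(3L, 3L)))
      return("endplate must be a 3 x 3 matrix of points")
    if (.collinear(object@endplate))
      return("endplate points must not be collinear")
    if (isTRUE(all(object@anteriorBody == object@posteriorSpinous)))
      return("anteriorBody and posteriorSpinous must differ")
    if (!object@side %in% c("left", "right"))
      return("side must be 'left' or 'right'")
    TRUE
  })

.collinear <- function(pts) {
  ctr <- sweep(pts, 2L, colMeans(pts))
  s <- svd(ctr, nu = 0L, nv = 0L)$d
  s[2L] <= 1e-9 * max(s[1L], 1)
}

#' PedicleMeasurement: the four screw-planning dimensions
#'
#' @slot width medial-lateral pedicle extent (mm).
#' @slot height superior-inferior pedicle extent (mm).
#' @slot transverseAngle angle in the endplate plane between the pedicle axis
#'   projection and the midline (degrees, unsigned, 0-90).
#' @slot sagittalAngle elevation of the pedicle axis from the endplate plane
#'   (degrees, unsigned, 0-90).
#' @slot repeatError named half-ranges over repeats (width, height,
#'   transverseAngle, sagittalAngle); NA when not aggregated.
#' @export
setClass("PedicleMeasurement",
  representation(width = "numeric", height = "numeric",
                 transverseAngle = "numeric", sagittalAngle = "numeric",
                 repeatError = "numeric"),
  prototype(repeatError = c(width = NA_real_, height = NA_real_,
                            transverseAngle = NA_real_,
                            sagittalAngle = NA_real_)),
  validity = function(object) {
    if (object@width <= 0 || object@height <= 0)
      return("width and height must be positive")
    for (a in c(object@transverseAngle, object@sagittalAngle))
      if (a < 0 || a > 90) return("angles must lie in [0, 90] degrees")
    TRUE
  })

#' SyntheticSpec: parameters of the synthetic vertebra population generator
#'
#' See \code{\link{syntheticSpec}} for the user constructor and parameter
#' semantics.
#'
#' @slot params named numeric vector of template geometry parameters (mm /
#'   degrees).
#' @slot modes list of planted modes; each a list(name, parameter, sd) where
#'   sd is mm along the unit shape-space mode direction.
#' @slot noiseSD RMS 3D perturbation per point (mm).
#' @slot nShapes number of shapes (per level).
#' @slot nLevels number of vertebral levels sharing the modes (level-specific
#'   mean offsets applied to the body size).
#' @slot pointsPerShape points per generated shape.
#' @slot seed integer seed.
#' @slot scramble "none", "rigid", or "rigid+permute".
#' @export
setClass("SyntheticSpec",
  representation(params = "numeric", modes = "list", noiseSD = "numeric",
                 nShapes = "integer", nLevels = "integer",
                 pointsPerShape = "integer", seed = "integer",
                 scramble = "character"),
  validity = function(object) {
    geom <- object@params[setdiff(names(object@params),
                                  c("transverse_angle", "sagittal_angle"))]
    if (any(geom <= 0))
      return("all template dimensions must be positive")
    if (object@params["pedicle_radius_w"] >= object@params["body_axis_y"])
      return("pedicle radius must be smaller than the body half-width")
    for (md in object@modes) {
      if (!all(c("name", "parameter", "sd") %in% names(md)))
        return("each mode needs name, parameter, sd")
      if (md$sd <= 0) return("mode sds must be positive")
      if (!md$parameter %in% names(object@params))
        return(sprintf("unknown mode parameter '%s'", md$parameter))
    }
    if (object@noiseSD < 0) return("noiseSD must be non-negative")
    if (object@nShapes < 1L) return("nShapes must be >= 1")
    if (object@pointsPerShape < 50L)
      return("pointsPerShape must be >= 50")
    if (!object@scramble %in% c("none", "rigid", "rigid+permute"))
      return("scramble must be none, rigid or rigid+permute")
    TRUE
  })

#' GroundTruth: everything the generator knows about its population
#'
#' Recorded pre-scramble, so every pipeline stage can be scored against it.
#'
#' @slot weights n x K matrix of standard-normal mode weights (SD units).
#' @slot sds planted per-mode effective shape-space scales (mm along the
#'   unit mode direction; the per-point sd times the square root of
#'   the mode's support size).
#' @slot modeDirections 3m x K orthonormal planted shape-space modes.
#' @slot cleanMatrix n x 3m noise-free corresponded shape matrix.
#' @slot paramValues n x P matrix of effective template parameters per shape.
#' @slot poses list of applied \linkS4class{RigidTransform}s (identity when
#'   unscrambled).
#' @slot permutations list of applied vertex permutations (or NULL entries).
#' @slot labels per-point region tags of the template.
#' @slot templatePoints m x 3 template coordinates.
#' @export
setClass("GroundTruth",
  representation(weights = "matrix", sds = "numeric",
                 modeDirections = "matrix", cleanMatrix = "matrix",
                 paramValues = "matrix", poses = "list",
                 permutations = "list", labels = "character",
                 templatePoints = "matrix"),
  validity = function(object) {
    if (nrow(object@weights) != nrow(object@cleanMatrix))
      return("weights must have one row per shape")
    if (ncol(object@weights) != length(object@sds))
      return("weights must have one column per mode")
    TRUE
  })
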