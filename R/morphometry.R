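## Pedicle screw trajectory morphometry. From the landmark set (pedicle
## margins, endplate triplet, midline extremes, axis target) the four
## surgical-planning dimensions are derived: pedicle width and height
## (margin-to-margin distances), the transverse pedicle angle (between the
## pedicle axis projected into the endplate plane and the vertebral
## midline), and the sagittal pedicle angle (elevation of the axis from the
## plane). All angles are unsigned, in [0, 90] degrees, and every
## measurement is invariant under a common rigid transform of the
## landmarks.

#' Construct a PedicleLandmarks object
#'
#' @param superior,inferior,lateral,medial pedicle margin points (mm).
#' @param endplate three points on the superior endplate (3 x 3 matrix or
#'   list of 3-vectors).
#' @param anteriorBody most anterior point of the vertebral body.
#' @param posteriorSpinous most posterior point of the spinous process.
#' @param axisTarget a point anterior to the pedicle along its canal axis.
#' @param side "left" or "right".
#' @return a \linkS4class{PedicleLandmarks}.
#' @export
pedicleLandmarks <- function(superior, inferior, lateral, medial, endplate,
                             anteriorBody, posteriorSpinous, axisTarget,
                             side = "left") {
  if (is.list(endplate)) endplate <- do.call(rbind, endplate)
  new("PedicleLandmarks",
      superior = as.numeric(superior), inferior = as.numeric(inferior),
      lateral = as.numeric(lateral), medial = as.numeric(medial),
      endplate = endplate, anteriorBody = as.numeric(anteriorBody),
      posteriorSpinous = as.numeric(posteriorSpinous),
      axisTarget = as.numeric(axisTarget), side = side)
}

#' Pedicle width and height
#'
#' Width is the medial-lateral margin distance; height the
#' superior-inferior margin distance (mm). Both are symmetric in their
#' point pair.
#'
#' @param l a \linkS4class{PedicleLandmarks}.
#' @return distance in mm.
#' @export
pedicleWidth <- function(l) sqrt(sum((l@medial - l@lateral)^2))

#' @rdname pedicleWidth
#' @export
pedicleHeight <- function(l) sqrt(sum((l@superior - l@inferior)^2))

#' Superior endplate plane
#'
#' The plane through the three endplate points, with the unit normal
#' oriented toward the superior pedicle margin (cranial side).
#'
#' @param l a \linkS4class{PedicleLandmarks}.
#' @return a list with \code{normal} (unit 3-vector) and \code{offset}
#'   (so that \code{normal . x = offset} on the plane).
#' @export
endplatePlane <- function(l) {
  e <- l@endplate
  n <- .cross3(e[2L, ] - e[1L, ], e[3L, ] - e[1L, ])
  len <- sqrt(sum(n^2))
  if (len < 1e-12) stop("endplate points are collinear")
  n <- n / len
  if (sum(n * (l@superior - e[1L, ])) < 0) n <- -n
  list(normal = n, offset = sum(n * e[1L, ]))
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.projectToPlane <- function(p, plane) {
  p - (sum(plane$normal * p) - plane$offset) * plane$normal
}

#' Vertebral midline direction in the endplate plane
#'
#' Projects the anterior-body and posterior-spinous extremes onto the
#' endplate plane; the midline is the unit posterior-to-anterior vector
#' between the projections.
#'
#' @param l a \linkS4class{PedicleLandmarks}.
#' @param plane an \code{\link{endplatePlane}} result.
#' @return unit 3-vector in the plane.
#' @export
midlineDirection <- function(l, plane = endplatePlane(l)) {
  a <- .projectToPlane(l@anteriorBody, plane)
  p <- .projectToPlane(l@posteriorSpinous, plane)
  d <- a - p
  len <- sqrt(sum(d^2))
  if (len < 1e-9)
    stop("midline undefined: projected extremes coincide")
  d / len
}

#' Pedicle axis line
#'
#' The line through the centroid of the four margin points, directed toward
#' the axis target (the manual cross-section construction is supplied as a
#' landmark contract: the target point sits anterior to the pedicle along
#' its canal).
#'
#' @param l a \linkS4class{PedicleLandmarks}.
#' @return a list with \code{point} (margin centroid) and \code{direction}
#'   (unit 3-vector).
#' @export
pedicleAxis <- function(l) {
  ctr <- colMeans(rbind(l@superior, l@inferior, l@lateral, l@medial))
  d <- l@axisTarget - ctr
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("axis target coincides with the margin centroid")
  list(point = ctr, direction = d / len)
}

#' Transverse pedicle angle
#'
#' The angle, within the endplate plane, between the pedicle axis
#' projection and the midline; unsigned, in [0, 90] degrees.
#'
#' @param axis a \code{\link{pedicleAxis}} result.
#' @param midline a \code{\link{midlineDirection}} result.
#' @param plane an \code{\link{endplatePlane}} result.
#' @return angle in degrees.
#' @export
transverseAngle <- function(axis, midline, plane) {
  proj <- axis$direction - sum(axis$direction * plane$normal) * plane$normal
  len <- sqrt(sum(proj^2))
  if (len < 1e-9)
    stop("transverse angle undefined: pedicle axis is perpendicular to ",
         "the endplate plane")
  proj <- proj / len
  acos(min(1, abs(sum(proj * midline)))) * 180 / pi
}

#' Sagittal pedicle angle
#'
#' The elevation of the pedicle axis from the endplate plane; unsigned, in
#' [0, 90] degrees.
#'
#' @param axis a \code{\link{pedicleAxis}} result.
#' @param plane an \code{\link{endplatePlane}} result.
#' @return angle in degrees.
#' @export
sagittalAngle <- function(axis, plane) {
  asin(min(1, abs(sum(axis$direction * plane$normal)))) * 180 / pi
}

#' Measure all four pedicle dimensions from landmarks
#'
#' @param l a \linkS4class{PedicleLandmarks}.
#' @return a \linkS4class{PedicleMeasurement}.
#' @export
measurePedicle <- function(l) {
  plane <- endplatePlane(l)
  axis <- pedicleAxis(l)
  mid <- midlineDirection(l, plane)
  new("PedicleMeasurement",
      width = pedicleWidth(l), height = pedicleHeight(l),
      transverseAngle = transverseAngle(axis, mid, plane),
      sagittalAngle = sagittalAngle(axis, plane))
}

#' Aggregate repeated measurements
#'
#' Per dimension: the mean over repeats, with the repeat error recorded as
#' half the range (max - min) / 2 — the protocol of repeating the landmark
#' selection three times and averaging.
#'
#' @param measurements list of >= 2 \linkS4class{PedicleMeasurement}s.
#' @return a \linkS4class{PedicleMeasurement} with \code{repeatError}
#'   filled in.
#' @export
aggregateRepeats <- function(measurements) {
  if (length(measurements) < 2L)
    stop("at least 2 repeats are required")
  g <- function(s) vapply(measurements, slot, numeric(1), s)
  dims <- c("width", "height", "transverseAngle", "sagittalAngle")
  vals <- lapply(dims, g)
  names(vals) <- dims
  err <- vapply(vals, function(v) (max(v) - min(v)) / 2, numeric(1))
  new("PedicleMeasurement",
      width = mean(vals$width), height = mean(vals$height),
      transverseAngle = mean(vals$transverseAngle),
      sagittalAngle = mean(vals$sagittalAngle),
      repeatError = err)
}

#' Guide envelope: per-dimension range over a measurement table
#'
#' The min/max over all table entries per dimension — the range a
#' standardised guide set must accommodate (e.g. the recommended
#' transverse-angle coverage derived from the per-PC, per-offset
#' measurement table).
#'
#' @param table a data.frame with a \code{dimension} column and a
#'   \code{value} column (long format: one row per PC x offset entry), or a
#'   numeric matrix/data.frame whose rows are dimensions and columns
#'   entries.
#' @return a data.frame with columns dimension, min, max.
#' @export
guideEnvelope <- function(table) {
  if (is.data.frame(table) && all(c("dimension", "value") %in%
                                  names(table))) {
    dims <- unique(table$dimension)
    out <- data.frame(
      dimension = dims,
      min = vapply(dims, function(d)
        min(table$value[table$dimension == d]), numeric(1)),
      max = vapply(dims, function(d)
        max(table$value[table$dimension == d]), numeric(1)),
      row.names = NULL)
    return(out)
  }
  M <- as.matrix(table)
  if (!length(M)) stop("empty measurement table")
  data.frame(dimension = rownames(M), min = apply(M, 1L, min),
             max = apply(M, 1L, max), row.names = NULL)
}

#' Read / write landmark files
#'
#' Landmarks are exchanged as CSV with columns \code{name, x, y, z} (one
#' row per named point: superior, inferior, lateral, medial,
#' endplate_1..3, anterior_body, posterior_spinous, axis_target) plus an
#' optional \code{side} row, or as JSON with the same named points.
#'
#' @param path CSV file.
#' @return a \linkS4class{PedicleLandmarks}.
#' @export
readLandmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("superior", "inferior", "lateral", "medial", "endplate_1",
            "endplate_2", "endplate_3", "anterior_body",
            "posterior_spinous", "axis_target")
  missing <- setdiff(need, df$name)
  if (length(missing))
    stop("landmark file lacks points: ", paste(missing, collapse = ", "))
  gp <- function(nm) as.numeric(df[df$name == nm, c("x", "y", "z")][1L, ])
  side <- if ("side" %in% names(df) && !all(is.na(df$side)))
    stats::na.omit(df$side)[1L] else "left"
  pedicleLandmarks(gp("superior"), gp("inferior"), gp("lateral"),
                   gp("medial"),
                   rbind(gp("endplate_1"), gp("endplate_2"),
                         gp("endplate_3")),
                   gp("anterior_body"), gp("posterior_spinous"),
                   gp("axis_target"), side = side)
}

#' @rdname readLandmarks
#' @param l a \linkS4class{PedicleLandmarks}.
#' @export
writeLandmarks <- function(l, path) {
  pts <- rbind(superior = l@superior, inferior = l@inferior,
               lateral = l@lateral, medial = l@medial,
               endplate_1 = l@endplate[1L, ],
               endplate_2 = l@endplate[2L, ],
               endplate_3 = l@endplate[3L, ],
               anterior_body = l@anteriorBody,
               posterior_spinous = l@posteriorSpinous,
               axis_target = l@axisTarget)
  df <- data.frame(name = rownames(pts), x = pts[, 1L], y = pts[, 2L],
                   z = pts[, 3L], side = l@side)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Measure pedicle dimensions along model components
#'
#' Reproduces the measurement-table layout (dimension x PC x SD offset)
#' from a shape model and a landmark extractor: for each retained component
#' and offset the shape is synthesised and measured.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param landmarkFun function(PointSet) returning
#'   \linkS4class{PedicleLandmarks} for a synthesised shape (e.g. carrying
#'   template landmark indices through the correspondence).
#' @param retained component indices (default
#'   \code{selectComponents(model)}).
#' @param offsets SD offsets, default +3..-3.
#' @return a long-format data.frame with columns pc, sd_offset, dimension,
#'   value.
#' @export
measureAlongComponents <- function(model, landmarkFun,
                                   retained = selectComponents(model),
                                   offsets = c(3, 2, 1, 0, -1, -2, -3)) {
  rows <- list()
  for (k in retained) {
    for (off in offsets) {
      s <- synthesizeShape(model, weights = off, pc = k)
      meas <- measurePedicle(landmarkFun(s))
      rows[[length(rows) + 1L]] <- data.frame(
        pc = k, sd_offset = off,
        dimension = c("pedicle_width", "pedicle_height",
                      "transverse_angle", "sagittal_angle"),
        value = c(meas@width, meas@height, meas@transverseAngle,
                  meas@sagittalAngle))
    }
  }
  do.call(rbind, rows)
}
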