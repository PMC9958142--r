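## Synthetic vertebra populations with known ground truth. The template is
## assembled from analytic primitives — an ellipsoidal body, two elliptic-
## cylinder pedicles at specified transverse/sagittal angles, a posterior
## lamina arch, two transverse processes and a spinous process — sampled by
## a fixed deterministic pattern, so two templates built at different
## parameter values are in exact point-to-point correspondence. Every
## coordinate is an affine function of each size parameter, so planted
## modes acting on size parameters are exact linear directions in shape
## space; modes with disjoint regional support are exactly orthogonal and
## every landmark-derived measurement has a closed form.
##
## Axes: +x anterior, +y left, +z superior; units mm.

#' Specify a synthetic vertebra population
#'
#' The default template echoes mid-thoracic proportions (pedicle width
#' 5.6 mm, height 10.5 mm, transverse angle 8.8 deg, sagittal angle
#' 14.2 deg at the mean) and ~2000 surface points per shape. Planted modes
#' perturb one template parameter each; \code{sd} is the mode's standard
#' deviation expressed as mm RMS displacement per affected point (the
#' scale on which regional variability is reported; the effective
#' shape-space scale is \code{sd * sqrt(support size)}). The default
#' three modes scale the transverse processes, the spinous process and
#' the pedicle width: regionally disjoint (hence exactly orthogonal) and
#' with equal support sizes, so planted variance fractions are exactly
#' \code{sd^2 / sum(sd^2)}.
#'
#' @param nShapes shapes per level.
#' @param nLevels vertebral levels pooled into the population (each level
#'   applies a small fixed offset to the body half-axes; ids are prefixed
#'   \code{L<level>_}).
#' @param pointsPerShape surface points per shape.
#' @param modes list of modes, each \code{list(name, parameter, sd)};
#'   parameters must name entries of \code{params}.
#' @param noiseSD RMS 3D perturbation per point (mm); applied as isotropic
#'   Gaussian noise with per-coordinate sd \code{noiseSD/sqrt(3)}.
#' @param seed integer root seed.
#' @param scramble \code{"none"} (shapes stay in template vertex order and
#'   pose), \code{"rigid"} (random pose per shape), or
#'   \code{"rigid+permute"} (random pose and random vertex order).
#' @param params named overrides of the template geometry (see Details).
#' @details Template parameters (mm / degrees): body_axis_x/y/z (ellipsoid
#'   half-axes), pedicle_radius_w, pedicle_radius_h, pedicle_length,
#'   transverse_angle, sagittal_angle, lamina_thickness,
#'   transverse_process_length, spinous_process_length.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nShapes = 90L, nLevels = 1L,
                          pointsPerShape = 2000L,
                          modes = defaultModes(), noiseSD = 0.05,
                          seed = 1L, scramble = "none",
                          params = c()) {
  p <- c(body_axis_x = 10, body_axis_y = 14, body_axis_z = 9,
         pedicle_radius_w = 2.8, pedicle_radius_h = 5.25,
         pedicle_length = 10, transverse_angle = 8.8,
         sagittal_angle = 14.2, lamina_thickness = 4,
         transverse_process_length = 15, spinous_process_length = 20)
  if (length(params)) {
    unknown <- setdiff(names(params), names(p))
    if (length(unknown))
      stop("unknown template parameters: ",
           paste(unknown, collapse = ", "))
    p[names(params)] <- params
  }
  new("SyntheticSpec", params = p, modes = modes,
      noiseSD = as.numeric(noiseSD), nShapes = as.integer(nShapes),
      nLevels = as.integer(nLevels),
      pointsPerShape = as.integer(pointsPerShape), seed = as.integer(seed),
      scramble = scramble)
}

#' @rdname syntheticSpec
#' @param sds per-mode scales (mm RMS per affected point) for the three
#'   default modes.
#' @export
defaultModes <- function(sds = c(3, 2, 1)) {
  stopifnot(length(sds) == 3L)
  list(list(name = "transverse_process_growth",
            parameter = "transverse_process_length", sd = sds[1L]),
       list(name = "spinous_process_growth",
            parameter = "spinous_process_length", sd = sds[2L]),
       list(name = "pedicle_widening",
            parameter = "pedicle_radius_w", sd = sds[3L]))
}

## golden-spiral sampling of n points on a unit sphere (deterministic)
.goldenSphere <- function(n) {
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  r <- sqrt(pmax(0, 1 - z * z))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

## grid triangulation helper: points indexed p[(a-1)*nb + b], a=1..na rows,
## b=1..nb columns; wrap joins column nb back to column 1
.gridFaces <- function(na, nb, wrap = FALSE, offset = 0L) {
  fs <- list()
  bmax <- if (wrap) nb else nb - 1L
  for (a in seq_len(na - 1L)) {
    for (b in seq_len(bmax)) {
      b2 <- if (b == nb) 1L else b + 1L
      i00 <- (a - 1L) * nb + b; i01 <- (a - 1L) * nb + b2
      i10 <- a * nb + b; i11 <- a * nb + b2
      fs[[length(fs) + 1L]] <- rbind(c(i00, i10, i11), c(i00, i11, i01))
    }
  }
  (do.call(rbind, fs) - 1L) + offset
}

## pedicle frame for one side (s = +1 left, -1 right): unit axis direction
## pointing anteriorly into the body, and the in-plane cross-section axes
.pedicleFrame <- function(p, s) {
  tau <- p[["transverse_angle"]] * pi / 180
  zeta <- p[["sagittal_angle"]] * pi / 180
  d <- c(cos(zeta) * cos(tau), -s * cos(zeta) * sin(tau), sin(zeta))
  u2 <- .cross3(d, c(0, 0, 1))          # medial-lateral cross axis
  u2 <- u2 / sqrt(sum(u2^2))
  u1 <- .cross3(u2, d)                  # superior-inferior cross axis
  u1 <- u1 / sqrt(sum(u1^2))
  waist <- c(-p[["body_axis_x"]] - 4, s * 8, 1)
  list(d = d, u1 = u1, u2 = u2, waist = waist)
}

## all template geometry in one place; returns points, labels, faces
.templateGeometry <- function(p, nPoints) {
  stopifnot(nPoints >= 50L)
  ## the three default mode regions (pedicle pair, transverse-process
  ## pair, spinous process) get equal point counts, so the default planted
  ## modes have equal shape-space support
  nTPr <- 8L
  nPed <- max(24L, round(0.07 * nPoints / 8) * 8)
  nTP <- nPed
  nSPr <- 8L
  nSP <- 2L * nPed
  nLamZ <- 6L
  nLam <- max(24L, round(0.13 * nPoints / nLamZ) * nLamZ)
  nBody <- nPoints - 2L * nPed - 2L * nTP - nSP - nLam
  if (nBody < 10L) stop("pointsPerShape too small for the region layout")

  pts <- list(); labs <- list(); faces <- list()
  addGrid <- function(P, label, fc) {
    off <- sum(vapply(pts, nrow, 1L))
    pts[[length(pts) + 1L]] <<- P
    labs[[length(labs) + 1L]] <<- rep(label, nrow(P))
    if (!is.null(fc)) faces[[length(faces) + 1L]] <- fc + off
    faces <<- faces
  }

  ## vertebral body: ellipsoid, golden-spiral sampled, faceless
  sph <- .goldenSphere(nBody)
  body <- cbind(p[["body_axis_x"]] * sph[, 1L],
                p[["body_axis_y"]] * sph[, 2L],
                p[["body_axis_z"]] * sph[, 3L])
  addGrid(body, "body", NULL)

  ## pedicles: elliptic cylinders along the angled axis; circumference
  ## angles avoid the cross-axis zeros so the width-radius mode touches
  ## every pedicle point
  nt <- nPed %/% 8L
  for (s in c(1, -1)) {
    fr <- .pedicleFrame(p, s)
    tv <- seq(-0.5, 0.5, length.out = nt)
    av <- seq(0, 2 * pi, length.out = 9L)[-9L] + pi / 8
    P <- matrix(0, nt * 8L, 3L)
    k <- 0L
    for (t in tv) for (a in av) {
      k <- k + 1L
      P[k, ] <- fr$waist + t * p[["pedicle_length"]] * fr$d +
        p[["pedicle_radius_w"]] * cos(a) * fr$u2 +
        p[["pedicle_radius_h"]] * sin(a) * fr$u1
    }
    addGrid(P, if (s > 0) "pedicle_L" else "pedicle_R",
            .gridFaces(nt, 8L, wrap = TRUE))
  }

  ## lamina: posterior arch segment of a cylindrical shell around the canal
  canalC <- c(-p[["body_axis_x"]] - 7, 0, 0)
  nA <- nLam %/% nLamZ
  alphas <- seq(-70, 70, length.out = nA) * pi / 180
  zs <- seq(-6, 6, length.out = nLamZ)
  Rl <- 7 + 0.5 * p[["lamina_thickness"]]
  P <- matrix(0, nA * nLamZ, 3L)
  k <- 0L
  for (a in alphas) for (z in zs) {
    k <- k + 1L
    P[k, ] <- canalC + c(-Rl * cos(a), Rl * sin(a), z)
  }
  addGrid(P, "lamina", .gridFaces(nA, nLamZ, wrap = FALSE))

  ## transverse processes: thin cylinders pointing laterally
  ntt <- nTP %/% nTPr
  for (s in c(1, -1)) {
    dirT <- c(-0.30, s * 0.95, 0.12)
    dirT <- dirT / sqrt(sum(dirT^2))
    base <- c(-p[["body_axis_x"]] - 5, s * 10, 2)
    e2 <- .cross3(dirT, c(0, 0, 1)); e2 <- e2 / sqrt(sum(e2^2))
    e1 <- .cross3(e2, dirT)
    ## t starts off zero so every process point responds to the length
    ## parameter (equal mode support across the default mode regions)
    tv <- seq(1 / ntt, 1, length.out = ntt)
    av <- seq(0, 2 * pi, length.out = nTPr + 1L)[-(nTPr + 1L)]
    P <- matrix(0, ntt * nTPr, 3L)
    k <- 0L
    for (t in tv) for (a in av) {
      k <- k + 1L
      P[k, ] <- base + t * p[["transverse_process_length"]] * dirT +
        2 * cos(a) * e2 + 2 * sin(a) * e1
    }
    addGrid(P, if (s > 0) "transverse_process_L" else
      "transverse_process_R", .gridFaces(ntt, nTPr, wrap = TRUE))
  }

  ## spinous process: cylinder pointing posterior-inferior in the midplane
  dirS <- c(-cos(35 * pi / 180), 0, -sin(35 * pi / 180))
  baseS <- c(-p[["body_axis_x"]] - 13, 0, -1)
  e2 <- c(0, 1, 0); e1 <- .cross3(e2, dirS)
  nts <- nSP %/% nSPr
  tv <- seq(1 / nts, 1, length.out = nts)
  av <- seq(0, 2 * pi, length.out = nSPr + 1L)[-(nSPr + 1L)]
  P <- matrix(0, nts * nSPr, 3L)
  k <- 0L
  for (t in tv) for (a in av) {
    k <- k + 1L
    P[k, ] <- baseS + t * p[["spinous_process_length"]] * dirS +
      2.2 * cos(a) * e2 + 2.2 * sin(a) * e1
  }
  addGrid(P, "spinous_process", .gridFaces(nts, nSPr, wrap = TRUE))

  list(points = do.call(rbind, pts), labels = unlist(labs),
       faces = if (length(faces)) do.call(rbind, faces) else
         matrix(integer(0), 0L, 3L))
}

## analytic landmark set as a function of the parameters (affine in every
## size parameter)
.templateLandmarks <- function(p, side = "left") {
  s <- if (side == "left") 1 else -1
  fr <- .pedicleFrame(p, s)
  c0 <- fr$waist
  endZ <- 0.9 * p[["body_axis_z"]]
  er <- sqrt(1 - 0.9^2)
  psi <- c(90, 210, 330) * pi / 180
  endplate <- cbind(p[["body_axis_x"]] * er * cos(psi),
                    p[["body_axis_y"]] * er * sin(psi),
                    rep(endZ, 3L))
  dirS <- c(-cos(35 * pi / 180), 0, -sin(35 * pi / 180))
  spTip <- c(-p[["body_axis_x"]] - 13, 0, -1) +
    p[["spinous_process_length"]] * dirS
  ## medial = margin closer to the midline (smaller |y|)
  m1 <- c0 + p[["pedicle_radius_w"]] * fr$u2
  m2 <- c0 - p[["pedicle_radius_w"]] * fr$u2
  if (abs(m1[2L]) < abs(m2[2L])) { medial <- m1; lateral <- m2 }
  else { medial <- m2; lateral <- m1 }
  pedicleLandmarks(
    superior = c0 + p[["pedicle_radius_h"]] * fr$u1,
    inferior = c0 - p[["pedicle_radius_h"]] * fr$u1,
    lateral = lateral, medial = medial,
    endplate = endplate,
    anteriorBody = c(p[["body_axis_x"]], 0, 0),
    posteriorSpinous = spTip,
    axisTarget = c0 + 8 * fr$d,
    side = side)
}

#' Build the synthetic template vertebra
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param side which pedicle's landmark set to return.
#' @return a list with \code{mesh} (labelled \linkS4class{TriMesh},
#'   exactly \code{pointsPerShape} points) and \code{landmarks}
#'   (\linkS4class{PedicleLandmarks}).
#' @export
makeTemplate <- function(spec, side = "left") {
  geo <- .templateGeometry(spec@params, spec@pointsPerShape)
  list(mesh = triMesh(geo$points, geo$faces, labels = geo$labels,
                      id = "template"),
       landmarks = .templateLandmarks(spec@params, side))
}

## planted mode directions (affine => exact finite difference). Each mode
## is normalised to unit RMS per-point displacement over its support (the
## points it actually moves): one SD of mode k then displaces its region
## by sd_k mm RMS per point — the scale on which regional variability is
## reported. The effective shape-space scale is sd_k * sqrt(support size);
## the default modes have equal supports by construction, so planted
## variance fractions are exactly sd_k^2 / sum(sd^2).
.modeDirections <- function(spec) {
  p0 <- spec@params
  base <- .flattenShape(.templateGeometry(p0, spec@pointsPerShape)$points)
  K <- length(spec@modes)
  U <- matrix(0, length(base), K)
  gnorm <- numeric(K)     # raw Jacobian norm: parameter sensitivity
  support <- integer(K)   # points moved by the mode
  for (k in seq_len(K)) {
    pk <- p0
    pk[[spec@modes[[k]]$parameter]] <- pk[[spec@modes[[k]]$parameter]] + 1
    g <- .flattenShape(.templateGeometry(pk, spec@pointsPerShape)$points) -
      base
    nrm <- sqrt(sum(g * g))
    if (nrm < 1e-12)
      stop("mode '", spec@modes[[k]]$name, "' has no shape effect")
    U[, k] <- g / nrm
    gnorm[k] <- nrm
    support[k] <- sum(.pointNorms(g) > 1e-9 * max(abs(g)))
  }
  list(U = U, gnorm = gnorm, support = support, base = base)
}

#' Generate a synthetic population with ground truth
#'
#' Shape i is the template displaced by \code{sum_k w_ik sd_k u_k} (w
#' standard normal, u_k the unit planted mode directions), plus isotropic
#' point noise, then optionally scrambled by a random rigid pose and a
#' random vertex permutation. The \linkS4class{GroundTruth} records
#' everything pre-scramble.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return a list with \code{shapes} (list of labelled
#'   \linkS4class{PointSet}s), \code{truth} (\linkS4class{GroundTruth})
#'   and \code{template} (the \code{\link{makeTemplate}} result).
#' @export
samplePopulation <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  tmpl <- makeTemplate(spec)
  md <- .modeDirections(spec)
  K <- length(spec@modes)
  ## effective shape-space scale of mode k: its nominal sd (mm) times
  ## kappa * sqrt(support), i.e. a displacement field of amplitude
  ## kappa * sd mm RMS per affected point, independent of sampling
  ## density. kappa = 0.25 calibrates the +3 SD leading default mode to
  ## the few-mm peak regional variation typical of thoracic posterior
  ## elements (and sub-mm everywhere else).
  kappa <- 0.25
  sds <- vapply(spec@modes, `[[`, numeric(1), "sd") *
    kappa * sqrt(if (K) md$support else integer(0))
  n <- spec@nShapes * spec@nLevels
  m <- spec@pointsPerShape

  ## level offsets on the body half-axes (gradual size change by level)
  levelDelta <- if (spec@nLevels > 1L)
    (seq_len(spec@nLevels) - (spec@nLevels + 1) / 2) * 0.4 else 0
  levelOf <- rep(seq_len(spec@nLevels), each = spec@nShapes)

  set.seed(.stageSeed(spec@seed, "weights"))
  W <- matrix(rnorm(n * K), n, K)

  paramNames <- names(spec@params)
  paramValues <- matrix(rep(spec@params, each = n), n,
                        length(spec@params),
                        dimnames = list(NULL, paramNames))
  clean <- matrix(rep(md$base, each = n), n, 3L * m)
  if (spec@nLevels > 1L) {
    for (lv in seq_len(spec@nLevels)) {
      rows <- which(levelOf == lv)
      pl <- spec@params
      for (ax in c("body_axis_x", "body_axis_y", "body_axis_z"))
        pl[[ax]] <- pl[[ax]] + levelDelta[lv]
      lvBase <- .flattenShape(.templateGeometry(pl, m)$points)
      clean[rows, ] <- matrix(rep(lvBase, each = length(rows)),
                              length(rows), 3L * m)
      for (ax in c("body_axis_x", "body_axis_y", "body_axis_z"))
        paramValues[rows, ax] <- paramValues[rows, ax] + levelDelta[lv]
    }
  }
  if (K) {
    clean <- clean + (W %*% (diag(sds, K) %*% t(md$U)))
    for (k in seq_len(K))
      paramValues[, spec@modes[[k]]$parameter] <-
        paramValues[, spec@modes[[k]]$parameter] +
        W[, k] * sds[k] / md$gnorm[k]
  }

  set.seed(.stageSeed(spec@seed, "noise"))
  noisy <- clean
  if (spec@noiseSD > 0)
    noisy <- noisy + matrix(rnorm(n * 3L * m,
                                  sd = spec@noiseSD / sqrt(3)), n, 3L * m)

  set.seed(.stageSeed(spec@seed, "scramble"))
  poses <- vector("list", n)
  perms <- vector("list", n)
  shapes <- vector("list", n)
  labels <- tmpl$mesh@labels
  ids <- if (spec@nLevels > 1L)
    sprintf("L%d_%03d", levelOf, rep(seq_len(spec@nShapes),
                                     spec@nLevels))
  else sprintf("shape_%04d", seq_len(n))
  for (i in seq_len(n)) {
    P <- .unflattenShape(noisy[i, ])
    labs <- labels
    if (spec@scramble %in% c("rigid", "rigid+permute")) {
      tf <- rigidTransform(.randomRotation(), runif(3, -30, 30))
      P <- applyTransform(tf, P)
      poses[[i]] <- tf
    } else poses[[i]] <- rigidTransform()
    if (spec@scramble == "rigid+permute") {
      pm <- sample.int(m)
      P <- P[pm, , drop = FALSE]
      labs <- labs[pm]
      perms[[i]] <- pm
    } else perms[[i]] <- NULL
    shapes[[i]] <- pointSet(P, labels = labs, id = ids[i])
  }
  truth <- new("GroundTruth", weights = W, sds = sds,
               modeDirections = md$U, cleanMatrix = clean,
               paramValues = paramValues, poses = poses,
               permutations = perms, labels = labels,
               templatePoints = shapePoints(tmpl$mesh))
  list(shapes = shapes, truth = truth, template = tmpl)
}

#' Ground-truth landmarks for one generated shape
#'
#' The analytic landmark set evaluated at the shape's effective template
#' parameters, carried through the shape's applied pose.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param shapeIndex which shape.
#' @param side which pedicle.
#' @return a \linkS4class{PedicleLandmarks}.
#' @export
truthLandmarks <- function(truth, shapeIndex, side = "left") {
  stopifnot(shapeIndex >= 1L, shapeIndex <= nrow(truth@weights))
  p <- truth@paramValues[shapeIndex, ]
  l <- .templateLandmarks(p, side)
  applyTransform(truth@poses[[shapeIndex]], l)
}

#' Snap landmark points to template vertex indices
#'
#' Returns a function that extracts \linkS4class{PedicleLandmarks} from any
#' shape corresponded with the template, by carrying the nearest template
#' vertex of each landmark through the correspondence. Useful for
#' measuring synthesised model shapes.
#'
#' @param templatePoints m x 3 template coordinates.
#' @param landmarks template \linkS4class{PedicleLandmarks}.
#' @return function(PointSet or matrix) -> \linkS4class{PedicleLandmarks}.
#' @export
makeLandmarkFun <- function(templatePoints, landmarks) {
  pick <- function(p) .nearestIndex(matrix(p, 1L, 3L), templatePoints)
  idx <- list(superior = pick(landmarks@superior),
              inferior = pick(landmarks@inferior),
              lateral = pick(landmarks@lateral),
              medial = pick(landmarks@medial),
              e1 = pick(landmarks@endplate[1L, ]),
              e2 = pick(landmarks@endplate[2L, ]),
              e3 = pick(landmarks@endplate[3L, ]),
              anteriorBody = pick(landmarks@anteriorBody),
              posteriorSpinous = pick(landmarks@posteriorSpinous),
              axisTarget = pick(landmarks@axisTarget))
  side <- landmarks@side
  function(shape) {
    P <- if (is(shape, "PointSet")) shapePoints(shape) else shape
    pedicleLandmarks(P[idx$superior, ], P[idx$inferior, ],
                     P[idx$lateral, ], P[idx$medial, ],
                     rbind(P[idx$e1, ], P[idx$e2, ], P[idx$e3, ]),
                     P[idx$anteriorBody, ], P[idx$posteriorSpinous, ],
                     P[idx$axisTarget, ], side = side)
  }
}
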