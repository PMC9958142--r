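## Dense correspondence: relevance-based subsampling of template and sample,
## coarse non-rigid CPD on the subsets, evaluation of the recovered
## deformation field on the full-resolution template, then local refinement
## against the original (full) sample so the sub-sampling leaves no imprint
## on the final correspondence.

#' Relevance-based subsampling of a shape
#'
#' Farthest-point sampling (FPS), optionally weighted by a per-point
#' curvature feature so that feature-dense regions are sampled more densely.
#' The curvature feature is the kNN-PCA surface variation (smallest local
#' eigenvalue over the eigenvalue sum); FPS greedily picks the point
#' maximising \code{weight * distance-to-selected}. The first point is the
#' one farthest from the centroid, so the selection depends only on the
#' geometry, not on vertex order.
#'
#' @param shape a \linkS4class{PointSet} or \linkS4class{TriMesh}.
#' @param nSamples number of points to keep (<= point count).
#' @param strategy \code{"curvature_fps"} (default), \code{"uniform_fps"},
#'   or \code{"random"}.
#' @param seed integer seed (used by \code{"random"} only).
#' @param epsilon floor added to the curvature weight.
#' @return integer vector of selected point indices (1-based), in selection
#'   order.
#' @export
relevanceSample <- function(shape, nSamples,
                            strategy = c("curvature_fps", "uniform_fps",
                                         "random"),
                            seed = 1L, epsilon = 0.01) {
  strategy <- match.arg(strategy)
  pts <- if (is(shape, "PointSet")) shapePoints(shape) else shape
  n <- nrow(pts)
  if (nSamples > n)
    stop("nSamples (", nSamples, ") exceeds point count (", n, ")")
  if (nSamples == n) return(seq_len(n))
  if (strategy == "random") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    return(sample.int(n, nSamples))
  }
  wts <- if (strategy == "curvature_fps") {
    epsilon + .surfaceVariation(pts)
  } else rep(1, n)
  sel <- integer(nSamples)
  ctr <- colMeans(pts)
  d0 <- rowSums(sweep(pts, 2L, ctr)^2)
  sel[1L] <- which.max(d0)
  mind <- .dist2(pts, pts[sel[1L], , drop = FALSE])[, 1L]
  for (k in seq_len(nSamples - 1L)) {
    score <- wts * mind
    score[sel[seq_len(k)]] <- -Inf
    sel[k + 1L] <- which.max(score)
    dnew <- .dist2(pts, pts[sel[k + 1L], , drop = FALSE])[, 1L]
    mind <- pmin(mind, dnew)
  }
  sel
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Coarse non-rigid coherent point drift
#'
#' Registers a (subsampled) template onto a (subsampled) sample with the
#' motion-coherence parameterisation: displaced template = Y + G W, where
#' G is the Gaussian kernel Gram matrix of width \code{beta} over the
#' template points and W is found by EM with the regularised M-step system
#' \code{(d(P1) G + lambda sigma2 I) W = P X - d(P1) Y}. The penalised
#' negative log-likelihood is non-increasing.
#'
#' @param templateSub template subset (\linkS4class{PointSet} or matrix);
#'   its points become the control points of the returned field.
#' @param sampleSub sample subset (the data of the mixture).
#' @param beta Gaussian kernel width (mm); controls deformation smoothness.
#' @param lambda motion-coherence regularisation weight.
#' @param w uniform outlier weight.
#' @param maxIterations,tolerance EM stopping controls.
#' @return a list with \code{field} (\linkS4class{DeformationField}),
#'   \code{deformed} (displaced control points), \code{sigma2},
#'   \code{trace} (penalised negative log-likelihood per iteration),
#'   \code{iterations}, \code{converged}.
#' @export
nonrigidCPDCoarse <- function(templateSub, sampleSub, beta, lambda = 1,
                              w = 0, maxIterations = 100L,
                              tolerance = 1e-8) {
  Y <- if (is(templateSub, "PointSet")) shapePoints(templateSub) else
    templateSub
  X <- if (is(sampleSub, "PointSet")) shapePoints(sampleSub) else sampleSub
  stopifnot(beta > 0, lambda >= 0, w >= 0, w < 1)
  M <- nrow(Y); N <- nrow(X)
  d2 <- .dist2(Y, Y)
  diam <- sqrt(max(d2))
  if (beta > 2 * diam)
    stop("kernel system is numerically singular: beta = ", beta,
         " exceeds the spread of the control points (diameter ",
         signif(diam, 3), ")")
  G <- exp(-d2 / (2 * beta^2))
  W <- matrix(0, M, 3L)
  sigma2 <- sum(.dist2(Y, X)) / (3 * N * M)
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  T_ <- Y
  while (iter < maxIterations) {
    iter <- iter + 1L
    es <- .cpdEStep(X, T_, sigma2, w)
    obj <- es$nll + (lambda / 2) * sum(W * (G %*% W))
    trace <- c(trace, obj)
    P <- es$P
    P1 <- rowSums(P)
    PX <- P %*% X
    A <- G * P1 + diag(lambda * sigma2, M)   # d(P1) G + lambda sigma2 I
    B <- PX - Y * P1
    W <- solve(A, B)
    T_ <- Y + G %*% W
    Np <- sum(P1)
    Px1 <- colSums(P)
    xPx <- sum(Px1 * rowSums(X * X))
    trPT <- sum(PX * T_)
    tPt <- sum(P1 * rowSums(T_ * T_))
    sigma2 <- max((xPx - 2 * trPT + tPt) / (3 * Np), 1e-12)
    if (is.finite(prev) && abs(prev - obj) <= tolerance * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- obj
    if (sigma2 <= 1e-10) { converged <- TRUE; break }
  }
  field <- new("DeformationField", controlPoints = Y, coefficients = W,
               beta = beta)
  list(field = field, deformed = T_, sigma2 = sigma2, trace = trace,
       iterations = iter, converged = converged)
}

#' Evaluate a deformation field at arbitrary points
#'
#' Displacement at x is the Gaussian-kernel combination of the field
#' coefficients over its control points; used to carry the coarse
#' deformation from the subsampled template to the full-resolution template.
#'
#' @param field a \linkS4class{DeformationField}.
#' @param points n x 3 matrix or \linkS4class{PointSet}.
#' @return n x 3 matrix of displaced points.
#' @export
evaluateField <- function(field, points) {
  P <- if (is(points, "PointSet")) shapePoints(points) else points
  K <- exp(-.dist2(P, field@controlPoints) / (2 * field@beta^2))
  P + K %*% field@coefficients
}

#' Local fine refinement of a coarsely registered template
#'
#' Starting from the coarsely deformed full-resolution template, iteratively
#' minimises the sum of squared distances to the nearest sample location
#' plus a kNN-Laplacian stiffness penalty on the per-point displacements:
#' \code{sum_i |p_i + d_i - q_i|^2 + stiffness * sum_(i,j in kNN)
#' |d_i - d_j|^2}. Nearest locations are sample points, or the projection
#' onto the incident triangles of the nearest vertex when the sample has
#' faces and \code{target = "surface"}. Residuals are reported per template
#' point; if the mean residual increases three iterations running the
#' refinement stops early with a warning.
#'
#' @param deformedTemplate full-resolution template after the coarse stage
#'   (\linkS4class{PointSet} or matrix).
#' @param sample the original full-resolution sample (\linkS4class{PointSet}
#'   or \linkS4class{TriMesh}).
#' @param stiffness non-negative displacement-smoothness weight.
#' @param iterations number of alternation steps.
#' @param k number of nearest neighbours in the stiffness graph.
#' @param target \code{"point"} (nearest sample point) or \code{"surface"}
#'   (nearest point on incident faces, requires a TriMesh sample).
#' @return a \linkS4class{CorrespondenceMap}.
#' @export
localRefine <- function(deformedTemplate, sample, stiffness = 1,
                        iterations = 20L, k = 6L,
                        target = c("point", "surface")) {
  target <- match.arg(target)
  P0 <- if (is(deformedTemplate, "PointSet")) shapePoints(deformedTemplate)
        else deformedTemplate
  S <- if (is(sample, "PointSet")) shapePoints(sample) else sample
  if (!nrow(S)) stop("sample is empty")
  faces <- if (target == "surface" && is(sample, "TriMesh"))
    meshFaces(sample) else NULL
  m <- nrow(P0)
  D <- matrix(0, m, 3L)
  ## stiffness operator: symmetrised kNN graph Laplacian
  L <- NULL
  if (stiffness > 0) {
    kk <- min(k, m - 1L)
    nn <- .knnIndex(P0, kk)
    ii <- rep(seq_len(m), each = kk)
    jj <- as.integer(t(nn))
    Adj <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                                x = 1, dims = c(m, m))
    Adj@x[] <- 1   # duplicates were summed; binarise (union graph)
    L <- Matrix::Diagonal(x = Matrix::rowSums(Adj)) - Adj
  }
  lhs <- if (!is.null(L))
    Matrix::Diagonal(m) + stiffness * L else NULL
  lhsFac <- if (!is.null(lhs)) Matrix::Cholesky(Matrix::forceSymmetric(lhs))
            else NULL
  prevRes <- Inf
  rising <- 0L
  residuals <- numeric(m)
  Q <- P0
  for (it in seq_len(max(1L, iterations))) {
    cur <- P0 + D
    Q <- .closestOnSample(cur, S, faces)
    residuals <- sqrt(rowSums((cur - Q)^2))
    mres <- mean(residuals)
    if (mres > prevRes + 1e-12) {
      rising <- rising + 1L
      if (rising >= 3L) {
        warning("local refinement diverging; stopping early at iteration ",
                it)
        break
      }
    } else rising <- 0L
    prevRes <- mres
    rhs <- Q - P0
    D <- if (!is.null(lhsFac))
      as.matrix(Matrix::solve(lhsFac, rhs)) else rhs
  }
  final <- P0 + D
  Q <- .closestOnSample(final, S, faces)
  new("CorrespondenceMap", coordinates = final,
      residuals = sqrt(rowSums((final - Q)^2)))
}

## closest sample location for each query point: nearest vertex, optionally
## refined by projecting onto the triangles incident to that vertex
.closestOnSample <- function(P, S, faces = NULL) {
  idx <- .nearestIndex(P, S)
  Q <- S[idx, , drop = FALSE]
  if (is.null(faces) || !nrow(faces)) return(Q)
  f1 <- faces + 1L
  incid <- split(rep(seq_len(nrow(f1)), 3L), as.vector(f1))
  for (i in seq_len(nrow(P))) {
    fs <- incid[[as.character(idx[i])]]
    if (is.null(fs)) next
    best <- Q[i, ]; bd <- sum((P[i, ] - best)^2)
    for (fi in fs) {
      pr <- .pointToTriangle(P[i, ], S[f1[fi, 1L], ], S[f1[fi, 2L], ],
                             S[f1[fi, 3L], ])
      d <- sum((P[i, ] - pr)^2)
      if (d < bd) { bd <- d; best <- pr }
    }
    Q[i, ] <- best
  }
  Q
}

## closest point on triangle (a, b, c) to p (Ericson, Real-Time Collision
## Detection, 5.1.5)
.pointToTriangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

#' Correspondence parameter bundle
#'
#' @param nSubsample points kept per shape by relevance sampling.
#' @param strategy subsampling strategy (see \code{\link{relevanceSample}}).
#' @param beta coarse-stage kernel width (mm); default (NA) is twice the
#'   mean nearest-neighbour spacing of the template.
#' @param lambda coarse-stage regularisation weight.
#' @param w coarse-stage outlier weight.
#' @param coarseIterations,coarseTolerance coarse-stage stopping controls.
#' @param stiffness,refineIterations,refineK fine-stage controls (see
#'   \code{\link{localRefine}}).
#' @param target fine-stage target mode.
#' @param procrustesPolish after refinement, remove the residual rigid
#'   pose of each sample's correspondence image by closed-form Procrustes
#'   alignment to the template (the density-based rigid stage leaves a
#'   small per-shape pose jitter that would otherwise enter the model as
#'   spurious variance).
#' @param seed root seed for the stage.
#' @return a list of class \code{CorrespondenceParams}.
#' @export
correspondenceParams <- function(nSubsample = 500L,
                                 strategy = "curvature_fps", beta = NA,
                                 lambda = 1, w = 0,
                                 coarseIterations = 100L,
                                 coarseTolerance = 1e-8, stiffness = 1,
                                 refineIterations = 20L, refineK = 6L,
                                 target = "point", procrustesPolish = TRUE,
                                 seed = 1L) {
  structure(list(nSubsample = as.integer(nSubsample), strategy = strategy,
                 beta = beta, lambda = lambda, w = w,
                 coarseIterations = as.integer(coarseIterations),
                 coarseTolerance = coarseTolerance, stiffness = stiffness,
                 refineIterations = as.integer(refineIterations),
                 refineK = as.integer(refineK), target = target,
                 procrustesPolish = isTRUE(procrustesPolish),
                 seed = as.integer(seed)),
            class = "CorrespondenceParams")
}

## closed-form rigid Procrustes (no scale): transform aligning A onto B
.procrustesRigid <- function(A, B) {
  muA <- colMeans(A); muB <- colMeans(B)
  H <- crossprod(sweep(A, 2L, muA), sweep(B, 2L, muB))
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  rigidTransform(R, muB - as.numeric(R %*% muA))
}

## mean nearest-neighbour spacing of a point matrix
.meanSpacing <- function(pts) {
  d2 <- .dist2(pts, pts)
  diag(d2) <- Inf
  mean(sqrt(apply(d2, 1L, min)))
}

#' Establish dense correspondence between a template and every sample
#'
#' For each (already rigidly aligned) sample: subsample template and sample,
#' run the coarse non-rigid stage on the subsets, evaluate the recovered
#' field on the full template, then refine locally against the original
#' full-resolution sample. The refined template point positions (continuous
#' space, not snapped to sample vertices) become the sample's shape-vector,
#' so every shape-vector has length 3 x (template point count).
#'
#' @param template the reference \linkS4class{PointSet} or
#'   \linkS4class{TriMesh} (typically the rigid-alignment reference).
#' @param samples list of aligned \linkS4class{PointSet}s.
#' @param params a \code{\link{correspondenceParams}} bundle.
#' @param iterateMean re-register against the current mean shape this many
#'   extra times (0 = one-pass correspondence).
#' @return a \linkS4class{CorrespondedPopulation}; per-sample failures are
#'   recorded in \code{attr(, "failures")} and their shapes omitted.
#' @export
correspondPopulation <- function(template, samples,
                                 params = correspondenceParams(),
                                 iterateMean = 0L) {
  tpts <- shapePoints(template)
  m <- nrow(tpts)
  nSub <- min(params$nSubsample, m)
  beta <- params$beta
  tSubIdx <- relevanceSample(template, nSub, strategy = params$strategy,
                             seed = params$seed)
  tSub <- tpts[tSubIdx, , drop = FALSE]
  if (is.na(beta)) beta <- 2 * .meanSpacing(tSub)
  ids <- vapply(seq_along(samples), function(i) {
    id <- shapeID(samples[[i]])
    if (is.na(id)) sprintf("shape_%04d", i) else id
  }, "")
  corrOne <- function(sample, refPts, refSubIdx, refSub) {
    spts <- shapePoints(sample)
    sSubIdx <- relevanceSample(sample, min(nSub, nrow(spts)),
                               strategy = params$strategy,
                               seed = params$seed)
    sSub <- spts[sSubIdx, , drop = FALSE]
    coarse <- nonrigidCPDCoarse(refSub, sSub, beta = beta,
                                lambda = params$lambda, w = params$w,
                                maxIterations = params$coarseIterations,
                                tolerance = params$coarseTolerance)
    warped <- evaluateField(coarse$field, refPts)
    cm <- localRefine(warped, sample, stiffness = params$stiffness,
                      iterations = params$refineIterations,
                      k = params$refineK, target = params$target)
    if (isTRUE(params$procrustesPolish)) {
      tf <- .procrustesRigid(cm@coordinates, refPts)
      cm@coordinates <- applyTransform(tf, cm@coordinates)
    }
    cm
  }
  shapes <- matrix(NA_real_, length(samples), 3L * m)
  failures <- list()
  for (i in seq_along(samples)) {
    res <- tryCatch(corrOne(samples[[i]], tpts, tSubIdx, tSub),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[ids[i]]] <- conditionMessage(res)
    } else {
      shapes[i, ] <- .flattenShape(res@coordinates)
    }
  }
  ok <- !vapply(seq_along(samples), function(i) ids[i] %in% names(failures),
                TRUE)
  pop <- new("CorrespondedPopulation",
             shapes = shapes[ok, , drop = FALSE], ids = ids[ok],
             templatePoints = tpts,
             templateFaces = if (is(template, "TriMesh"))
               meshFaces(template) else matrix(integer(0), 0L, 3L),
             labels = if (length(template@labels)) template@labels
                      else character(0))
  it <- as.integer(iterateMean)
  while (it > 0L) {
    it <- it - 1L
    meanPts <- .unflattenShape(colMeans(pop@shapes))
    meanShape <- pointSet(meanPts, labels = pop@labels, id = "mean")
    mSubIdx <- relevanceSample(meanShape, nSub, strategy = params$strategy,
                               seed = params$seed)
    mSub <- meanPts[mSubIdx, , drop = FALSE]
    for (i in which(ok)) {
      res <- tryCatch(corrOne(samples[[i]], meanPts, mSubIdx, mSub),
                      error = function(e) e)
      if (!inherits(res, "error"))
        pop@shapes[match(ids[i], pop@ids), ] <-
          .flattenShape(res@coordinates)
    }
  }
  attr(pop, "failures") <- failures
  pop
}
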