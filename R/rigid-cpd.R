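## Rigid coherent point drift: the moving point set is treated as the
## centroids of an isotropic Gaussian mixture (plus a uniform outlier
## component with weight w) and the fixed set as data; EM alternates soft
## assignment with a closed-form weighted Procrustes update of rotation,
## translation, (optionally) scale, and the shared variance sigma^2.

#' Rigid CPD parameter bundle
#'
#' @param w uniform outlier weight in [0, 1).
#' @param maxIterations EM iteration cap.
#' @param tolerance relative change of the negative log-likelihood at which
#'   to stop.
#' @param allowScaling estimate a uniform scale (held at 1 when FALSE, the
#'   default, so model measurements keep their physical units).
#' @param initialSigma2 optional starting variance (mm^2); default is the
#'   mean squared distance between the two sets divided by 3.
#' @param initialize \code{"moments"} (default): EM is run from the
#'   deterministic principal-axes pre-alignment under all four proper
#'   sign combinations plus the input pose, and the best final
#'   likelihood wins — keeping the local optimisation out of flipped
#'   basins under arbitrary initial pose. \code{"identity"}: a single
#'   run from the input pose.
#' @return a list of class \code{RigidCPDParams}.
#' @export
rigidCPDParams <- function(w = 0, maxIterations = 150L, tolerance = 1e-8,
                           allowScaling = FALSE, initialSigma2 = NULL,
                           initialize = c("moments", "identity")) {
  stopifnot(w >= 0, w < 1, tolerance > 0, maxIterations >= 1)
  structure(list(w = w, maxIterations = as.integer(maxIterations),
                 tolerance = tolerance, allowScaling = allowScaling,
                 initialSigma2 = initialSigma2,
                 initialize = match.arg(initialize)),
            class = "RigidCPDParams")
}

## deterministic moment-based pre-alignment candidates: align principal
## axes of the two sets under every proper signed axis permutation (the
## 24 rotations of the cube; close covariance eigenvalues can swap the
## axis order between two shapes of the same anatomy). Candidates are
## pre-screened by subsampled nearest-neighbour cost and the survivors
## are disambiguated downstream by running EM to convergence on each.
.momentInitCandidates <- function(Y, X, keep = 5L) {
  muY <- colMeans(Y); muX <- colMeans(X)
  Ey <- eigen(stats::cov(Y), symmetric = TRUE)$vectors
  Ex <- eigen(stats::cov(X), symmetric = TRUE)$vectors
  if (det(Ey) < 0) Ey[, 3L] <- -Ey[, 3L]
  if (det(Ex) < 0) Ex[, 3L] <- -Ex[, 3L]
  cands <- list()
  for (pm in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))) {
    P <- diag(3)[, pm]
    for (s in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                   c(-1, -1, 1), c(-1, -1, -1), c(-1, 1, 1),
                   c(1, -1, 1), c(1, 1, -1))) {
      Q <- P %*% diag(s)
      if (abs(det(Q) - 1) > 1e-9) next
      R0 <- Ex %*% Q %*% t(Ey)
      cands[[length(cands) + 1L]] <-
        list(R = R0, t = muX - as.numeric(R0 %*% muY))
    }
  }
  ## cheap screen: mean subsampled nearest-neighbour distance
  sub <- function(A) A[seq(1L, nrow(A),
                           by = max(1L, nrow(A) %/% 150L)), ,
                       drop = FALSE]
  Xs <- sub(X); Ys <- sub(Y)
  cost <- vapply(cands, function(cd) {
    Yt <- sweep(tcrossprod(Ys, cd$R), 2L, cd$t, "+")
    mean(apply(.dist2(Yt, Xs), 1L, min))
  }, numeric(1))
  cands[order(cost)[seq_len(min(keep, length(cands)))]]
}

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation length-3 numeric (mm).
#' @param scale positive scalar.
#' @return a \linkS4class{RigidTransform}.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation), scale = as.numeric(scale))
}

#' Compose and invert rigid transforms
#'
#' \code{composeTransform(a, b)} is the transform "apply b, then a";
#' \code{invertTransform(t)} undoes t. Both stay within the class.
#'
#' @param a,b,transform \linkS4class{RigidTransform}s.
#' @return a \linkS4class{RigidTransform}.
#' @export
composeTransform <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 a@scale * as.numeric(a@rotation %*% b@translation) +
                   a@translation,
                 a@scale * b@scale)
}

#' @rdname composeTransform
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, -as.numeric(Rt %*% transform@translation) /
                   transform@scale, 1 / transform@scale)
}

setMethod("applyTransform", signature("RigidTransform", "matrix"),
  function(transform, shape) {
    sweep(transform@scale * tcrossprod(shape, transform@rotation), 2L,
          transform@translation, "+")
  })

setMethod("applyTransform", signature("RigidTransform", "PointSet"),
  function(transform, shape) {
    out <- shape
    out@points <- applyTransform(transform, shape@points)
    out
  })

setMethod("applyTransform", signature("RigidTransform", "PedicleLandmarks"),
  function(transform, shape) {
    tp <- function(p) as.numeric(applyTransform(transform,
                                                matrix(p, 1L, 3L)))
    new("PedicleLandmarks",
        superior = tp(shape@superior), inferior = tp(shape@inferior),
        lateral = tp(shape@lateral), medial = tp(shape@medial),
        endplate = applyTransform(transform, shape@endplate),
        anteriorBody = tp(shape@anteriorBody),
        posteriorSpinous = tp(shape@posteriorSpinous),
        axisTarget = tp(shape@axisTarget), side = shape@side)
  })

## E-step: posterior P (M x N) of GMM centroids T for data X, plus the
## negative log-likelihood of the current parameters.
.cpdEStep <- function(X, T_, sigma2, w) {
  N <- nrow(X); M <- nrow(T_)
  d2 <- .dist2(T_, X)
  G <- exp(-d2 / (2 * sigma2))
  cst <- (2 * pi * sigma2)^1.5 * (w / (1 - w)) * (M / N)
  den <- colSums(G) + cst
  den[den == 0] <- .Machine$double.xmin
  P <- sweep(G, 2L, den, "/")
  nll <- -sum(log(den * (1 - w) / (M * (2 * pi * sigma2)^1.5)))
  list(P = P, nll = nll)
}

## Weighted Procrustes M-step shared by the rigid solver and its tests:
## given data X (N x 3), source Y (M x 3) and posteriors P (M x N), returns
## R (proper), t, s, and the updated sigma^2.
.rigidMStep <- function(X, Y, P, allowScaling = FALSE) {
  Np <- sum(P)
  if (!is.finite(Np) || Np <= 0)
    stop("rigid CPD posteriors vanished (sigma^2 collapsed)")
  Px1 <- colSums(P)          # length N: weight of each data point
  P1 <- rowSums(P)           # length M: weight of each centroid
  muX <- as.numeric(crossprod(X, Px1)) / Np
  muY <- as.numeric(crossprod(Y, P1)) / Np
  Xh <- sweep(X, 2L, muX)
  Yh <- sweep(Y, 2L, muY)
  A <- crossprod(Xh, crossprod(P, Yh))   # t(Xh) %*% t(P) %*% Yh
  sv <- svd(A)
  C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% C %*% t(sv$v)
  trAR <- sum(diag(crossprod(A, R)))
  yTy <- sum(P1 * rowSums(Yh * Yh))
  s <- if (allowScaling) trAR / yTy else 1
  t_ <- muX - s * as.numeric(R %*% muY)
  xTx <- sum(Px1 * rowSums(Xh * Xh))
  sigma2 <- (xTx - s * trAR) / (3 * Np)
  list(R = R, t = t_, s = s, sigma2 = max(sigma2, 1e-12), Np = Np)
}

#' Rigid coherent point drift registration
#'
#' Registers \code{source} onto \code{target}: the source points are the
#' Gaussian-mixture centroids, moved rigidly (rotation, translation, and
#' optionally a uniform scale) to maximise the likelihood of the target
#' points under the mixture plus a uniform outlier component. The negative
#' log-likelihood is non-increasing across EM iterations.
#'
#' @param source,target \linkS4class{PointSet}s or n x 3 matrices; point
#'   counts need not match.
#' @param params a \code{\link{rigidCPDParams}} bundle.
#' @return a list with \code{transform} (\linkS4class{RigidTransform}),
#'   \code{aligned} (transformed source, same class as input),
#'   \code{sigma2} (final mixture variance, mm^2), \code{trace} (per-
#'   iteration negative log-likelihood), \code{iterations}, and
#'   \code{converged}.
#' @examples
#' pts <- matrix(rnorm(300), 100, 3)
#' tgt <- pts %*% t(pedicleSSM:::.axisRotation(c(0, 0, 1), 30)) +
#'   matrix(c(5, -3, 2), 100, 3, byrow = TRUE)
#' fit <- rigidCPD(pts, tgt)
#' rotationAngle(fit$transform@rotation)  # ~30
#' @export
rigidCPD <- function(source, target, params = rigidCPDParams()) {
  srcObj <- if (is(source, "PointSet")) source else NULL
  Y <- if (is(source, "PointSet")) shapePoints(source) else source
  X <- if (is(target, "PointSet")) shapePoints(target) else target
  stopifnot(ncol(Y) == 3L, ncol(X) == 3L)
  if (max(.dist2(Y, Y)) < 1e-24)
    stop("degenerate source geometry: all points coincide")
  inits <- if (identical(params$initialize, "identity"))
    list(list(R = diag(3), t = c(0, 0, 0)))
  else c(list(list(R = diag(3),
                   t = colMeans(X) - colMeans(Y))),   # classic CPD start
         .momentInitCandidates(Y, X))
  ## every candidate initialisation is run to convergence; the winner is
  ## the run with the smallest final mixture variance (the residual
  ## overlay error), with the likelihood as tie-break. Raw likelihoods
  ## cannot be compared across runs because the Gaussian likelihood is
  ## unbounded as sigma^2 collapses on a near-perfect overlay.
  runs <- lapply(inits, function(it)
    .rigidCPDLoop(X, Y, it$R, it$t, params,
                  maxIterations = params$maxIterations))
  sig <- vapply(runs, function(b) b$sigma2, numeric(1))
  nll <- vapply(runs, function(b) b$trace[length(b$trace)], numeric(1))
  res <- runs[[order(sig, nll)[1L]]]
  if (!res$converged)
    warning("rigid CPD did not converge within ", params$maxIterations,
            " iterations; returning best transform")
  tf <- rigidTransform(res$R, res$t, res$s)
  aligned <- if (!is.null(srcObj)) applyTransform(tf, srcObj) else
    applyTransform(tf, Y)
  list(transform = tf, aligned = aligned, sigma2 = res$sigma2,
       trace = res$trace, iterations = length(res$trace),
       converged = res$converged)
}

## EM inner loop; resumable (state in, state out), trace accumulates the
## negative log-likelihood at the start of each iteration
.rigidCPDLoop <- function(X, Y, R, t_, params, maxIterations, s = 1,
                          sigma2 = NULL, trace = numeric(0)) {
  N <- nrow(X); M <- nrow(Y)
  if (is.null(sigma2))
    sigma2 <- if (!is.null(params$initialSigma2)) params$initialSigma2
      else sum(.dist2(sweep(s * tcrossprod(Y, R), 2L, t_, "+"), X)) /
        (3 * N * M)
  converged <- FALSE
  prev <- if (length(trace)) trace[length(trace)] else Inf
  iter <- 0L
  while (iter < maxIterations) {
    iter <- iter + 1L
    T_ <- sweep(s * tcrossprod(Y, R), 2L, t_, "+")
    es <- .cpdEStep(X, T_, sigma2, params$w)
    if (sum(es$P) <= 0) { converged <- TRUE; break }  # sigma2 collapsed
    trace <- c(trace, es$nll)
    ms <- .rigidMStep(X, Y, es$P, params$allowScaling)
    R <- ms$R; t_ <- ms$t; s <- ms$s; sigma2 <- ms$sigma2
    if (is.finite(prev) &&
        abs(prev - es$nll) <= params$tolerance * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- es$nll
    if (sigma2 < 1e-8) { converged <- TRUE; break }
  }
  list(R = R, t = t_, s = s, sigma2 = sigma2, trace = trace,
       converged = converged)
}

#' Rigidly align a population of shapes to a common reference
#'
#' Each shape is registered onto the reference with \code{\link{rigidCPD}}.
#' Per-shape failures are recorded and the run continues.
#'
#' @param shapes list of \linkS4class{PointSet}s (point counts may differ).
#' @param reference reference \linkS4class{PointSet}; default is the first
#'   shape after sorting ids (deterministic).
#' @param params a \code{\link{rigidCPDParams}} bundle.
#' @return a list with \code{aligned} (list of aligned shapes),
#'   \code{transforms}, \code{reference}, and \code{failures} (named list of
#'   error messages).
#' @export
alignPopulation <- function(shapes, reference = NULL,
                            params = rigidCPDParams()) {
  stopifnot(length(shapes) >= 1L)
  if (length(shapes) == 1L && is.null(reference)) {
    return(list(aligned = shapes, transforms = list(rigidTransform()),
                reference = shapes[[1L]], failures = list()))
  }
  if (is.null(reference)) {
    ids <- vapply(shapes, shapeID, "")
    ids[is.na(ids)] <- sprintf("shape_%04d", which(is.na(ids)))
    reference <- shapes[[order(ids)[1L]]]
  }
  aligned <- vector("list", length(shapes))
  transforms <- vector("list", length(shapes))
  failures <- list()
  for (i in seq_along(shapes)) {
    res <- tryCatch(rigidCPD(shapes[[i]], reference, params),
                    error = function(e) e)
    if (inherits(res, "error")) {
      key <- shapeID(shapes[[i]])
      if (is.na(key)) key <- sprintf("shape_%04d", i)
      failures[[key]] <- conditionMessage(res)
      aligned[[i]] <- shapes[[i]]
      transforms[[i]] <- rigidTransform()
    } else {
      aligned[[i]] <- res$aligned
      transforms[[i]] <- res$transform
    }
  }
  list(aligned = aligned, transforms = transforms, reference = reference,
       failures = failures)
}

#' Serialise a rigid transform as a 12-number row-major record
#'
#' Layout: the 3 rows of \code{scale * R} followed by the translation — the
#' run-log (CSV) representation of a transform.
#'
#' @param transform a \linkS4class{RigidTransform}.
#' @return numeric vector of length 12.
#' @export
transformToRecord <- function(transform) {
  c(as.numeric(t(transform@scale * transform@rotation)),
    transform@translation)
}

#' @rdname transformToRecord
#' @param record numeric vector of length 12 (see
#'   \code{transformToRecord}).
#' @export
recordToTransform <- function(record) {
  stopifnot(length(record) == 12L)
  M <- matrix(record[1:9], 3L, 3L, byrow = TRUE)
  s <- det(M)^(1 / 3)
  rigidTransform(M / s, record[10:12], s)
}
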