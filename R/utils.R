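#' Construct a PointSet
#'
#' @param points n x 3 numeric matrix (mm).
#' @param labels optional per-point region tags.
#' @param id optional identifier.
#' @return a \linkS4class{PointSet}.
#' @export
pointSet <- function(points, labels = character(0), id = NA_character_) {
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  new("PointSet", points = points, labels = as.character(labels),
      id = as.character(id))
}

#' Construct a TriMesh
#'
#' @param points n x 3 numeric matrix (mm).
#' @param faces f x 3 matrix of 0-based vertex indices.
#' @param labels optional per-point region tags.
#' @param id optional identifier.
#' @return a \linkS4class{TriMesh}.
#' @export
triMesh <- function(points, faces = matrix(integer(0), 0L, 3L),
                    labels = character(0), id = NA_character_) {
  storage.mode(points) <- "double"
  faces <- matrix(as.integer(faces), ncol = 3L)
  dimnames(points) <- dimnames(faces) <- NULL
  new("TriMesh", points = points, faces = faces,
      labels = as.character(labels), id = as.character(id))
}

## squared Euclidean distances between rows of A (n x 3) and B (m x 3)
.dist2 <- function(A, B) {
  d2 <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

## index of nearest row of B for each row of A, chunked to bound memory
.nearestIndex <- function(A, B, chunk = 2048L) {
  n <- nrow(A)
  idx <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    idx[s:e] <- max.col(-.dist2(A[s:e, , drop = FALSE], B), "first")
  }
  idx
}

## k nearest neighbours (excluding self) among rows of X; n x k index matrix
.knnIndex <- function(X, k) {
  d2 <- .dist2(X, X)
  diag(d2) <- Inf
  t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
}

#' Rotation angle of a 3 x 3 rotation matrix
#'
#' @param R proper orthogonal 3 x 3 matrix.
#' @return rotation angle in degrees.
#' @export
rotationAngle <- function(R) {
  c <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c))) * 180 / pi
}

## rotation about a unit axis by angle (degrees)
.axisRotation <- function(axis, angleDeg) {
  a <- angleDeg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

## uniform random proper rotation (QR of Gaussian matrix, det fixed to +1)
.randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

## deterministic per-stage seed derived from a root seed (kept below 2^31)
.stageSeed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 2654435761 + h * 97 + 12345) %% 2147483647)
}

## flatten an m x 3 matrix to (x1,y1,z1,...) and back
.flattenShape <- function(pts) as.numeric(t(pts))
.unflattenShape <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

## per-point Euclidean norms of a flattened displacement vector
.pointNorms <- function(v) {
  m <- .unflattenShape(v)
  sqrt(rowSums(m * m))
}

#' Normal-distribution coverage of a symmetric +/- k SD interval
#'
#' The design rationale for synthesising shapes at +/- 3 SD: approximately
#' 99.7\% of a normally distributed population lies within 3 SD of the mean
#' (95\% within 2 SD).
#'
#' @param k half-width of the interval in standard deviations.
#' @return coverage in percent.
#' @examples
#' normalCoverage(3)  # 99.73
#' normalCoverage(2)  # 95.45
#' @export
normalCoverage <- function(k) {
  stopifnot(k >= 0)
  100 * (2 * pnorm(k) - 1)
}

## Qn robust scale (Rousseeuw & Croux): c * k-th smallest pairwise distance
.qnScale <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  d <- abs(outer(x, x, "-"))
  d <- d[lower.tri(d)]
  h <- floor(n / 2) + 1L
  k <- h * (h - 1L) / 2L
  2.2219 * sort(d, partial = k)[k]
}

## vertex normals: area-weighted face normals where faces exist, kNN-PCA
## normals elsewhere; oriented outward from the centroid
.vertexNormals <- function(pts, faces = NULL, k = 10L) {
  n <- nrow(pts)
  N <- matrix(0, n, 3L)
  if (!is.null(faces) && nrow(faces)) {
    f <- faces + 1L
    e1 <- pts[f[, 2L], , drop = FALSE] - pts[f[, 1L], , drop = FALSE]
    e2 <- pts[f[, 3L], , drop = FALSE] - pts[f[, 1L], , drop = FALSE]
    fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted
    for (j in 1:3) {
      N[, 1] <- N[, 1] + tabulate2(f[, j], fn[, 1], n)
      N[, 2] <- N[, 2] + tabulate2(f[, j], fn[, 2], n)
      N[, 3] <- N[, 3] + tabulate2(f[, j], fn[, 3], n)
    }
  }
  missing <- rowSums(N * N) < 1e-20
  if (any(missing)) {
    kk <- min(k, n - 1L)
    nn <- .knnIndex(pts, kk)
    for (i in which(missing)) {
      P <- pts[nn[i, ], , drop = FALSE]
      P <- sweep(P, 2L, colMeans(P))
      N[i, ] <- svd(P, nu = 0L)$v[, 3L]
    }
  }
  len <- sqrt(rowSums(N * N))
  len[len == 0] <- 1
  N <- N / len
  ctr <- colMeans(pts)
  out <- rowSums(N * sweep(pts, 2L, ctr))
  N[out < 0, ] <- -N[out < 0, , drop = FALSE]
  N
}

## sum values by integer group (base tabulate with weights)
tabulate2 <- function(idx, vals, n) {
  as.numeric(tapply2(idx, vals, n))
}

tapply2 <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

## kNN-PCA surface-variation curvature proxy: lambda3 / (l1+l2+l3)
.surfaceVariation <- function(pts, k = 10L) {
  n <- nrow(pts)
  kk <- min(k, n - 1L)
  nn <- .knnIndex(pts, kk)
  vapply(seq_len(n), function(i) {
    P <- pts[c(i, nn[i, ]), , drop = FALSE]
    P <- sweep(P, 2L, colMeans(P))
    ev <- svd(P, nu = 0L, nv = 0L)$d^2
    if (sum(ev) <= 0) 0 else ev[3L] / sum(ev)
  }, numeric(1))
}
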