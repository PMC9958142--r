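## Shared fixtures and independent oracles for the test suite. Oracles are
## deliberately written from first principles (plain loops, base svd) so
## they do not share code paths with the implementation they check.

rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

rotAxis <- function(axis, deg) pedicleSSM:::.axisRotation(axis, deg)

randomCloud <- function(n, scale = 10, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = scale), n, 3L)
}

## unit tetrahedron mesh
tetraMesh <- function() {
  triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(0, 1, 2), c(0, 1, 3), c(0, 2, 3), c(1, 2, 3)))
}

## closed UV-sphere mesh (poles + rings) with exact outward normals
uvSphereMesh <- function(nu = 10L, nv = 16L, r = 5) {
  th <- seq(0, pi, length.out = nu + 2L)[-c(1L, nu + 2L)]
  ph <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
  pts <- rbind(c(0, 0, r),
               as.matrix(expand.grid(ph = ph, th = th))[, c(1, 2)] |>
                 (\(g) cbind(r * sin(g[, 2]) * cos(g[, 1]),
                             r * sin(g[, 2]) * sin(g[, 1]),
                             r * cos(g[, 2])))(),
               c(0, 0, -r))
  n <- nrow(pts)
  faces <- list()
  ring <- function(i) 1L + (i - 1L) * nv + seq_len(nv)   # 1-based
  r1 <- ring(1L)
  for (j in seq_len(nv)) {
    j2 <- if (j == nv) 1L else j + 1L
    faces[[length(faces) + 1L]] <- c(1L, r1[j], r1[j2])
  }
  for (i in seq_len(nu - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    for (j in seq_len(nv)) {
      j2 <- if (j == nv) 1L else j + 1L
      faces[[length(faces) + 1L]] <- c(a[j], b[j], b[j2])
      faces[[length(faces) + 1L]] <- c(a[j], b[j2], a[j2])
    }
  }
  rl <- ring(nu)
  for (j in seq_len(nv)) {
    j2 <- if (j == nv) 1L else j + 1L
    faces[[length(faces) + 1L]] <- c(n, rl[j2], rl[j])
  }
  triMesh(pts, do.call(rbind, faces) - 1L)
}

## brute-force nearest-neighbour oracle
nnOracle <- function(A, B) {
  t(vapply(seq_len(nrow(A)), function(i) {
    d <- colSums((t(B) - A[i, ])^2)
    B[which.min(d), ]
  }, numeric(3)))
}

## independent orthogonal-Procrustes oracle (base svd, textbook form)
procrustesOracle <- function(A, B) {
  ## rotation R minimising ||R A_c - B_c||_F with det(R) = +1
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  M <- t(Bc) %*% Ac
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

## monotone non-increasing trace check with relative slack
expect_monotone_trace <- function(trace, slack = 1e-9) {
  if (length(trace) < 2L) return(invisible(TRUE))
  ok <- diff(trace) <= slack * pmax(1, abs(trace[-length(trace)]))
  expect_true(all(ok), info = paste("objective increased at iteration",
                                    paste(which(!ok), collapse = ", ")))
}

## flatten/unflatten shorthand used across tests
flat <- pedicleSSM:::.flattenShape
unflat <- pedicleSSM:::.unflattenShape

## fractions of the realized planted population: eigenvalues of
## diag(sd) cov(W) diag(sd) (the covariance actually sampled)
plantedFractions <- function(truth) {
  C <- diag(truth@sds) %*% stats::cov(truth@weights) %*% diag(truth@sds)
  ev <- eigen(C, symmetric = TRUE)$values
  ev / sum(ev)
}

## largest principal angle (degrees) between the column spaces of A and B
maxPrincipalAngle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  max(acos(pmin(1, s))) * 180 / pi
}

## realized planted variance structure vs the recovered model: the
## eigen-directions of the realized 3x3 mode covariance are carried into
## shape space, mapped into the model frame (reference permutation and
## pose), and each is matched to the best-aligned recovered component.
## Returns recovered and true fraction triples.
recoveredPlantedFractions <- function(ct, truth) {
  C <- diag(truth@sds) %*% stats::cov(truth@weights) %*% diag(truth@sds)
  eg <- eigen(C, symmetric = TRUE)
  pm1 <- truth@permutations[[1]]
  if (is.null(pm1)) pm1 <- seq_len(nrow(truth@templatePoints))
  R1 <- truth@poses[[1]]@rotation
  Ushape <- truth@modeDirections %*% eg$vectors
  M <- ct$model@modes
  sdj <- ct$model@sd
  v <- numeric(ncol(Ushape))
  used <- integer(0)
  for (k in seq_len(ncol(Ushape))) {
    uk <- matrix(Ushape[, k], ncol = 3, byrow = TRUE)[pm1, ,
                                                      drop = FALSE] %*%
      t(R1)
    al <- abs(as.numeric(crossprod(M, as.numeric(t(uk)))))
    al[used] <- -1
    j <- which.max(al)
    used <- c(used, j)
    v[k] <- sdj[j]^2
  }
  list(recovered = v / sum(v), planted = eg$values / sum(eg$values))
}

## independent Croux--Ruiz-Gazen oracle: plain-loop projection pursuit
## with observation candidates (variance index), written separately from
## the implementation it checks
ppOracle <- function(X, K) {
  Xc <- sweep(X, 2, colMeans(X))
  Z <- Xc
  dirs <- NULL; scales <- numeric(0)
  for (k in seq_len(K)) {
    best <- -Inf; bestDir <- NULL
    for (i in seq_len(nrow(Z))) {
      nrm <- sqrt(sum(Z[i, ]^2))
      if (nrm <= 1e-12) next
      a <- Z[i, ] / nrm
      s <- stats::sd(Xc %*% a)
      if (s > best) { best <- s; bestDir <- a }
    }
    if (is.null(bestDir) || best <= 1e-12) break
    dirs <- cbind(dirs, bestDir)
    scales <- c(scales, best)
    for (i in seq_len(nrow(Z)))
      Z[i, ] <- Z[i, ] - sum(Z[i, ] * bestDir) * bestDir
  }
  ord <- order(scales, decreasing = TRUE)
  list(directions = dirs[, ord, drop = FALSE], scales = scales[ord])
}

table1Path <- function() {
  system.file("extdata", "pedicle_dimension_table.csv",
              package = "pedicleSSM")
}
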