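test_that("model building: contracts, capping, degenerate populations", {
  X <- matrix(rnorm(5 * 12), 5, 12)
  pop <- correspondedPopulation(X)
  expect_error(buildShapeModel(correspondedPopulation(X[1, , drop = FALSE])),
               "at least 2")
  expect_warning(m <- buildShapeModel(pop, method = "classical_pca",
                                      K = 10L), "capping")
  expect_lte(ncol(m@modes), 4L)
  ## identical shapes: degenerate model with zero spread and the shape as
  ## its mean
  same <- correspondedPopulation(matrix(rep(X[1, ], 4), 4, 12,
                                        byrow = TRUE))
  md <- buildShapeModel(same)
  expect_true(md@degenerate)
  expect_true(all(md@sd == 0))
  expect_equal(md@mean, X[1, ])
})

test_that("classical PCA recovers a planted 2-plane exactly", {
  set.seed(51)
  p <- 30
  B <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
  scores <- matrix(rnorm(20 * 2, sd = c(4, 2)), 20, 2, byrow = TRUE)
  X <- scores %*% t(B) + matrix(rep(rnorm(p), each = 20), 20, p)
  m <- buildShapeModel(correspondedPopulation(X), method = "classical_pca")
  ang <- maxPrincipalAngle(m@modes[, 1:2, drop = FALSE], B)
  expect_lt(ang * pi / 180, 1e-6)
})

test_that("training shapes reconstruct exactly from all n-1 components", {
  set.seed(52)
  X <- matrix(rnorm(12 * 30, sd = 3), 12, 30)
  pop <- correspondedPopulation(X)
  m <- buildShapeModel(pop, method = "classical_pca")
  for (i in c(1L, 7L)) {
    r <- X[i, ] - m@mean
    w <- crossprod(m@modes, r)
    rec <- m@mean + as.numeric(m@modes %*% w)
    expect_lt(max(abs(rec - X[i, ])), 1e-6)
  }
})

test_that("ppPCA: scales match the brute-force candidate search and are
          bounded by classical eigenvalues", {
  set.seed(53)
  X <- matrix(rnorm(15 * 21, sd = 2), 15, 21)
  pop <- correspondedPopulation(X)
  mp <- buildShapeModel(pop, method = "pp_pca", index = "variance", K = 4L)
  mc <- buildShapeModel(pop, method = "classical_pca")
  ## full plain-loop oracle: every component's scale and direction must
  ## match the brute-force candidate search with deflation
  orc <- ppOracle(X, 4L)
  expect_equal(mp@sd, orc$scales, tolerance = 1e-10)
  expect_lt(max(abs(abs(colSums(mp@modes * orc$directions)) - 1)), 1e-8)
  ## the leading pp scale cannot exceed the leading eigen-scale, and the
  ## cumulative pp variance is majorised by the eigen-spectrum
  expect_lte(mp@sd[1L], mc@sd[1L] + 1e-10)
  k <- min(ncol(mp@modes), ncol(mc@modes))
  expect_true(all(cumsum(mp@sd[1:k]^2) <= cumsum(mc@sd[1:k]^2) + 1e-8))
  ## orthonormal modes, fractions sum to one, sd non-increasing
  expect_lt(max(abs(crossprod(mp@modes) - diag(ncol(mp@modes)))), 1e-8)
  expect_equal(sum(mp@varianceFractions), 1, tolerance = 1e-9)
  expect_true(all(diff(mp@sd) <= 1e-12))
})

test_that("robust projection indices are usable and deflation-orthogonal", {
  set.seed(54)
  X <- matrix(rnorm(12 * 12), 12, 12)
  X[1, ] <- X[1, ] + 20   # gross outlier
  for (idx in c("mad", "qn")) {
    m <- buildShapeModel(correspondedPopulation(X), method = "pp_pca",
                         index = idx, K = 3L)
    expect_lt(max(abs(crossprod(m@modes) - diag(ncol(m@modes)))), 1e-8)
    expect_true(all(m@sd >= 0))
  }
})

test_that("component selection applies the >threshold rule", {
  fr <- c(0.20, 0.12, 0.077, 0.04, rep(0.563 / 20, 20))
  sd_ <- sqrt(fr)
  m2 <- new("ShapeModel", mean = numeric(30),
            modes = diag(1, 30)[, seq_along(fr)], sd = sd_,
            varianceFractions = fr, nTrain = 30L,
            method = "classical_pca", index = "variance")
  expect_identical(selectComponents(m2, 0.05), 1:3)
  expect_identical(selectComponents(m2, 0.5), integer(0))
  expect_identical(selectComponents(m2, 0), seq_along(fr))
  ## the retention rule yields a prefix of the (sorted) component order
  expect_identical(selectComponents(m2, 0.05),
                   seq_len(length(selectComponents(m2, 0.05))))
})

test_that("shape synthesis is linear in the weights", {
  spec <- syntheticSpec(nShapes = 12, pointsPerShape = 300, seed = 55,
                        noiseSD = 0.02)
  p <- samplePopulation(spec)
  X <- do.call(rbind, lapply(p$shapes, function(s) flat(shapePoints(s))))
  m <- buildShapeModel(correspondedPopulation(X), method = "classical_pca")
  expect_equal(flat(shapePoints(synthesizeShape(m))), m@mean)
  plus <- flat(shapePoints(synthesizeShape(m, 3, pc = 1L)))
  minus <- flat(shapePoints(synthesizeShape(m, -3, pc = 1L)))
  expect_lt(max(abs(plus + minus - 2 * m@mean)), 1e-9)
  ## single-known-mode model: +1 SD displaces by exactly sd1 * mode1
  m1 <- new("ShapeModel", mean = m@mean,
            modes = m@modes[, 1L, drop = FALSE], sd = m@sd[1L],
            varianceFractions = 1, nTrain = m@nTrain,
            method = "classical_pca", index = "variance")
  s1 <- flat(shapePoints(synthesizeShape(m1, 1)))
  expect_lt(max(abs(s1 - (m@mean + m@sd[1L] * m@modes[, 1L]))), 1e-12)
  expect_warning(synthesizeShape(m1, 11), "10 SD")
  expect_error(synthesizeShape(m1, c(1, 2)), "more weights")
})

test_that("leave-one-out: contracts, in-subspace floor, identical shapes", {
  X <- matrix(rnorm(2 * 12), 2, 12)
  expect_error(looRMSE(correspondedPopulation(X)), "at least 3")
  spec <- syntheticSpec(nShapes = 10, pointsPerShape = 200, seed = 56,
                        noiseSD = 0)
  p <- samplePopulation(spec)
  r <- looRMSE(correspondedPopulation(p$truth@cleanMatrix))
  expect_lt(r$overall, 1e-6)
  expect_length(r$perFold, 10L)
  same <- correspondedPopulation(matrix(rep(rnorm(12), 3), 3, 12,
                                        byrow = TRUE))
  expect_lt(looRMSE(same)$overall, 1e-12)
})

test_that("partial-shape fitting recovers known weights and completes", {
  spec <- syntheticSpec(nShapes = 15, pointsPerShape = 300, seed = 57,
                        noiseSD = 0.02)
  p <- samplePopulation(spec)
  X <- do.call(rbind, lapply(p$shapes, function(s) flat(shapePoints(s))))
  m <- buildShapeModel(correspondedPopulation(X), method = "classical_pca",
                       K = 5L)
  wTrue <- c(1.5, -0.8, 0.4, 0, 0.9)
  full <- shapePoints(synthesizeShape(m, wTrue))
  fit <- fitToPartial(m, full, observedIdx = seq_len(nrow(full)))
  expect_lt(max(abs(fit$weights - wTrue)), 1e-6)
  expect_lt(fit$rms, 1e-9)
  ## 60% of the points still identify the weights exactly (noiseless)
  keep <- seq_len(round(0.6 * nrow(full)))
  fit2 <- fitToPartial(m, full[keep, , drop = FALSE], observedIdx = keep)
  expect_lt(max(abs(fit2$weights - wTrue)), 1e-6)
  ## completed shape matches the held-out region
  comp <- shapePoints(fit2$completed)
  expect_lt(max(abs(comp - full)), 1e-6)
  ## heavy ridge shrinks to the mean shape
  fit3 <- fitToPartial(m, full, observedIdx = seq_len(nrow(full)),
                       ridge = 1e12)
  expect_lt(max(abs(fit3$weights)), 1e-3)
  expect_lt(max(abs(shapePoints(fit3$completed) - unflat(m@mean))), 0.05)
  expect_error(fitToPartial(m, full[0, , drop = FALSE],
                            observedIdx = integer(0)), "empty")
})
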