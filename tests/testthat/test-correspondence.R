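test_that("relevance sampling: contracts and determinism", {
  pts <- randomCloud(100, seed = 31)
  ps <- pointSet(pts)
  expect_identical(relevanceSample(ps, 100L), seq_len(100L))
  expect_error(relevanceSample(ps, 101L), "exceeds")
  s1 <- relevanceSample(ps, 30L, strategy = "curvature_fps", seed = 1L)
  s2 <- relevanceSample(ps, 30L, strategy = "curvature_fps", seed = 1L)
  expect_identical(s1, s2)
  expect_identical(anyDuplicated(s1), 0L)
  r1 <- relevanceSample(ps, 30L, strategy = "random", seed = 5L)
  r2 <- relevanceSample(ps, 30L, strategy = "random", seed = 5L)
  expect_identical(r1, r2)
})

test_that("FPS spreads samples wider than random sampling on a sphere", {
  sph <- pedicleSSM:::.goldenSphere(400)
  ps <- pointSet(sph)
  fps <- relevanceSample(ps, 50L, strategy = "uniform_fps")
  rnd <- relevanceSample(ps, 50L, strategy = "random", seed = 1L)
  minGap <- function(idx) {
    d2 <- pedicleSSM:::.dist2(sph[idx, ], sph[idx, ])
    diag(d2) <- Inf
    sqrt(min(d2))
  }
  expect_gte(minGap(fps), minGap(rnd))
})

test_that("curvature-weighted FPS samples a bump denser than the plane", {
  g <- as.matrix(expand.grid(x = seq(-10, 10, 0.8),
                             y = seq(-10, 10, 0.8)))
  z <- 3 * exp(-(g[, 1]^2 + g[, 2]^2) / 4)   # central bump
  pts <- cbind(g, z)
  ps <- pointSet(pts)
  sel <- relevanceSample(ps, 120L, strategy = "curvature_fps")
  r <- sqrt(g[, 1]^2 + g[, 2]^2)
  bumpArea <- sum(r < 4); planeArea <- sum(r > 6)
  bumpSel <- sum(r[sel] < 4); planeSel <- sum(r[sel] > 6)
  density <- c(bump = bumpSel / bumpArea, plane = planeSel / planeArea)
  expect_gte(density[["bump"]], 1.5 * density[["plane"]])
})

test_that("coarse non-rigid CPD: self-registration and large-lambda limit", {
  tm <- makeTemplate(syntheticSpec(pointsPerShape = 300))$mesh
  pts <- shapePoints(tm)
  diam <- max(dist(pts[sample(nrow(pts), 50), ]))
  r <- nonrigidCPDCoarse(pts, pts, beta = 4, lambda = 1)
  disp <- sqrt(rowSums((r$deformed - pts)^2))
  expect_lt(max(disp), 1e-3 * diam)
  expect_monotone_trace(r$trace)
  ## lambda -> very large: displacement field collapses to near-uniform
  tgt <- pts + matrix(c(2, 1, -1), nrow(pts), 3, byrow = TRUE)
  rL <- nonrigidCPDCoarse(pts, tgt, beta = 4, lambda = 1e9)
  d <- rL$deformed - pts
  expect_lt(max(apply(d, 2, var)), 1e-3)
  expect_monotone_trace(rL$trace)
})

test_that("coarse non-rigid CPD recovers a smooth sinusoidal bend", {
  g <- as.matrix(expand.grid(x = seq(0, 20, 1.5), y = seq(0, 20, 1.5),
                             z = 0))
  amp <- 2
  s <- g; s[, 3] <- amp * sin(g[, 1] / 6)
  r <- nonrigidCPDCoarse(g, s, beta = 5, lambda = 1)
  resid <- mean(sqrt(rowSums((r$deformed - s)^2)))
  expect_lt(resid, 0.1 * amp)
  expect_monotone_trace(r$trace)
  ## conditioning guard: absurdly wide kernel on a tight cluster
  tiny <- randomCloud(30, scale = 1e-4, seed = 3)
  expect_error(nonrigidCPDCoarse(tiny, tiny, beta = 1e6, lambda = 1),
               "beta")
})

test_that("deformation fields evaluate consistently off their controls", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 2), y = seq(0, 10, 2), z = 0))
  s <- g; s[, 3] <- sin(g[, 1] / 3)
  r <- nonrigidCPDCoarse(g, s, beta = 4, lambda = 1)
  ## evaluating at the control points reproduces the deformed controls
  ev <- evaluateField(r$field, g)
  expect_lt(max(abs(ev - r$deformed)), 1e-9)
})

test_that("local refinement: trivial case and the exhaustive NN oracle", {
  tm <- makeTemplate(syntheticSpec(pointsPerShape = 200))$mesh
  pts <- shapePoints(tm)
  cm <- localRefine(pts, pointSet(pts), stiffness = 1)
  expect_lt(max(cm@residuals), 1e-9)
  expect_lt(max(abs(cm@coordinates - pts)), 1e-9)
  ## stiffness 0, point targets: each point snaps to its nearest sample
  samp <- randomCloud(150, scale = 12, seed = 33)
  cm0 <- localRefine(pts, pointSet(samp), stiffness = 0, iterations = 1L)
  expect_lt(max(abs(cm0@coordinates - nnOracle(pts, samp))), 1e-12)
  expect_error(localRefine(pts, matrix(numeric(0), 0, 3)), "empty")
})

test_that("refinement improves on the coarse stage for ground-truth warps", {
  g <- as.matrix(expand.grid(x = seq(0, 20, 1.5), y = seq(0, 20, 1.5),
                             z = 0))
  s <- g; s[, 3] <- 2 * sin(g[, 1] / 6)
  r <- nonrigidCPDCoarse(g, s, beta = 6, lambda = 3, maxIterations = 30L)
  coarseErr <- sqrt(mean(rowSums((r$deformed - s)^2)))
  cm <- localRefine(r$deformed, pointSet(s), stiffness = 0.5)
  fineErr <- sqrt(mean(rowSums((cm@coordinates - s)^2)))
  expect_lt(fineErr, coarseErr)
})

test_that("population correspondence: identity, permutation, known warps", {
  spec <- syntheticSpec(nShapes = 3, pointsPerShape = 300, seed = 41,
                        noiseSD = 0.02)
  p <- samplePopulation(spec)
  tm <- p$template$mesh
  ## single sample equal to the template
  self <- correspondPopulation(tm, list(as(tm, "PointSet")),
                               params = correspondenceParams())
  expect_lt(max(abs(self@shapes[1, ] - flat(shapePoints(tm)))), 1e-3)

  ## known smooth warps: per-point error bounded by noise + 5% of max
  ## warp. The samples already live in the template frame, so the
  ## modulo-rigid polish is disabled to compare against the raw truth.
  pop <- correspondPopulation(tm, p$shapes,
                              params = correspondenceParams(
                                procrustesPolish = FALSE))
  maxWarp <- max(vapply(1:3, function(i) max(sqrt(rowSums(
    (unflat(p$truth@cleanMatrix[i, ]) - shapePoints(tm))^2))),
    numeric(1)))
  for (i in seq_len(3)) {
    est <- unflat(pop@shapes[i, ])
    tru <- unflat(p$truth@cleanMatrix[i, ])
    err <- sqrt(rowSums((est - tru)^2))
    expect_lt(mean(err), spec@noiseSD + 0.05 * max(maxWarp, 1))
  }

  ## permuting sample vertex order leaves the result unchanged
  set.seed(99)
  pm <- sample.int(nPoints(p$shapes[[2]]))
  permuted <- pointSet(shapePoints(p$shapes[[2]])[pm, ], id = "perm")
  a <- correspondPopulation(tm, list(p$shapes[[2]]),
                            params = correspondenceParams())
  b <- correspondPopulation(tm, list(permuted),
                            params = correspondenceParams())
  expect_lt(max(abs(a@shapes - b@shapes)), 1e-6)
})

test_that("correspondence is deterministic given seeds and config", {
  spec <- syntheticSpec(nShapes = 2, pointsPerShape = 250, seed = 43,
                        noiseSD = 0.05, scramble = "rigid")
  p <- samplePopulation(spec)
  al <- alignPopulation(p$shapes)
  a <- correspondPopulation(al$reference, al$aligned,
                            params = correspondenceParams(seed = 3L))
  b <- correspondPopulation(al$reference, al$aligned,
                            params = correspondenceParams(seed = 3L))
  expect_identical(a@shapes, b@shapes)
})
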