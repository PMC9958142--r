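test_that("transform algebra: apply, invert, compose, closed forms", {
  t1 <- rigidTransform(rotZ(90), c(0, 0, 0))
  expect_equal(as.numeric(applyTransform(t1, matrix(c(1, 0, 0), 1L))),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(4)
  t2 <- rigidTransform(rotAxis(c(1, 2, 3), 37), c(4, -1, 2))
  pts <- randomCloud(50, seed = 5)
  back <- applyTransform(invertTransform(t2), applyTransform(t2, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  t3 <- composeTransform(t2, invertTransform(t2))
  expect_lt(max(abs(t3@rotation - diag(3))), 1e-9)
  expect_lt(max(abs(t3@translation)), 1e-9)
  ## identity transform leaves a PointSet unchanged
  ps <- pointSet(pts, labels = rep("body", 50), id = "x")
  out <- applyTransform(rigidTransform(), ps)
  expect_equal(shapePoints(out), pts)
  expect_identical(regionLabels(out), regionLabels(ps))
  ## 12-number record round-trip
  rec <- transformToRecord(t2)
  expect_length(rec, 12L)
  t4 <- recordToTransform(rec)
  expect_lt(max(abs(t4@rotation - t2@rotation)), 1e-9)
})

test_that("rigid CPD: identity, known transform, clutter", {
  pts <- randomCloud(200, seed = 7)
  fit <- rigidCPD(pts, pts, rigidCPDParams(w = 0))
  expect_lt(rotationAngle(fit$transform@rotation), 1e-6 * 180 / pi + 1e-6)
  expect_lt(sqrt(sum(fit$transform@translation^2)), 1e-6)
  expect_monotone_trace(fit$trace)

  src <- randomCloud(150, seed = 8)
  R <- rotZ(30); tt <- c(5, -3, 2)
  tgt <- src %*% t(R) + matrix(tt, 150, 3, byrow = TRUE)
  fit2 <- rigidCPD(src, tgt, rigidCPDParams(w = 0))
  expect_lt(rotationAngle(t(fit2$transform@rotation) %*% R), 0.01)
  expect_lt(sqrt(sum((fit2$transform@translation - tt)^2)), 1e-3)
  expect_monotone_trace(fit2$trace)

  ## 10% uniform clutter in the target, outlier weight 0.1
  set.seed(9)
  clutter <- matrix(runif(45, -25, 25), 15, 3)
  fit3 <- rigidCPD(src, rbind(tgt, clutter), rigidCPDParams(w = 0.1))
  expect_lt(rotationAngle(t(fit3$transform@rotation) %*% R), 1)
  expect_monotone_trace(fit3$trace)
})

test_that("M-step rotation equals the orthogonal-Procrustes oracle", {
  src <- randomCloud(80, seed = 10)
  R <- rotAxis(c(0, 1, 1), 25)
  tgt <- src %*% t(R) + matrix(c(1, 2, 3), 80, 3, byrow = TRUE)
  ## perfect correspondence: P = identity
  ms <- pedicleSSM:::.rigidMStep(tgt, src, diag(80))
  Ro <- procrustesOracle(src, tgt)
  expect_lt(max(abs(ms$R - Ro)), 1e-9)
  expect_lt(max(abs(ms$R - R)), 1e-9)
  expect_equal(det(ms$R), 1, tolerance = 1e-9)
})

test_that("rigid CPD is equivariant under a common rigid motion", {
  src <- randomCloud(120, seed = 12)
  tgt <- src %*% t(rotZ(20)) + matrix(c(2, 0, -1), 120, 3, byrow = TRUE)
  base <- rigidCPD(src, tgt, rigidCPDParams())
  g <- rigidTransform(rotAxis(c(1, 0, 2), 40), c(-3, 7, 1))
  fit <- rigidCPD(applyTransform(g, src), applyTransform(g, tgt),
                  rigidCPDParams())
  ## conjugation: T' = g T g^{-1}
  conj <- composeTransform(composeTransform(g, base$transform),
                           invertTransform(g))
  expect_lt(max(abs(fit$transform@rotation - conj@rotation)), 1e-6)
  expect_lt(max(abs(fit$transform@translation - conj@translation)), 1e-5)
})

test_that("degenerate and non-converging inputs are handled", {
  degen <- matrix(1, 10, 3) + 1e-16
  expect_error(rigidCPD(degen, randomCloud(10)), "degenerate")
  src <- randomCloud(60, seed = 13)
  tgt <- src %*% t(rotZ(25))
  expect_warning(rigidCPD(src, tgt, rigidCPDParams(maxIterations = 2L)),
                 "converge")
})

test_that("population alignment brings random poses to a common frame", {
  base <- makeTemplate(syntheticSpec(pointsPerShape = 300))$mesh
  set.seed(21)
  shapes <- lapply(1:3, function(i) {
    tf <- rigidTransform(pedicleSSM:::.randomRotation(), runif(3, -20, 20))
    out <- applyTransform(tf, as(base, "PointSet"))
    out@id <- sprintf("s%d", i)
    out
  })
  al <- alignPopulation(shapes)
  expect_length(al$failures, 0L)
  A <- shapePoints(al$aligned[[1L]])
  for (i in 2:3) {
    B <- shapePoints(al$aligned[[i]])
    expect_lt(sqrt(mean(rowSums((A - B)^2))), 1e-3)
  }
  ## population of one: identity transform
  one <- alignPopulation(shapes[1L])
  expect_identical(one$aligned[[1L]], shapes[[1L]])
  expect_lt(max(abs(one$transforms[[1L]]@rotation - diag(3))), 1e-12)
  ## unequal point counts are accepted (unrelated clouds may warn about
  ## non-convergence, which is the documented behaviour)
  mixed <- list(pointSet(randomCloud(100, seed = 1), id = "a"),
                pointSet(randomCloud(140, seed = 2), id = "b"))
  expect_length(suppressWarnings(alignPopulation(mixed))$aligned, 2L)
})
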