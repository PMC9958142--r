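test_that("the template satisfies its construction contract", {
  spec <- syntheticSpec(pointsPerShape = 800)
  tm <- makeTemplate(spec)
  expect_equal(nPoints(tm$mesh), 800L)
  labs <- regionLabels(tm$mesh)
  for (r in c("body", "pedicle_L", "pedicle_R", "lamina",
              "transverse_process_L", "transverse_process_R",
              "spinous_process"))
    expect_true(r %in% labs)
  ## landmark closed forms
  expect_equal(pedicleWidth(tm$landmarks),
               2 * spec@params[["pedicle_radius_w"]], tolerance = 1e-6)
  expect_equal(pedicleHeight(tm$landmarks),
               2 * spec@params[["pedicle_radius_h"]], tolerance = 1e-6)
  m <- measurePedicle(tm$landmarks)
  expect_equal(m@transverseAngle, spec@params[["transverse_angle"]],
               tolerance = 0.1)
  expect_equal(m@sagittalAngle, spec@params[["sagittal_angle"]],
               tolerance = 0.1)
  ## both sides measure identically by symmetry
  mR <- measurePedicle(makeTemplate(spec, side = "right")$landmarks)
  expect_equal(mR@transverseAngle, m@transverseAngle, tolerance = 1e-6)
  ## impossible geometry is rejected
  expect_error(syntheticSpec(params = c(pedicle_radius_w = 20)),
               "pedicle radius")
})

test_that("a tilted endplate is recovered to 0.1 degree", {
  l <- makeTemplate(syntheticSpec())$landmarks
  tilt <- rotAxis(c(0, 1, 0), 7)
  l2 <- l
  l2@endplate <- l@endplate %*% t(tilt)
  pl <- endplatePlane(l2)
  trueNormal <- as.numeric(tilt %*% c(0, 0, 1))
  ang <- acos(min(1, abs(sum(pl$normal * trueNormal)))) * 180 / pi
  expect_lt(ang, 0.1)
})

test_that("population sampling: degenerate, statistical and closed-form checks", {
  ## no modes, no noise, no scramble: every shape equals the template
  spec0 <- syntheticSpec(nShapes = 3, pointsPerShape = 300, noiseSD = 0,
                         modes = list())
  p0 <- samplePopulation(spec0)
  tpl <- shapePoints(p0$template$mesh)
  for (s in p0$shapes) expect_equal(shapePoints(s), tpl)

  ## weight means obey a CLT bound at n = 1000
  spec1 <- syntheticSpec(nShapes = 1000, pointsPerShape = 200, seed = 8,
                         noiseSD = 0)
  p1 <- samplePopulation(spec1)
  expect_true(all(abs(colMeans(p1$truth@weights)) <= 0.1))

  ## planted pedicle-width mode: population width SD matches closed form
  spec2 <- syntheticSpec(nShapes = 400, pointsPerShape = 300, seed = 82,
                         noiseSD = 0,
                         modes = list(list(name = "pw",
                                           parameter = "pedicle_radius_w",
                                           sd = 0.5)))
  p2 <- samplePopulation(spec2)
  widths <- vapply(seq_len(400), function(i)
    pedicleWidth(truthLandmarks(p2$truth, i)), numeric(1))
  ## width = 2 * r_w; delta r_w per SD = sd_eff / |dT/dr_w|
  md <- pedicleSSM:::.modeDirections(spec2)
  sdWidth <- 2 * p2$truth@sds[1] / md$gnorm[1]
  expect_lt(abs(sd(widths) - sdWidth) / sdWidth, 0.15)
})

test_that("planted modes are orthonormal with disjoint regional support", {
  spec <- syntheticSpec(pointsPerShape = 500)
  md <- pedicleSSM:::.modeDirections(spec)
  expect_lt(max(abs(crossprod(md$U) - diag(3))), 1e-12)
  expect_equal(md$support[1], md$support[2])
  expect_equal(md$support[1], md$support[3])
  labs <- regionLabels(makeTemplate(spec)$mesh)
  ## the transverse-process mode moves only transverse-process points
  moved <- pedicleSSM:::.pointNorms(md$U[, 1]) > 1e-12
  expect_true(all(grepl("transverse_process", labs[moved])))
})

test_that("ground-truth landmarks follow deformation and pose", {
  spec <- syntheticSpec(nShapes = 4, pointsPerShape = 300, seed = 83,
                        noiseSD = 0, scramble = "rigid")
  p <- samplePopulation(spec)
  for (i in 1:2) {
    lm <- truthLandmarks(p$truth, i)
    ## equivariance: landmarks equal pose * (deformed template landmarks)
    lm0 <- pedicleSSM:::.templateLandmarks(p$truth@paramValues[i, ],
                                           "left")
    lmP <- applyTransform(p$truth@poses[[i]], lm0)
    expect_lt(max(abs(lm@superior - lmP@superior)), 1e-9)
    ## measured width equals the perturbed-radius closed form
    expect_equal(pedicleWidth(lm),
                 unname(2 * p$truth@paramValues[i, "pedicle_radius_w"]),
                 tolerance = 1e-6)
  }
  ## unscrambled zero-weight shape reproduces the template landmarks
  spec0 <- syntheticSpec(nShapes = 2, pointsPerShape = 300, noiseSD = 0,
                         modes = list())
  p0 <- samplePopulation(spec0)
  l0 <- truthLandmarks(p0$truth, 1L)
  lt <- p0$template$landmarks
  expect_lt(max(abs(l0@medial - lt@medial)), 1e-12)
})

test_that("the generator is bit-reproducible and levels pool correctly", {
  spec <- syntheticSpec(nShapes = 3, pointsPerShape = 200, seed = 84,
                        noiseSD = 0.05, scramble = "rigid+permute")
  a <- samplePopulation(spec)
  b <- samplePopulation(spec)
  for (i in 1:3)
    expect_identical(shapePoints(a$shapes[[i]]), shapePoints(b$shapes[[i]]))
  expect_identical(a$truth@weights, b$truth@weights)

  lv <- syntheticSpec(nShapes = 2, nLevels = 3, pointsPerShape = 200,
                      seed = 85, noiseSD = 0)
  pl <- samplePopulation(lv)
  expect_length(pl$shapes, 6L)
  expect_true(all(grepl("^L[123]_", vapply(pl$shapes, shapeID, ""))))
  ## level offsets change the body size monotonically
  bodyWidth <- function(s)
    max(shapePoints(s)[regionLabels(s) == "body", 2])
  expect_lt(bodyWidth(pl$shapes[[1]]), bodyWidth(pl$shapes[[5]]))
})

test_that("unscrambled populations are corresponded and recover modes", {
  spec <- syntheticSpec(nShapes = 60, pointsPerShape = 500, seed = 86,
                        noiseSD = 0.05)
  p <- samplePopulation(spec)
  X <- do.call(rbind, lapply(p$shapes, function(s) flat(shapePoints(s))))
  m <- buildShapeModel(correspondedPopulation(X),
                       method = "classical_pca", K = 10L)
  ang <- maxPrincipalAngle(m@modes[, 1:3], p$truth@modeDirections)
  expect_lt(ang, 8)
})
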