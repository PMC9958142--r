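## A hand-built landmark set with known geometry: margins on a circle in
## the x = 0 plane around the origin, axis target on +x, endplate z = 0.
simpleLandmarks <- function(axisDirDeg = 0, elevDeg = 0) {
  d <- c(cos(elevDeg * pi / 180) * cos(axisDirDeg * pi / 180),
         cos(elevDeg * pi / 180) * sin(axisDirDeg * pi / 180),
         sin(elevDeg * pi / 180))
  pedicleLandmarks(
    superior = c(0, 0, 1), inferior = c(0, 0, -1),
    lateral = c(0, 2.8, 0), medial = c(0, -2.8, 0),
    endplate = rbind(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5)),
    anteriorBody = c(10, 0, 0), posteriorSpinous = c(-20, 0, 0),
    axisTarget = 10 * d, side = "left")
}

test_that("pedicle width and height are margin distances, symmetric", {
  l <- pedicleLandmarks(superior = c(0, 0, 10.5), inferior = c(0, 0, 0),
                        lateral = c(5.6, 0, 3), medial = c(0, 0, 3),
                        endplate = rbind(c(0, 0, 12), c(1, 0, 12),
                                         c(0, 1, 12)),
                        anteriorBody = c(20, 0, 6),
                        posteriorSpinous = c(-20, 0, 6),
                        axisTarget = c(10, 0, 3))
  expect_equal(pedicleWidth(l), 5.6)
  expect_equal(pedicleHeight(l), 10.5)
  ## swapping the pair leaves the distance unchanged
  l2 <- l; l2@medial <- l@lateral; l2@lateral <- l@medial
  expect_equal(pedicleWidth(l2), pedicleWidth(l))
})

test_that("endplate plane: orientation rule and equivariance", {
  l <- simpleLandmarks()
  l@endplate <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  l@superior <- c(0, 0, 1)   # cranial side above the plane
  pl <- endplatePlane(l)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  ## rigid equivariance of the whole measurement set
  g <- rigidTransform(rotAxis(c(2, 1, 1), 33), c(4, -2, 9))
  lg <- applyTransform(g, l)
  plg <- endplatePlane(lg)
  expect_lt(max(abs(plg$normal - as.numeric(g@rotation %*% pl$normal))),
            1e-9)
  bad <- l
  bad@endplate <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(validObject(bad), "collinear")
})

test_that("midline projects the body/spinous extremes into the plane", {
  l <- simpleLandmarks()
  pl <- list(normal = c(0, 0, 1), offset = 0)
  ## points already in the plane
  l@anteriorBody <- c(10, 0, 0); l@posteriorSpinous <- c(-20, 0, 0)
  expect_equal(midlineDirection(l, pl), c(1, 0, 0))
  ## out-of-plane points give the same answer as their projections
  l@anteriorBody <- c(10, 0, 7); l@posteriorSpinous <- c(-20, 0, -4)
  expect_equal(midlineDirection(l, pl), c(1, 0, 0))
  l@posteriorSpinous <- c(10, 0, 3)   # projections coincide
  expect_error(midlineDirection(l, pl), "midline")
})

test_that("pedicle axis runs from the margin centroid to the target", {
  l <- simpleLandmarks()
  ax <- pedicleAxis(l)
  expect_equal(ax$point, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ax$direction, c(1, 0, 0), tolerance = 1e-12)
  l@axisTarget <- c(0, 0, 0)
  expect_error(pedicleAxis(l), "centroid")
})

test_that("transverse and sagittal angles reproduce constructed values", {
  pl <- list(normal = c(0, 0, 1), offset = 0)
  mid <- c(1, 0, 0)
  ## in-plane axis at an exact 10 degrees
  ax10 <- list(point = c(0, 0, 0),
               direction = c(cos(10 * pi / 180), sin(10 * pi / 180), 0))
  expect_equal(transverseAngle(ax10, mid, pl), 10, tolerance = 1e-6)
  ## parallel and orthogonal limits
  expect_equal(transverseAngle(list(direction = mid), mid, pl), 0)
  expect_equal(transverseAngle(list(direction = c(0, 1, 0)), mid, pl), 90)
  expect_error(transverseAngle(list(direction = c(0, 0, 1)), mid, pl),
               "perpendicular")
  ## sagittal: in-plane, along-normal, and a 14.2 degree elevation
  expect_equal(sagittalAngle(list(direction = c(1, 0, 0)), pl), 0)
  expect_equal(sagittalAngle(list(direction = c(0, 0, 1)), pl), 90)
  e <- 14.2 * pi / 180
  expect_equal(sagittalAngle(list(direction = c(cos(e), 0, sin(e))), pl),
               14.2, tolerance = 1e-6)
})

test_that("all measurements are rigid-invariant", {
  spec <- syntheticSpec()
  l <- makeTemplate(spec)$landmarks
  m0 <- measurePedicle(l)
  set.seed(71)
  for (rep in 1:3) {
    g <- rigidTransform(pedicleSSM:::.randomRotation(), runif(3, -50, 50))
    m1 <- measurePedicle(applyTransform(g, l))
    expect_equal(m1@width, m0@width, tolerance = 1e-6)
    expect_equal(m1@height, m0@height, tolerance = 1e-6)
    expect_equal(m1@transverseAngle, m0@transverseAngle, tolerance = 1e-6)
    expect_equal(m1@sagittalAngle, m0@sagittalAngle, tolerance = 1e-6)
  }
})

test_that("repeat aggregation averages and halves the range", {
  mk <- function(w) new("PedicleMeasurement", width = w, height = 10,
                        transverseAngle = 8, sagittalAngle = 14)
  agg <- aggregateRepeats(list(mk(5.5), mk(5.6), mk(5.7)))
  expect_equal(agg@width, 5.6)
  expect_equal(agg@repeatError[["width"]], 0.1)
  same <- aggregateRepeats(list(mk(5.5), mk(5.5)))
  expect_equal(same@repeatError[["width"]], 0)
  expect_error(aggregateRepeats(list(mk(5))), "2 repeats")
  ## repeats drawn from a known +/- 0.2 uniform window
  set.seed(72)
  draws <- lapply(runif(6, 5.4, 5.8), mk)
  expect_lte(aggregateRepeats(draws)@repeatError[["width"]], 0.2)
})

test_that("guide envelope reproduces the published worked example", {
  tab <- read.csv(table1Path())
  env <- guideEnvelope(tab)
  g <- function(d, col) env[env$dimension == d, col]
  expect_equal(g("transverse_angle", "min"), 3.5)
  expect_equal(g("transverse_angle", "max"), 12.4)
  expect_equal(g("pedicle_width", "min"), 4.7)
  expect_equal(g("pedicle_width", "max"), 6.2)
  ## single entry: degenerate range
  one <- guideEnvelope(data.frame(dimension = "pedicle_width", value = 5))
  expect_equal(one$min, one$max)
  expect_error(guideEnvelope(matrix(numeric(0), 0, 0)), "empty")
})

test_that("landmark files round-trip through CSV", {
  l <- makeTemplate(syntheticSpec())$landmarks
  f <- tempfile(fileext = ".csv")
  writeLandmarks(l, f)
  back <- readLandmarks(f)
  expect_equal(back@superior, l@superior, tolerance = 1e-9)
  expect_equal(back@endplate, l@endplate, tolerance = 1e-9)
  expect_identical(back@side, l@side)
  m1 <- measurePedicle(l); m2 <- measurePedicle(back)
  expect_equal(m2@transverseAngle, m1@transverseAngle, tolerance = 1e-9)
})
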