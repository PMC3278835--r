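test_that("polar resampling reproduces analytic shapes", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]

  # circle: all radii equal R
  circ <- radialPolygon(rep(10, length(th)), th)
  pb <- polarResample(circ, c(0, 0), M = 36)
  expect_equal(pb$radii, rep(10, 36), tolerance = 1e-9)

  # ellipse: matches r(theta) = ab / sqrt((b cos)^2 + (a sin)^2)
  a <- 20; b <- 10
  ell <- cbind(row = b * sin(th), col = a * cos(th))
  pe <- polarResample(ell, c(0, 0), M = 90)
  expected <- a * b / sqrt((b * cos(pe$angles))^2 + (a * sin(pe$angles))^2)
  expect_equal(pe$radii, expected, tolerance = 1e-3)

  # square: radii between half-side and half-diagonal, 4-fold symmetric
  sq <- cbind(row = c(-5, -5, 5, 5), col = c(-5, 5, 5, -5))
  ps <- polarResample(sq, c(0, 0), M = 32)
  expect_true(all(ps$radii >= 5 - 1e-9 & ps$radii <= 5 * sqrt(2) + 1e-9))
  expect_equal(ps$radii[1:8], ps$radii[9:16], tolerance = 1e-9)

  # centre outside the polygon is an error
  expect_error(polarResample(sq, c(50, 50), M = 16), "outside")
  expect_error(polarResample(sq, M = 4), "M must be")
})

test_that("marker displacement splits dilation and contraction correctly", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  c1 <- polarResample(radialPolygon(rep(10, 180), th), c(0, 0), M = 60)
  expect_equal(boundaryDisplacement(c1, c1), rep(0, 60))

  c2 <- polarResample(radialPolygon(rep(12.5, 180), th), c(0, 0), M = 60)
  expect_equal(boundaryDisplacement(c1, c2), rep(2.5, 60), tolerance = 1e-9)

  # half-plane expansion / half-plane contraction
  M <- 60
  thm <- seq(0, 2 * pi, length.out = M + 1)[-(M + 1)]
  r2 <- ifelse(thm < pi, 11, 9)
  p1 <- polarResample(radialPolygon(rep(10, M), thm), c(0, 0), M = M)
  p2 <- polarResample(radialPolygon(r2, thm), c(0, 0), M = M)
  d <- boundaryDisplacement(p1, p2)
  expect_equal(sum(abs(d - 1) < 0.3), 30, tolerance = 2)
  expect_equal(sum(abs(d + 1) < 0.3), 30, tolerance = 2)

  expect_error(boundaryDisplacement(c1, polarResample(sqChk <- radialPolygon(
    rep(10, 180), th), c(0, 0), M = 30)), "marker grid")
})

test_that("a 12-frame track yields 22 edge features", {
  sim <- simulateCellMovie(simConfig(nCells = 2, imageShape = c(256, 256),
                                     seed = 19))
  ep <- edgePrint(sim$tracks, M = 90)
  expect_identical(ncol(edgeFeatureMatrix(ep)), 22L)
  expect_identical(ncol(protrusion(ep)), 11L)
  expect_true(all(edgeFeatureMatrix(ep) >= 0))
})

test_that("edge prints are invariant under per-frame translation", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  shape <- function(t) radialPolygon(10 + 1.5 * sin(3 * th + 0.4 * t), th)
  polys <- lapply(1:5, shape)
  shifted <- lapply(seq_along(polys), function(i)
    sweep(polys[[i]], 2, c(-7 * i, 13 * i), "+"))
  ts1 <- syntheticTrackSet(list(c1 = polys))
  ts2 <- syntheticTrackSet(list(c1 = shifted))
  e1 <- edgePrint(ts1, M = 72)
  e2 <- edgePrint(ts2, M = 72)
  expect_equal(protrusion(e1), protrusion(e2), tolerance = 1e-9)
  expect_equal(retraction(e1), retraction(e2), tolerance = 1e-9)

  # rigid translation of a fixed shape: zero print
  fixed <- lapply(1:4, function(i) sweep(polys[[1]], 2, c(5 * i, -3 * i), "+"))
  ez <- edgePrint(syntheticTrackSet(list(c1 = fixed)), M = 72)
  expect_lt(max(edgeFeatureMatrix(ez)), 1e-9)
})

test_that("doubling the marker count barely changes a smooth print", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  shape <- function(t) radialPolygon(12 + 2 * sin(2 * th + 0.5 * t) +
                                     1 * sin(5 * th - 0.3 * t), th)
  ts <- syntheticTrackSet(list(c1 = lapply(1:6, shape)))
  eA <- edgeFeatureMatrix(edgePrint(ts, M = 180))
  eB <- edgeFeatureMatrix(edgePrint(ts, M = 360))
  expect_lt(max(abs(eA - eB) / pmax(abs(eB), 1e-6)), 0.02)
})

test_that("zero protrusion implies non-increasing area for star-shaped cells", {
  # pure contraction: p_t = 0 and the area shrinks
  delta <- -1
  cfg <- simConfig(nCells = 1, imageShape = c(160, 160), nFrames = 4,
                   speed = 0, boundaryModes = NULL, protrusionBias = delta,
                   noiseSd = 0, seed = 4)
  sim <- simulateCellMovie(cfg)
  expect_identical(max(protrusion(sim$edgePrints)), 0)
  areas <- trackRecords(sim$tracks)$area
  expect_true(all(diff(areas) < 0))
})

test_that("recovered prints match the generator ground truth closely", {
  sim <- simulateCellMovie(simConfig(nCells = 4, imageShape = c(384, 384),
                                     seed = 23))
  regions <- lapply(seq_len(12), function(f)
    extractRegions(sim$labels[, , f], sim$movie@frames[, , f], minArea = 50))
  tr <- buildTracks(regions, labelMasks = sim$labels,
                    frames = sim$movie@frames,
                    pixelSize = 0.707, frameInterval = 10)
  ep <- edgePrint(tr)
  map <- matchTrackIds(trackRecords(sim$tracks), trackRecords(tr))
  E <- edgeFeatureMatrix(ep)
  G <- edgeFeatureMatrix(sim$edgePrints)[map[rownames(E)], , drop = FALSE]
  rms <- sqrt(mean((E - G)^2)) / sqrt(mean(G^2))
  expect_lt(rms, 0.05)
})

test_that("marker displacement table is long-format and consistent", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  polys <- list(radialPolygon(rep(10, 180), th),
                radialPolygon(rep(11, 180), th))
  ts <- syntheticTrackSet(list(c1 = polys))
  tab <- markerDisplacementTable(ts, "c1", M = 36)
  expect_identical(nrow(tab), 36L)
  expect_equal(tab$displacement_um, rep(1, 36), tolerance = 1e-9)
})
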