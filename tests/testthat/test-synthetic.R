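test_that("PRW track generator honours its degenerate limits", {
  # zero speed: the cell never moves
  xy <- simulatePRWTrack(0, 1, 10, 8, seed = 1)
  expect_true(all(xy == 0))

  # near-infinite persistence: straight line at (numerically) constant speed
  xy <- simulatePRWTrack(10, 1e8, 10, 20, seed = 2)
  steps <- diff(xy)
  lens <- sqrt(rowSums(steps^2))
  expect_lt(max(lens) - min(lens), 1e-3 * mean(lens))
  headings <- atan2(steps[, 2], steps[, 1])
  expect_lt(max(headings) - min(headings), 1e-2)

  expect_error(simulatePRWTrack(-1, 1, 10, 5), "speed")
  expect_error(simulatePRWTrack(1, 0, 10, 5), "persistence")
})

test_that("ensemble MSD of simulated PRW tracks matches the closed form", {
  set.seed(101)
  S <- 10; P <- 1
  msds <- vapply(seq_len(2000), function(i)
    computeMSD(simulatePRWTrack(S, P, 10, 12), 1, 10)$msd_um2,
    numeric(11))
  emp <- rowMeans(msds)
  theo <- prwMSD((1:11) / 6, S, P)
  expect_lt(max(abs(emp / theo - 1)), 0.05)
})

test_that("time-averaged speed of a long track converges to S", {
  set.seed(7)
  S <- 8; P <- 0.5; dt <- 10 / 60
  xy <- simulatePRWTrack(S, P, 10, 10000)
  vrms <- sqrt(mean(rowSums(diff(xy)^2)) / dt^2)
  # the finite-step estimate of S carries a small O(dt/P) discretization bias
  bias <- sqrt(prwMSD(dt, S, P)) / (S * dt)
  expect_lt(abs(vrms / (S * bias) - 1), 0.05)
})

test_that("movie generation is reproducible and obeys its invariants", {
  cfg <- simConfig(nCells = 2, imageShape = c(128, 128), nFrames = 3, seed = 5)
  s1 <- simulateCellMovie(cfg)
  s2 <- simulateCellMovie(cfg)
  expect_identical(s1$movie@frames, s2$movie@frames)
  expect_identical(trackRecords(s1$tracks), trackRecords(s2$tracks))
  expect_identical(protrusion(s1$edgePrints), protrusion(s2$edgePrints))

  # non-negative ground-truth edge prints
  expect_true(all(edgeFeatureMatrix(s1$edgePrints) >= 0))
  # intensities within the 12-bit range
  expect_true(all(s1$movie@frames >= 0 & s1$movie@frames <= 4095))
})

test_that("rigid, stationary cells produce identical frames and a zero print", {
  cfg <- simConfig(nCells = 2, imageShape = c(128, 128), nFrames = 4,
                   speed = 0, boundaryModes = NULL, noiseSd = 0, seed = 1)
  sim <- simulateCellMovie(cfg)
  for (f in 2:4)
    expect_identical(sim$movie@frames[, , f], sim$movie@frames[, , 1])
  expect_identical(max(edgeFeatureMatrix(sim$edgePrints)), 0)
})

test_that("uniform radial growth gives protrusion delta/tau and no retraction", {
  delta <- 1.5
  cfg <- simConfig(nCells = 1, imageShape = c(160, 160), nFrames = 4,
                   speed = 0, boundaryModes = NULL, protrusionBias = delta,
                   noiseSd = 0, seed = 2)
  sim <- simulateCellMovie(cfg)
  expect_equal(max(abs(protrusion(sim$edgePrints) - delta / 10)), 0,
               tolerance = 1e-12)
  expect_identical(max(retraction(sim$edgePrints)), 0)
})

test_that("overcrowded configurations are rejected", {
  expect_error(simulateCellMovie(simConfig(nCells = 50,
                                           imageShape = c(128, 128))),
               "overlap")
})

test_that("feature-table sampler matches its mixture specification", {
  # degenerate component: all rows equal the mean
  tab <- simulateFeatureTable(classMeans = cbind(c(1, 2)),
                              classCovariances = matrix(0, 2, 2),
                              nSamples = 20, seed = 1)
  expect_true(all(tab[[1]] == 1 & tab[[2]] == 2))

  # class means recovered within 3 standard errors (isotropic sd 1)
  tab <- simulateFeatureTable(nSamples = 4000, seed = 2)
  mns <- motilityClassMeans()
  for (k in 1:4) {
    Xk <- as.matrix(tab[tab$.class == k, seq_len(8)])
    se <- 1 / sqrt(nrow(Xk))
    expect_true(all(abs(colMeans(Xk) - mns[, k]) < 3.5 * se))
  }

  # empirical proportions of two well-separated components within binomial CI
  tab <- simulateFeatureTable(classMeans = cbind(0, 10),
                              classCovariances = matrix(1),
                              classWeights = c(0.3, 0.7),
                              nSamples = 1000, seed = 3)
  phat <- mean(tab$.class == 2)
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.3 * 0.7 / 1000))

  expect_error(simulateFeatureTable(classWeights = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
})
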