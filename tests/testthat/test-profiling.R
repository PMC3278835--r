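test_that("a one-component fit reproduces the closed-form ML solution", {
  set.seed(31)
  X <- matrix(rnorm(200), 100, 2)
  m <- fitGMM(X, 1, seed = 1)
  expect_equal(as.vector(m@means), colMeans(X), tolerance = 1e-8)
  Sml <- cov(X) * 99 / 100
  expect_equal(m@covariances[[1]], Sml, tolerance = 1e-4)
  expect_equal(m@weights, 1)
})

test_that("EM log-likelihood is monotone and weights stay on the simplex", {
  set.seed(32)
  X <- rbind(matrix(rnorm(120, 0), , 2), matrix(rnorm(120, 4), , 2))
  m <- fitGMM(X, 2, seed = 2)
  tr <- attr(m, "trace")
  expect_true(all(diff(tr) >= -1e-7 * (1 + abs(tr[-length(tr)]))))
  expect_equal(sum(m@weights), 1, tolerance = 1e-12)
  expect_true(all(m@weights > 0))
  # well-separated spherical components: means within 0.1 sigma of truth
  mu <- m@means[order(m@means[, 1]), ]
  expect_lt(max(abs(mu[1, ] - 0)), 0.35)   # 0.1 sigma_mean ~ sd/sqrt(n)*3
  expect_lt(max(abs(mu[2, ] - 4)), 0.35)
})

test_that("degenerate duplicated points keep covariances positive definite", {
  X <- rbind(matrix(rnorm(40), , 2), matrix(2, 30, 2))  # 30 identical points
  m <- fitGMM(X, 2, seed = 3)
  for (S in m@covariances) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  expect_true(is.finite(m@logLik))
})

test_that("MDL matches a hand computation on a tiny dataset", {
  x <- matrix(c(1, 2, 3, 6), 4, 1)
  m <- fitGMM(x, 1, seed = 1)
  mu <- mean(x); s2 <- mean((x - mu)^2)
  llHand <- sum(dnorm(x, mu, sqrt(s2), log = TRUE))
  Lp <- 1 * (1 + 1 + 1) - 1
  mdlHand <- -llHand + 0.5 * Lp * log(4 * 1)
  expect_equal(mdlScore(m), mdlHand, tolerance = 1e-10)
  # with a single feature the two penalty conventions coincide
  expect_equal(mdlScore(m, penalty = "logN"), mdlScore(m), tolerance = 1e-12)
})

test_that("MDL structure: fit improves and penalty grows with K", {
  set.seed(34)
  X <- rbind(matrix(rnorm(150, 0), , 3), matrix(rnorm(150, 5), , 3))
  fits <- lapply(1:3, function(k) fitGMM(X, k, seed = k, restartPolicy = "best"))
  lls <- vapply(fits, function(m) m@logLik, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))      # -logL non-increasing in K
  pens <- vapply(fits, function(m) mdlScore(m) + m@logLik, numeric(1))
  expect_true(all(diff(pens) > 0))          # penalty strictly increasing
  # penalty scales as log(N n): tenfold data inflates it by Lp/2 * log(10)
  X10 <- X[rep(seq_len(nrow(X)), 10), ]
  m1 <- fitGMM(X, 1); m10 <- fitGMM(X10, 1)
  pen1 <- mdlScore(m1) + m1@logLik
  pen10 <- mdlScore(m10) + m10@logLik
  Lp <- 1 * (1 + 3 + 6) - 1
  expect_equal(pen10 - pen1, 0.5 * Lp * log(10), tolerance = 1e-10)
})

test_that("model order selection behaves at the edges", {
  set.seed(35)
  # single Gaussian cloud: small K wins and MDL(1) < MDL(4)
  X <- matrix(rnorm(600), 200, 3)
  sel <- selectK(X, 1, 4, seed = 5)
  expect_lte(sel$K, 2)
  expect_lt(sel$mdl["1"], sel$mdl["4"])

  # degenerate range
  sel2 <- selectK(X, 2, 2, seed = 6)
  expect_identical(sel2$K, 2L)

  # kMax clipped with a warning
  expect_warning(selectK(matrix(rnorm(40), 20, 2), 2, 50, seed = 7),
                 "clipped")
})

test_that("two-phase K-means recovers separated blobs and descends", {
  set.seed(36)
  X <- rbind(matrix(rnorm(300, 0), , 3),
             matrix(rnorm(300, 7), , 3),
             cbind(rnorm(100, 7), rnorm(100, -7), rnorm(100, 0)))
  truth <- rep(1:3, each = 100)
  tp <- twoPhaseKmeans(X, 3, seed = 8, standardize = FALSE)
  expect_identical(length(tp$cluster), 300L)
  # perfect recovery up to label permutation
  tab <- table(tp$cluster, truth)
  expect_identical(sum(apply(tab, 1, max)), 300L)
  # descent: final objective <= objective of the phase-1 seeds on full data
  d2 <- function(ctr) sum(vapply(seq_len(nrow(X)), function(i)
    min(colSums((t(ctr) - X[i, ])^2)), numeric(1)))
  expect_lte(tp$totWithinss, d2(tp$phase1Centers) + 1e-8)

  # K = 1: centroid is the grand mean
  t1 <- twoPhaseKmeans(X, 1, seed = 9, standardize = FALSE)
  expect_equal(as.vector(t1$centers), colMeans(X), tolerance = 1e-8)
})

test_that("probability plot coordinates follow the midpoint formula", {
  pp <- probabilityPlotCoords(c(3, 1, 2, 4))
  expect_equal(pp$midpoints, c(0.125, 0.375, 0.625, 0.875))
  expect_equal(pp$x, c(1, 2, 3, 4))

  # an exact normal-quantile sample hugs the quartile chord between the
  # quartiles (outside them the bounded CDF must leave the straight line)
  xs <- qnorm((seq_len(200) - 0.5) / 200)
  pq <- probabilityPlotCoords(xs)
  fitted <- pq$intercept + pq$slope * pq$x
  mid <- pq$midpoints
  keep <- mid >= 0.25 & mid <= 0.75
  expect_lt(max(abs(mid[keep] - fitted[keep])), 0.015)

  # heavy tails depart from the line in opposite directions
  set.seed(37)
  xt <- qcauchy((seq_len(200) - 0.5) / 200)
  pt_ <- probabilityPlotCoords(xt)
  resid <- pt_$midpoints - (pt_$intercept + pt_$slope * pt_$x)
  expect_gt(resid[5], 0)              # lower tail above the chord
  expect_lt(resid[196], 0)            # upper tail below the chord
})

test_that("chi-square GOF against a normal has the stated calibration", {
  # counts exactly equal to expected: statistic 0, p = 1
  x <- qnorm((seq_len(50) - 0.5) / 50)
  g <- chisqGofNormal(x, nBins = 10)
  expect_lt(g$statistic, 1e-6)
  expect_gt(g$p.value, 1 - 1e-6)
  expect_identical(g$df, 7L)

  # type-I error near nominal alpha for normal samples
  set.seed(38)
  rej <- mean(replicate(400, chisqGofNormal(rnorm(200))$p.value < 0.05))
  expect_lt(abs(rej - 0.05), 0.04)

  # a uniform sample is rejected with high power
  set.seed(39)
  pu <- chisqGofNormal(runif(1000), nBins = 10)$p.value
  expect_lt(pu, 0.01)
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  set.seed(54)
  X <- rbind(matrix(rnorm(200, 0), , 2), matrix(rnorm(300, 4), , 2))
  ours <- fitGMM(X, 2, seed = 4)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(ours@logLik, ref$loglik, tolerance = 1e-4)
  mu1 <- ours@means[order(ours@means[, 1]), ]
  mu2 <- t(ref$parameters$mean)[order(t(ref$parameters$mean)[, 1]), ]
  expect_equal(mu1, mu2, tolerance = 0.02, ignore_attr = TRUE)
})
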