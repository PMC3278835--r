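test_that("time-averaged edge features are plain means", {
  pr <- matrix(c(0, 0, 0, 2, 2, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  re <- matrix(c(0, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE,
               dimnames = list(c("a", "b"), NULL))
  eps <- new("EdgePrintSet", protrusion = pr, retraction = re, tau = 10,
             normalized = TRUE)
  ta <- timeAverageEdge(eps)
  expect_equal(ta$protrusion_velocity, c(0, 2))
  expect_equal(ta$retraction_velocity, c(0, 2))
})

test_that("Spearman correlation is exact under monotone transforms", {
  set.seed(41)
  x <- rnorm(30)
  tab <- data.frame(x = x, y = exp(2 * x) + 5)   # strictly monotone in x
  sp <- spearmanWithP(tab)
  expect_equal(sp$rho[1, 2], 1)
  expect_equal(sp$p[1, 2], 0)
  expect_true(sp$significant[1, 2])
  # matrix structure
  expect_equal(sp$rho, t(sp$rho))
  expect_equal(diag(sp$rho), c(x = 1, y = 1))
})

test_that("t-transform p-values track the exact permutation distribution", {
  set.seed(7)
  for (i in 1:3) {
    x <- rnorm(8); y <- 0.6 * x + rnorm(8)
    sp <- spearmanWithP(cbind(a = x, b = y))
    expect_lt(abs(sp$p[1, 2] - spearmanPermP(x, y)), 0.02)
  }
})

test_that("significance flags fire at about the nominal rate under the null", {
  set.seed(43)
  hits <- replicate(600, {
    tab <- matrix(rnorm(2 * 25), 25, 2)
    spearmanWithP(tab)$significant[1, 2]
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})

test_that("multiple correlation equals its closed forms", {
  set.seed(44)
  n <- 50
  X <- matrix(rnorm(3 * n), n, 3)
  y <- 2 * X[, 1] - X[, 2] + 0.5 * X[, 3]
  tab <- data.frame(speed_um_per_h = y, a = X[, 1], b = X[, 2], c = X[, 3])
  expect_equal(multipleCorrelation(tab)$r_squared, 1, tolerance = 1e-10)

  # single predictor: R^2 is the squared Pearson correlation
  y2 <- X[, 1] + rnorm(n)
  tab2 <- data.frame(speed_um_per_h = y2, a = X[, 1])
  expect_equal(multipleCorrelation(tab2)$r_squared, cor(y2, X[, 1])^2,
               tolerance = 1e-12)

  # under independence E[R^2] ~ p / (N - 1)
  set.seed(45)
  r2 <- replicate(300, {
    tab <- data.frame(speed_um_per_h = rnorm(40), matrix(rnorm(40 * 4), 40))
    multipleCorrelation(tab)$r_squared
  })
  expect_lt(abs(mean(r2) - 4 / 39), 0.03)
})

test_that("jackknife correlations equal brute-force delete-one recomputation", {
  set.seed(46)
  tab <- data.frame(m1 = rnorm(12), m2 = rnorm(12),
                    e1 = rnorm(12), e2 = rnorm(12))
  jk <- jackknifeCorrelation(tab, c("m1", "m2"), c("e1", "e2"))
  for (i in 1:12) {
    ref <- cor(tab[-i, c("m1", "m2")], tab[-i, c("e1", "e2")],
               method = "spearman")
    expect_identical(jk$estimates[, , i], ref)
  }
  expect_equal(jk$mean, apply(jk$estimates, 1:2, mean))

  # perfectly correlated pair: mean 1, sd 0
  tp <- data.frame(m = 1:10, e = (1:10)^2)
  jp <- jackknifeCorrelation(tp, "m", "e")
  expect_equal(jp$mean[1, 1], 1)
  expect_equal(jp$sd[1, 1], 0)

  # an outlier inflates the jackknife sd
  set.seed(47)
  x <- rnorm(15); y <- x + rnorm(15, 0, 0.2)
  clean <- data.frame(m = x, e = y)
  dirty <- clean; dirty$e[1] <- 25
  expect_gt(jackknifeCorrelation(dirty, "m", "e", method = "pearson")$sd[1, 1],
            jackknifeCorrelation(clean, "m", "e", method = "pearson")$sd[1, 1])
})

test_that("factor analysis recovers planted structure and conserves variance", {
  set.seed(48)
  N <- 500
  Fa <- matrix(rnorm(2 * N), N, 2)
  L <- cbind(c(1, 0.9, 0.8, 0, 0, 0), c(0, 0, 0, 1, 0.9, 0.8))
  X <- Fa %*% t(L) + matrix(rnorm(6 * N, 0, 0.1), N)
  fa <- factorAnalysisFeatures(as.data.frame(X))
  expect_identical(fa$n_retained, 2L)
  congr <- abs(cor(fa$loadings, L))
  expect_true(all(apply(congr, 2, max) >= 0.95))
  expect_equal(sum(fa$eigenvalues), sum(diag(cov(X))), tolerance = 1e-8)
  expect_true(all(diff(fa$cumulative_variance) >= -1e-9))
  expect_lte(max(fa$cumulative_variance), 100 + 1e-9)
  # suppressed view blanks small loadings only
  sup <- fa$loadings_suppressed
  expect_true(all(is.na(sup[abs(fa$loadings) < 0.4])))

  # identity covariance: all correlation-scale eigenvalues near 1
  set.seed(49)
  Xi <- matrix(rnorm(5 * 800), 800, 5)
  fi <- factorAnalysisFeatures(as.data.frame(Xi))
  expect_true(all(abs(fi$kaiser_eigenvalues - 1) < 0.25))

  # rank-1 covariance: one factor explains ~100%
  z <- rnorm(300)
  Xr <- cbind(z, 2 * z, -z) + matrix(rnorm(900, 0, 1e-3), 300)
  fr <- factorAnalysisFeatures(as.data.frame(Xr))
  expect_identical(fr$n_retained, 1L)
  expect_gt(fr$variance_explained[1], 99)
})

test_that("the class-level correlation report assembles all pieces", {
  set.seed(50)
  sim <- simulateCellMovie(simConfig(nCells = 12, seed = 29))
  mot <- motilityFeatures(sim$tracks)
  eds <- timeAverageEdge(sim$edgePrints)
  rep <- correlationReport(mot, eds)
  expect_identical(dim(rep$spearman$rho), c(10L, 10L))
  expect_true(rep$r_squared >= 0 && rep$r_squared <= 1)
  expect_identical(dim(rep$jackknife$mean), c(8L, 2L))
  expect_identical(nrow(rep$barplot_data), 16L)
})
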