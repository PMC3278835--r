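## log densities of K multivariate normals at the rows of X: N x K matrix
gmmLogDens <- function(X, means, covariances) {
  N <- nrow(X); n <- ncol(X); K <- nrow(means)
  out <- matrix(NA_real_, N, K)
  for (k in seq_len(K)) {
    U <- chol(covariances[[k]])
    z <- forwardsolve(t(U), t(X) - means[k, ])
    out[, k] <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(U))) +
                        colSums(z^2))
  }
  out
}

logRowSumExp <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Maximum-likelihood estimation of a K-component Gaussian mixture with full
#' covariance matrices. Parameters are initialized from a K-means partition
#' and refined by EM; the per-iteration log-likelihood is non-decreasing (the
#' trace is returned in the fit). Every covariance update adds a small ridge
#' (`ridge` times the mean feature variance) to the diagonal so components
#' degenerating onto few points stay positive definite.
#'
#' Following the convention that a run is re-attempted with fresh initial
#' conditions until it converges, up to `maxRestarts` attempts are made and
#' the first converged attempt is returned (`restartPolicy = "first"`). With
#' `restartPolicy = "best"` all attempts are run and the converged fit with
#' the highest log-likelihood wins.
#'
#' @param X numeric matrix (N x n) or data.frame of features.
#' @param K number of components (>= 1, <= N).
#' @param maxRestarts maximum EM attempts with new initializations (default 5).
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-5, the usual EM stopping scale).
#' @param maxIter EM iterations per attempt (default 200).
#' @param seed optional integer seed (controls K-means initializations).
#' @param ridge diagonal regularization as a fraction of the mean feature
#'   variance (default 1e-6).
#' @param restartPolicy `"first"` (stop at first converged attempt) or
#'   `"best"`.
#' @return a [MixtureModel-class]; its `converged` slot is `FALSE` when no
#'   attempt converged (the best attempt is still returned). The
#'   log-likelihood trace of the returned fit is in `attr(, "trace")` and the
#'   posterior responsibilities in `attr(, "responsibilities")`.
#' @examples
#' X <- rbind(matrix(rnorm(100), , 2), matrix(rnorm(100, 5), , 2))
#' fitGMM(X, 2, seed = 1)
#' @export
fitGMM <- function(X, K, maxRestarts = 5L, tol = 1e-5, maxIter = 200L,
                   seed = NULL, ridge = 1e-6,
                   restartPolicy = c("first", "best")) {
  restartPolicy <- match.arg(restartPolicy)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  N <- nrow(X); n <- ncol(X)
  stopifnot(K >= 1L, N >= K)
  if (!is.null(seed)) set.seed(seed)
  eps <- ridge * mean(apply(X, 2, var))
  if (!is.finite(eps) || eps <= 0) eps <- ridge

  runEM <- function(attempt) {
    km <- tryCatch(
      suppressWarnings(kmeans(X, centers = min(K, nrow(unique(X))),
                              nstart = 10, iter.max = 50)),
      error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < K) {
      grp <- sample(rep_len(seq_len(K), N))
    } else grp <- km$cluster
    w <- tabulate(grp, K) / N
    w[w == 0] <- 1 / N; w <- w / sum(w)
    mu <- matrix(NA_real_, K, n)
    Sg <- vector("list", K)
    for (k in seq_len(K)) {
      xk <- X[grp == k, , drop = FALSE]
      mu[k, ] <- if (nrow(xk)) colMeans(xk) else X[sample.int(N, 1), ]
      Ck <- if (nrow(xk) > 1) cov(xk) * (nrow(xk) - 1) / nrow(xk) else
        diag(eps, n)
      Sg[[k]] <- Ck + diag(eps, n)
    }
    ll <- -Inf; trace <- numeric(0); converged <- FALSE
    for (it in seq_len(maxIter)) {
      ld <- gmmLogDens(X, mu, Sg) + rep(log(w), each = N)
      tot <- logRowSumExp(ld)
      llNew <- sum(tot)
      trace <- c(trace, llNew)
      if (it > 1 && abs(llNew - ll) <= tol * (1 + abs(llNew))) {
        converged <- TRUE; ll <- llNew; break
      }
      ll <- llNew
      R <- exp(ld - tot)                       # responsibilities
      Nk <- colSums(R)
      w <- Nk / N
      for (k in seq_len(K)) {
        mu[k, ] <- colSums(R[, k] * X) / Nk[k]
        Xc <- sweep(X, 2, mu[k, ])
        Sg[[k]] <- crossprod(Xc * sqrt(R[, k])) / Nk[k] + diag(eps, n)
      }
    }
    ld <- gmmLogDens(X, mu, Sg) + rep(log(w), each = N)
    tot <- logRowSumExp(ld)
    list(w = w, mu = mu, Sg = Sg, ll = sum(tot), converged = converged,
         iters = length(trace), trace = trace, R = exp(ld - tot))
  }

  best <- NULL
  for (attempt in seq_len(maxRestarts)) {
    res <- runEM(attempt)
    if (is.null(best) ||
        (res$converged && !best$converged) ||
        (res$converged == best$converged && res$ll > best$ll))
      best <- res
    if (restartPolicy == "first" && best$converged) break
  }
  mm <- new("MixtureModel", K = as.integer(K), weights = best$w,
            means = best$mu, covariances = best$Sg, logLik = best$ll,
            converged = best$converged, nObs = as.integer(N),
            nFeatures = as.integer(n), iterations = as.integer(best$iters))
  attr(mm, "trace") <- best$trace
  attr(mm, "responsibilities") <- best$R
  mm
}

#' Minimum description length of a fitted mixture
#'
#' \deqn{\mathrm{MDL} = -\log L(\Theta) + \tfrac{1}{2} L_p \log(Nn),}
#' where the free-parameter count of a K-component full-covariance mixture in
#' n dimensions is `L_p = K (1 + n + n(n+1)/2) - 1`. The penalty argument
#' includes the number of features n; `penalty = "logN"` swaps `log(Nn)` for
#' the classical `log N`.
#'
#' @param model a converged [MixtureModel-class].
#' @param penalty `"logNn"` (default) or `"logN"`.
#' @return the MDL score (smaller is better).
#' @export
mdlScore <- function(model, penalty = c("logNn", "logN")) {
  penalty <- match.arg(penalty)
  stopifnot(is(model, "MixtureModel"))
  N <- model@nObs; n <- model@nFeatures; K <- model@K
  Lp <- K * (1 + n + n * (n + 1) / 2) - 1
  arg <- if (penalty == "logNn") N * n else N
  -model@logLik + 0.5 * Lp * log(arg)
}

#' Select the mixture order by minimum description length
#'
#' Fits a Gaussian mixture for every candidate `K` in `kMin..kMax` and picks
#' the converged candidate minimizing [mdlScore()].
#'
#' @param X feature matrix or data.frame.
#' @param kMin,kMax candidate range (defaults 2 and 100; `kMax` is clipped to
#'   `N - 1` with a warning when the sample is small).
#' @param standardize z-score features first (default TRUE; features can span
#'   orders of magnitude).
#' @param seed integer seed; attempt `i` for candidate K uses a deterministic
#'   substream so runs are reproducible.
#' @param penalty passed to [mdlScore()].
#' @param ... passed to [fitGMM()].
#' @return list with `K` (selected order), `mdl` (named vector over
#'   candidates, NA where unconverged), `model` (the selected
#'   [MixtureModel-class]) and `cluster` (MAP component per row).
#' @export
selectK <- function(X, kMin = 2L, kMax = 100L, standardize = TRUE,
                    seed = NULL, penalty = "logNn", ...) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (kMax >= N) {
    warning("kMax clipped to N - 1")
    kMax <- N - 1L
  }
  stopifnot(kMin >= 1L, kMin <= kMax)
  Z <- if (standardize) scale(X) else X
  ks <- kMin:kMax
  mdl <- setNames(rep(NA_real_, length(ks)), ks)
  models <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    m <- fitGMM(Z, ks[i], seed = if (is.null(seed)) NULL else seed + ks[i], ...)
    if (m@converged) {
      mdl[i] <- mdlScore(m, penalty = penalty)
      models[[i]] <- m
    }
  }
  if (all(is.na(mdl))) stop("no candidate K converged")
  sel <- which.min(mdl)
  model <- models[[sel]]
  R <- attr(model, "responsibilities")
  list(K = ks[sel], mdl = mdl, model = model,
       cluster = max.col(R))
}

#' Two-phase K-means
#'
#' Clustering-phase initialization for K-means: a first K-means pass on a
#' uniform random subsample (default 10% of rows) supplies the initial
#' centroids for a second pass over the full data, avoiding the usual
#' sensitivity to random initial centroids.
#'
#' @param X feature matrix or data.frame.
#' @param K number of clusters; must not exceed the subsample size.
#' @param sampleFrac subsample fraction for phase 1 (default 0.10).
#' @param nIter maximum iterations per phase (default 1000).
#' @param nStart random initializations of the phase-1 run (default 5; the
#'   subsample is small, so extra starts are cheap insurance against a poor
#'   seeding of phase 2).
#' @param seed optional integer seed.
#' @param standardize z-score features first (default TRUE).
#' @return list with `cluster`, `centers`, `totWithinss`, `withinss` and
#'   `phase1Centers` (centroids that seeded phase 2; same scale as
#'   `centers`).
#' @export
twoPhaseKmeans <- function(X, K, sampleFrac = 0.10, nIter = 1000L,
                           seed = NULL, standardize = TRUE, nStart = 5L) {
  X <- as.matrix(X)
  if (!is.null(seed)) set.seed(seed)
  Z <- if (standardize) scale(X) else X
  N <- nrow(Z)
  m <- min(N, max(K + 1L, floor(sampleFrac * N)))
  if (K >= m) stop("K exceeds the phase-1 subsample size")
  idx <- sample.int(N, m)
  p1 <- suppressWarnings(kmeans(Z[idx, , drop = FALSE], centers = K,
                                iter.max = nIter, nstart = nStart))
  ctr <- p1$centers
  # duplicate phase-1 centroids would abort phase 2; jitter minimally
  if (anyDuplicated(ctr))
    ctr <- ctr + matrix(rnorm(length(ctr), 0, 1e-8), nrow(ctr))
  p2 <- suppressWarnings(kmeans(Z, centers = ctr, iter.max = nIter))
  list(cluster = p2$cluster, centers = p2$centers,
       totWithinss = p2$tot.withinss, withinss = p2$withinss,
       phase1Centers = ctr)
}

#' Coordinates of a normal probability plot
#'
#' Sorted sample values paired with the empirical-CDF jump midpoints
#' `(j - 0.5) / N`, plus the reference line through the first- and
#' third-quartile points extrapolated outward: data on a straight line
#' conform to the hypothesized normal shape, departures (typically in the
#' tails) indicate non-normality.
#'
#' @param x numeric sample, N >= 4.
#' @return list with `x` (sorted values), `midpoints`, and the reference-line
#'   `slope` and `intercept` (in (x, midpoint) coordinates).
#' @examples
#' pp <- probabilityPlotCoords(rnorm(100))
#' plot(pp$x, pp$midpoints); abline(pp$intercept, pp$slope)
#' @export
probabilityPlotCoords <- function(x) {
  N <- length(x)
  stopifnot(N >= 4L)
  xs <- sort(x)
  mid <- (seq_len(N) - 0.5) / N
  xq <- quantile(xs, c(0.25, 0.75), names = FALSE)
  if (xq[2] <= xq[1]) stop("degenerate sample: identical quartiles")
  slope <- 0.5 / (xq[2] - xq[1])
  intercept <- 0.25 - slope * xq[1]
  list(x = xs, midpoints = mid, slope = slope, intercept = intercept)
}

#' Chi-square goodness of fit against a fitted normal
#'
#' Partitions the real line into `nBins` equal-probability bins under the
#' normal with moment-estimated mean and standard deviation, and compares
#' observed and expected counts. Two estimated parameters plus the count
#' constraint give `nBins - 3` degrees of freedom.
#'
#' @param x numeric sample with `N >= 5 * nBins` (expected count of at least
#'   5 per bin).
#' @param nBins number of equal-probability bins (default 10).
#' @return list with `statistic`, `df`, `p.value`, `observed`, `expected`.
#' @export
chisqGofNormal <- function(x, nBins = 10L) {
  nBins <- as.integer(nBins)
  N <- length(x)
  stopifnot(N >= 5L * nBins)
  mhat <- mean(x); shat <- sd(x)
  if (shat <= 0) stop("degenerate sample")
  br <- qnorm(seq(0, 1, length.out = nBins + 1L), mhat, shat)
  br[1] <- -Inf; br[nBins + 1L] <- Inf
  O <- as.vector(table(cut(x, br)))
  E <- rep(N / nBins, nBins)
  stat <- sum((O - E)^2 / E)
  df <- nBins - 3L
  list(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE),
       observed = O, expected = E)
}
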