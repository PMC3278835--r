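#' Build a synthetic-movie configuration
#'
#' Convenience constructor for [SimulationConfig-class] with defaults that
#' emulate a short high-content imaging experiment: 12 frames at 10-minute
#' intervals, 12-bit intensities, 0.707 um pixels (0.5 um^2 area), bright
#' cells on a dark background. Cell centroids follow a persistent random walk
#' and the boundary of each cell is a star-shaped region
#' `r(theta, t) = baseRadius + sum_j A_j sin(f_j theta + psi_j + omega_j t)`
#' whose travelling modes produce protrusion and retraction activity of a few
#' micrometres per frame interval, comparable to membrane ruffling of motile
#' macrophage-like cells.
#'
#' @param nFrames number of frames (default 12).
#' @param frameInterval minutes between frames (default 10).
#' @param pixelSize micrometres per pixel side (default 0.707, i.e. 0.5 um^2).
#' @param imageShape image (rows, cols) in pixels.
#' @param nCells number of cells.
#' @param speed RMS cell speed in um/h, recycled across cells.
#' @param persistence velocity correlation time in hours, recycled.
#' @param baseRadius resting radius in um.
#' @param boundaryModes matrix with columns (freq, amplitude um, rate rad/h);
#'   `NULL` for a rigid circle.
#' @param protrusionBias uniform signed radial drift, um per frame interval.
#' @param noiseSd additive Gaussian intensity noise sd.
#' @param foreground,background mean cell / background intensity (12-bit scale).
#' @param bitDepth intensity bit depth (default 12).
#' @param divisionFrame frame at which cell 1 divides into two children, or
#'   `NA` (default) for no division.
#' @param seed integer random seed.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(nCells = 4, seed = 1)
#' cfg
#' @export
simConfig <- function(nFrames = 12L, frameInterval = 10, pixelSize = 0.707,
                      imageShape = c(512L, 512L), nCells = 10L,
                      speed = 10, persistence = 2, baseRadius = 12,
                      boundaryModes = defaultBoundaryModes(),
                      protrusionBias = 0, noiseSd = 50,
                      foreground = 3000, background = 200,
                      bitDepth = 12L, divisionFrame = NA_integer_,
                      seed = 1L) {
  if (is.null(boundaryModes))
    boundaryModes <- matrix(numeric(0), 0, 3)
  boundaryModes <- matrix(as.numeric(boundaryModes), ncol = 3,
                          dimnames = list(NULL, c("freq", "amplitude", "rate")))
  new("SimulationConfig",
      nFrames = as.integer(nFrames), frameInterval = frameInterval,
      pixelSize = pixelSize, imageShape = as.integer(imageShape),
      nCells = as.integer(nCells),
      speed = rep_len(speed, nCells), persistence = rep_len(persistence, nCells),
      baseRadius = baseRadius, boundaryModes = boundaryModes,
      protrusionBias = protrusionBias, noiseSd = noiseSd,
      foreground = foreground, background = background,
      bitDepth = as.integer(bitDepth),
      divisionFrame = as.integer(divisionFrame), seed = as.integer(seed))
}

#' Default travelling boundary modes
#'
#' Three sinusoidal modes whose combined radial velocity gives per-marker
#' boundary displacements with RMS near 1.5 um per 10-minute interval --
#' the order of magnitude of lamellipodial ruffling in motile cells -- while
#' keeping the cell star-shaped (total amplitude well below the resting
#' radius).
#' @return numeric matrix with columns (freq, amplitude, rate).
#' @export
defaultBoundaryModes <- function() {
  cbind(freq = c(2, 3, 7),
        amplitude = c(2.0, 1.2, 0.6),
        rate = c(3, 5, 9))
}

#' Simulate a persistent-random-walk centroid track
#'
#' Samples cell positions whose velocity is a 2-D Ornstein-Uhlenbeck process
#' with stationary root-mean-square speed `speed` (um/h) and correlation time
#' `persistence` (h). The exact Gaussian transition of the integrated OU
#' process is used (not an Euler scheme), so the ensemble mean squared
#' displacement matches the persistent-random-walk closed form
#' `MSD(t) = 2 S^2 P (t - P (1 - exp(-t/P)))` at every lag, not only
#' asymptotically.
#'
#' @param speed RMS speed S in um/h (0 allowed: a stationary cell).
#' @param persistence correlation time P in hours (> 0).
#' @param frameInterval minutes between frames.
#' @param nFrames number of positions to return (>= 2).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param x0 starting position, um (default origin).
#' @return an `nFrames` x 2 matrix of (x, y) positions in um.
#' @examples
#' xy <- simulatePRWTrack(10, 1, 10, 12, seed = 1)
#' head(xy)
#' @export
simulatePRWTrack <- function(speed, persistence, frameInterval, nFrames,
                             seed = NULL, x0 = c(0, 0)) {
  if (speed < 0 || persistence <= 0 || frameInterval <= 0)
    stop("speed must be >= 0 and persistence, frameInterval > 0")
  nFrames <- as.integer(nFrames)
  if (nFrames < 2L) stop("nFrames must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(0, nFrames, 2, dimnames = list(NULL, c("x", "y")))
  pos[1, ] <- x0
  if (speed == 0) {
    pos[, 1] <- x0[1]; pos[, 2] <- x0[2]
    return(pos)
  }
  dt <- frameInterval / 60        # hours
  P <- persistence
  s2 <- speed^2 / 2               # per-axis stationary velocity variance
  a <- exp(-dt / P)
  vxx <- s2 * (2 * P * dt - P^2 * (3 - 4 * a + a^2))  # Var(position increment)
  vvv <- s2 * (1 - a^2)                               # Var(velocity innovation)
  vxv <- s2 * P * (1 - a)^2                           # their covariance
  S2 <- matrix(c(vxx, vxv, vxv, vvv), 2, 2)
  L <- tryCatch(t(chol(S2)), error = function(e) {
    # numerically semi-definite in the ballistic limit: fall back to sqrtm
    e <- eigen(S2, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2) %*% t(e$vectors)
  })
  v <- rnorm(2, 0, sqrt(s2))      # stationary initial velocity
  for (t in 2:nFrames) {
    z <- matrix(rnorm(4), 2, 2)   # column per axis
    eta <- L %*% z                # row 1: position noise, row 2: velocity noise
    pos[t, ] <- pos[t - 1, ] + v * P * (1 - a) + eta[1, ]
    v <- v * a + eta[2, ]
  }
  pos
}

#' Closed-form persistent-random-walk mean squared displacement
#'
#' `2 S^2 P (t - P (1 - exp(-t/P)))` for lag `t` in hours; ballistic
#' (`S^2 t^2`) at `t << P` and diffusive (`2 S^2 P t`) at `t >> P`.
#'
#' @param t lag times in hours.
#' @param S RMS speed, um/h.
#' @param P persistence time, h.
#' @return MSD in um^2 at each lag.
#' @export
prwMSD <- function(t, S, P) 2 * S^2 * P * (t - P * (1 - exp(-t / P)))

## radius of one synthetic cell at angles theta (radians) and time tHours
starRadius <- function(theta, tHours, cfg, phases, biasIntervals = 0) {
  r <- rep(cfg@baseRadius + cfg@protrusionBias * biasIntervals, length(theta))
  bm <- cfg@boundaryModes
  if (nrow(bm))
    for (j in seq_len(nrow(bm)))
      r <- r + bm[j, "amplitude"] *
        sin(bm[j, "freq"] * theta + phases[j] + bm[j, "rate"] * tHours)
  r
}

## closed polygon (row, col in px) of a star-shaped cell, dense angular grid
starPolygon <- function(centerPx, radiiUm, theta, pixelSize) {
  rpx <- radiiUm / pixelSize
  cbind(row = centerPx[1] + rpx * sin(theta),
        col = centerPx[2] + rpx * cos(theta))
}

placeCells <- function(cfg) {
  # grid placement with jitter; margin keeps cells inside all frames
  rmaxUm <- cfg@baseRadius + sum(abs(cfg@boundaryModes[, "amplitude"])) +
    abs(cfg@protrusionBias) * (cfg@nFrames - 1)
  tTot <- (cfg@nFrames - 1) * cfg@frameInterval / 60
  # travel allowance: 1.5 x RMS total displacement keeps cells inside the
  # frame and (with pitch 2x margin) inter-cell contact rare
  travelUm <- 1.5 * sqrt(max(prwMSD(tTot, max(cfg@speed), max(cfg@persistence)),
                             0))
  marginPx <- ceiling((rmaxUm + travelUm) / cfg@pixelSize) + 2
  rows <- cfg@imageShape[1]; cols <- cfg@imageShape[2]
  pitch <- 2 * marginPx
  gr <- seq(marginPx, rows - marginPx, by = pitch)
  gc <- seq(marginPx, cols - marginPx, by = pitch)
  if (length(gr) * length(gc) < cfg@nCells)
    stop("configuration error: cells cannot be placed without initial overlap")
  grid <- expand.grid(row = gr, col = gc)
  idx <- sample.int(nrow(grid), cfg@nCells)
  as.matrix(grid[idx, , drop = FALSE])
}

rasterizeCell <- function(shape, centerPx, radiiUm, theta, pixelSize) {
  rpx <- radiiUm / pixelSize
  rmax <- ceiling(max(rpx)) + 1
  r0 <- max(0, floor(centerPx[1] - rmax)); r1 <- min(shape[1] - 1, ceiling(centerPx[1] + rmax))
  c0 <- max(0, floor(centerPx[2] - rmax)); c1 <- min(shape[2] - 1, ceiling(centerPx[2] + rmax))
  rr <- r0:r1; cc <- c0:c1
  dr <- rr - centerPx[1]; dc <- cc - centerPx[2]
  D <- sqrt(outer(dr^2, dc^2, "+"))
  TH <- atan2(outer(dr, rep(1, length(cc))), outer(rep(1, length(rr)), dc)) %% (2 * pi)
  # interpolate the radius profile at each pixel's angle
  Rint <- matrix(approx(c(theta, 2 * pi), c(rpx, rpx[1]), xout = as.vector(TH),
                        rule = 2)$y, nrow = length(rr))
  inside <- D <= Rint
  list(rows = rr, cols = cc, inside = inside)
}

#' Simulate a time-lapse movie of motile cells with ground truth
#'
#' Renders bright star-shaped cells on a dark noisy background. Each cell's
#' centroid follows a persistent random walk ([simulatePRWTrack()]) and its
#' boundary radius is a superposition of travelling sinusoidal modes, so both
#' whole-cell motility and edge protrusion/retraction activity are present
#' with known ground truth. Alongside the movie the generator emits per-frame
#' label masks, ground-truth tracks (with boundary polygons) and ground-truth
#' edge prints computed from the analytic boundary on the same equiangular
#' marker grid used by [edgePrint()], so downstream recovery can be scored
#' without resampling error.
#'
#' When `divisionFrame` is set in the config, cell 1 splits into two smaller
#' children at that frame (the children appear on either side of the parent
#' and continue their own random walks); this exists solely to exercise the
#' division branch of the tracker.
#'
#' @param config a [SimulationConfig-class], e.g. from [simConfig()].
#' @param M number of equiangular ground-truth markers (default 360).
#' @return a list with elements `movie` ([CellMovie-class]), `labels`
#'   (integer array rows x cols x frames; 0 = background), `tracks`
#'   (ground-truth [TrackSet-class]), `edgePrints` (ground-truth
#'   [EdgePrintSet-class] for cells alive in all frames) and `config`.
#' @examples
#' sim <- simulateCellMovie(simConfig(nCells = 2, imageShape = c(128, 128),
#'                                    nFrames = 3, seed = 7))
#' sim$movie
#' @export
simulateCellMovie <- function(config, M = 360L) {
  cfg <- config
  validObject(cfg)
  set.seed(cfg@seed)
  shape <- cfg@imageShape
  nF <- cfg@nFrames
  thetaDense <- seq(0, 2 * pi, length.out = 721L)[-721L]
  thetaM <- seq(0, 2 * pi, length.out = M + 1L)[-(M + 1L)]

  centers0 <- placeCells(cfg)
  dividing <- !is.na(cfg@divisionFrame)
  if (dividing && (cfg@divisionFrame < 2L || cfg@divisionFrame > nF - 1L))
    stop("divisionFrame must lie strictly inside the movie")

  # per-cell PRW tracks in um, converted to px displacements about placement
  cells <- vector("list", cfg@nCells)
  for (i in seq_len(cfg@nCells)) {
    xy <- simulatePRWTrack(cfg@speed[i], cfg@persistence[i],
                           cfg@frameInterval, nF)
    phases <- runif(max(1, nrow(cfg@boundaryModes)), 0, 2 * pi)
    cells[[i]] <- list(id = i, frames = seq_len(nF),
                       centerPx = cbind(centers0[i, 1] + xy[, 2] / cfg@pixelSize,
                                        centers0[i, 2] + xy[, 1] / cfg@pixelSize),
                       phases = phases, scale = 1)
  }
  if (dividing) {
    par <- cells[[1]]
    f <- cfg@divisionFrame
    dir <- runif(1, 0, 2 * pi)
    offPx <- 0.9 * cfg@baseRadius / cfg@pixelSize
    parent <- par; parent$frames <- seq_len(f - 1L)
    parent$centerPx <- par$centerPx[seq_len(f - 1L), , drop = FALSE]
    kids <- lapply(1:2, function(k) {
      sgn <- if (k == 1) 1 else -1
      xy <- simulatePRWTrack(cfg@speed[1], cfg@persistence[1],
                             cfg@frameInterval, nF - f + 1L)
      start <- par$centerPx[f, ] + sgn * offPx * c(sin(dir), cos(dir))
      list(id = cfg@nCells + k, frames = f:nF,
           centerPx = cbind(start[1] + xy[, 2] / cfg@pixelSize,
                            start[2] + xy[, 1] / cfg@pixelSize),
           phases = runif(max(1, nrow(cfg@boundaryModes)), 0, 2 * pi),
           scale = 1 / sqrt(2))
    })
    cells <- c(list(parent), cells[-1], kids)
  }

  frames <- array(0, c(shape[1], shape[2], nF))
  labels <- array(0L, c(shape[1], shape[2], nF))
  rec <- list()
  boundaries <- list()
  radiiGT <- list()   # per cell: M x nFrames radii (um) about the true centroid

  for (cell in cells) {
    cid <- as.character(cell$id)
    boundaries[[cid]] <- vector("list", nF)
    radiiGT[[cid]] <- matrix(NA_real_, M, nF)
    for (k in seq_along(cell$frames)) {
      f <- cell$frames[k]
      tH <- (f - 1L) * cfg@frameInterval / 60
      radUm <- cell$scale * starRadius(thetaDense, tH, cfg, cell$phases,
                                       biasIntervals = f - 1L)
      if (any(radUm <= 0)) stop("boundary modes exceed base radius")
      ctr <- cell$centerPx[k, ]
      poly <- starPolygon(ctr, radUm, thetaDense, cfg@pixelSize)
      ras <- rasterizeCell(shape, ctr, radUm, thetaDense, cfg@pixelSize)
      sub <- labels[ras$rows + 1L, ras$cols + 1L, f]
      sub[ras$inside] <- cell$id
      labels[ras$rows + 1L, ras$cols + 1L, f] <- sub
      # geometric (area) centroid of the true polygon, px
      cen <- polygonCentroid(poly)
      boundaries[[cid]][[f]] <- poly
      radiiGT[[cid]][, f] <- polarRadiiFromPolygon(poly, cen, thetaM) *
        cfg@pixelSize
      rec[[length(rec) + 1L]] <- data.frame(
        cell_id = cid, frame = f,
        centroid_row = cen[1], centroid_col = cen[2],
        area = sum(ras$inside), mean_intensity = cfg@foreground)
    }
  }

  ceiling12 <- 2^cfg@bitDepth - 1
  for (f in seq_len(nF)) {
    img <- matrix(cfg@background, shape[1], shape[2])
    img[labels[, , f] > 0] <- cfg@foreground
    if (cfg@noiseSd > 0)
      img <- img + matrix(rnorm(length(img), 0, cfg@noiseSd), shape[1])
    frames[, , f] <- pmin(pmax(img, 0), ceiling12)
  }

  records <- do.call(rbind, rec)
  records <- records[order(records$cell_id, records$frame), ]
  rownames(records) <- NULL
  events <- if (dividing)
    data.frame(frame = cfg@divisionFrame, case = "DIVISION", parent = "1",
               children = paste(cfg@nCells + 1:2, collapse = "+"))
  else data.frame(frame = integer(0), case = character(0),
                  parent = character(0), children = character(0))
  tracks <- new("TrackSet", records = records, boundaries = boundaries,
                nFrames = nF, pixelSize = cfg@pixelSize,
                frameInterval = cfg@frameInterval, events = events)

  # ground-truth edge prints for cells alive in every frame
  full <- names(radiiGT)[vapply(radiiGT, function(m) !anyNA(m), logical(1))]
  tau <- cfg@frameInterval
  pr <- re <- matrix(0, length(full), nF - 1L,
                     dimnames = list(full, NULL))
  for (i in seq_along(full)) {
    R <- radiiGT[[full[i]]]
    d <- R[, -1L, drop = FALSE] - R[, -nF, drop = FALSE]
    pr[i, ] <- colMeans(pmax(d, 0)) / tau
    re[i, ] <- colMeans(pmax(-d, 0)) / tau
  }
  prints <- new("EdgePrintSet", protrusion = pr, retraction = re,
                tau = tau, normalized = TRUE)

  movie <- new("CellMovie", frames = frames, pixelSize = cfg@pixelSize,
               frameInterval = cfg@frameInterval, bitDepth = cfg@bitDepth)
  list(movie = movie, labels = labels, tracks = tracks,
       edgePrints = prints, config = cfg)
}

#' Reference mean feature vectors of four motility phenotypes
#'
#' Mean values of the eight whole-cell motility features for four canonical
#' phenotypes of cultured motile cells: (1) slow and unpersistent, (2) slow
#' but persistent, (3) fast and persistent, (4) fast but unpersistent.
#' Used as the default component means of [simulateFeatureTable()].
#'
#' @return an 8 x 4 numeric matrix (features x classes).
#' @export
motilityClassMeans <- function() {
  m <- cbind(
    class1 = c(9.50, 1.46, 0.10, 15.07, 1.85, 2.32, 0.30, 13.87),
    class2 = c(9.53, 8.93, 0.41, 14.46, 6.10, 8.30, 1.50, 85.10),
    class3 = c(11.95, 10.57, 0.34, 16.89, 6.55, 56.76, 3.41, 126.31),
    class4 = c(12.32, 0.82, 0.34, 17.27, 6.04, 21.96, 1.98, 10.10))
  rownames(m) <- motilityFeatureNames()
  m
}

#' Names of the eight whole-cell motility features
#' @return character(8)
#' @export
motilityFeatureNames <- function() {
  c("speed_um_per_h", "persistence_h", "chemotactic_index",
    "total_path_length_um", "total_displacement_um",
    "random_motility_coeff", "mean_path_length_um", "persistence_length_um")
}

#' Draw a labelled sample from a Gaussian mixture
#'
#' I.i.d. draws from a K-component Gaussian mixture with the true component
#' label of every row retained, for closed-loop testing of mixture fitting
#' and model-order selection.
#'
#' @param classMeans n_features x K matrix of component means (default:
#'   [motilityClassMeans()]).
#' @param classCovariances list of K covariance matrices, a single matrix
#'   recycled for all components, or a scalar s for isotropic `s^2 I`
#'   (default 1, i.e. unit isotropic).
#' @param classWeights mixing proportions (default uniform); must sum to 1.
#' @param nSamples number of rows to draw.
#' @param seed optional integer seed.
#' @return data.frame of features plus a `.class` integer column of true
#'   component labels.
#' @examples
#' tab <- simulateFeatureTable(nSamples = 100, seed = 1)
#' table(tab$.class)
#' @export
simulateFeatureTable <- function(classMeans = motilityClassMeans(),
                                 classCovariances = 1,
                                 classWeights = NULL,
                                 nSamples = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- ncol(classMeans)
  n <- nrow(classMeans)
  if (is.null(classWeights)) classWeights <- rep(1 / K, K)
  if (abs(sum(classWeights) - 1) > 1e-8)
    stop("classWeights must sum to 1")
  if (is.numeric(classCovariances) && !is.matrix(classCovariances) &&
      length(classCovariances) == 1) {
    classCovariances <- replicate(K, diag(classCovariances^2, n),
                                  simplify = FALSE)
  } else if (is.matrix(classCovariances)) {
    classCovariances <- replicate(K, classCovariances, simplify = FALSE)
  }
  for (S in classCovariances) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8 * max(abs(ev), 1)))
      stop("covariances must be positive semi-definite")
  }
  lab <- sample.int(K, nSamples, replace = TRUE, prob = classWeights)
  X <- matrix(NA_real_, nSamples, n)
  for (k in seq_len(K)) {
    idx <- which(lab == k)
    if (length(idx))
      X[idx, ] <- MASS::mvrnorm(length(idx), classMeans[, k],
                                classCovariances[[k]])
  }
  out <- as.data.frame(X)
  names(out) <- rownames(classMeans) %||% paste0("f", seq_len(n))
  out$.class <- lab
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
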