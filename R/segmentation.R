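#' Two-phase piecewise-constant (Chan-Vese) segmentation
#'
#' Segments bright objects from a dark background by minimizing the discrete
#' two-phase piecewise-constant energy
#' \deqn{E(\Omega, c_1, c_2) = \sum_{p \in \Omega} (I_p - c_1)^2 +
#'   \sum_{p \notin \Omega} (I_p - c_2)^2 + \mu \, \mathrm{Per}(\Omega),}
#' the region-based active-contour energy "without edges": no image gradients
#' are involved, so the result does not depend on an initial contour and does
#' not leak through weak boundaries. `Per` is the 4-neighbour boundary length
#' of the foreground set and `mu` (`lengthWeight`) is the only regularization
#' term.
#'
#' Minimization alternates exact updates of the region means with
#' checkerboard sweeps of single-pixel moves, each accepted only if it lowers
#' the energy; the energy is therefore non-increasing at every step (the trace
#' is returned in the `energy` attribute). Iteration stops when the relative
#' energy change over a sweep falls below `tol`.
#'
#' @param frame numeric matrix of intensities (non-negative, >= 16x16).
#' @param lengthWeight boundary-length weight `mu`; default
#'   `0.1 * diff(range(frame))^2`, scaling the penalty to the image's
#'   intensity dynamic range.
#' @param tol relative energy-change stopping tolerance (default 1e-6).
#' @param maxIter maximum number of sweeps (default 100).
#' @return integer 0/1 matrix (1 = foreground, the brighter phase), with
#'   attributes `energy` (per-sweep energy trace), `means` (c1, c2) and
#'   `flat` (TRUE when the image was constant and an empty mask is returned
#'   with a warning).
#' @examples
#' img <- matrix(200, 64, 64)
#' img[20:40, 20:40] <- 3000
#' m <- chanVese(img)
#' sum(m) # ~ 21^2
#' @export
chanVese <- function(frame, lengthWeight = NULL, tol = 1e-6, maxIter = 100L) {
  stopifnot(is.matrix(frame), min(dim(frame)) >= 16L)
  rng <- range(frame)
  if (diff(rng) < .Machine$double.eps * max(1, rng[2])) {
    warning("constant image: returning empty foreground")
    out <- matrix(0L, nrow(frame), ncol(frame))
    attr(out, "flat") <- TRUE
    attr(out, "energy") <- numeric(0)
    return(out)
  }
  if (is.null(lengthWeight)) lengthWeight <- 0.1 * diff(rng)^2
  stopifnot(lengthWeight >= 0)
  mu <- lengthWeight
  I <- frame
  phi <- I > mean(rng)                   # init: threshold at mid-range
  if (!any(phi)) phi <- I > mean(I)
  nr <- nrow(I); nc <- ncol(I)
  checker <- outer(seq_len(nr), seq_len(nc), "+") %% 2L == 0L

  nbSum <- function(m) {
    # sum of 4-neighbour values, zero-padded borders
    s <- matrix(0, nr, nc)
    s[-1, ] <- s[-1, ] + m[-nr, ]
    s[-nr, ] <- s[-nr, ] + m[-1, ]
    s[, -1] <- s[, -1] + m[, -nc]
    s[, -nc] <- s[, -nc] + m[, -1]
    s
  }
  nNb <- nbSum(matrix(1, nr, nc))        # 2..4 valid neighbours per pixel

  perimeter <- function(phi) {
    p <- phi * 1
    sum(abs(p[-1, ] - p[-nr, ])) + sum(abs(p[, -1] - p[, -nc]))
  }
  energyOf <- function(phi, c1, c2) {
    sum((I[phi] - c1)^2) + sum((I[!phi] - c2)^2) + mu * perimeter(phi)
  }

  energy <- numeric(0)
  for (iter in seq_len(maxIter)) {
    c1 <- mean(I[phi]); c2 <- mean(I[!phi])
    if (!is.finite(c1)) c1 <- rng[2]
    if (!is.finite(c2)) c2 <- rng[1]
    for (color in c(TRUE, FALSE)) {
      nFg <- nbSum(phi * 1)
      nSame <- ifelse(phi, nFg, nNb - nFg)
      dPer <- 2 * nSame - nNb            # perimeter change if pixel flips
      dData <- ifelse(phi, (I - c2)^2 - (I - c1)^2,
                           (I - c1)^2 - (I - c2)^2)
      flip <- (dData + mu * dPer < 0) & (checker == color)
      phi[flip] <- !phi[flip]
    }
    energy <- c(energy, energyOf(phi, mean(I[phi]), mean(I[!phi])))
    if (iter > 1 &&
        abs(energy[iter - 1] - energy[iter]) <= tol * abs(energy[iter - 1]))
      break
  }
  # foreground must be the brighter phase
  if (any(phi) && any(!phi) && mean(I[phi]) < mean(I[!phi])) phi <- !phi
  out <- matrix(as.integer(phi), nr, nc)
  attr(out, "energy") <- energy
  attr(out, "means") <- c(fg = mean(I[phi]), bg = mean(I[!phi]))
  attr(out, "flat") <- FALSE
  out
}

#' Split touching cells by marker-controlled watershed
#'
#' Connected foreground components that contain more than one cell are split
#' along watershed lines of the (negated) distance transform. Markers are the
#' regional maxima of a Gaussian-smoothed distance transform (smoothing with
#' `sigma` suppresses spurious maxima from boundary roughness); components
#' supporting a single marker pass through unchanged. The union of foreground
#' pixels is never altered, only subdivided.
#'
#' @param mask binary (0/1) matrix, e.g. from [chanVese()].
#' @param sigma Gaussian smoothing sd for the distance map, pixels (default 2).
#' @param tolerance minimum water depth (in distance-map units) separating two
#'   markers; shallower maxima are merged (default 1).
#' @return integer label matrix with contiguous labels `1..L`
#'   (0 = background).
#' @export
splitTouching <- function(mask, sigma = 2, tolerance = 1) {
  stopifnot(is.matrix(mask))
  if (!any(mask > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  m <- (mask > 0) * 1
  dm <- EBImage::distmap(m)
  sm <- EBImage::gblur(dm, sigma = sigma)
  sm[m == 0] <- 0
  ws <- EBImage::watershed(sm, tolerance = tolerance, ext = 1)
  lab <- matrix(as.integer(ws), nrow(mask), ncol(mask))
  # watershed on the smoothed map can leave stray foreground pixels at 0;
  # assign them to the nearest label so the foreground union is conserved
  orphan <- which(lab == 0L & m == 1)
  if (length(orphan)) {
    for (p in orphan) {
      # nearest labelled pixel within the same component, by expanding rings
      rc <- arrayInd(p, dim(lab))
      found <- 0L
      for (rad in 1:32) {
        rr <- max(1, rc[1] - rad):min(nrow(lab), rc[1] + rad)
        cc <- max(1, rc[2] - rad):min(ncol(lab), rc[2] + rad)
        sub <- lab[rr, cc]
        cand <- sub[sub > 0L]
        if (length(cand)) { found <- as.integer(names(which.max(table(cand)))); break }
      }
      lab[p] <- found
    }
  }
  relabelContiguous(lab)
}

relabelContiguous <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (!length(u)) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Extract per-cell regions from a label mask
#'
#' For every label: pixel count, intensity-unweighted geometric centroid
#' ((row, col), 0-based, pixel centres at integer coordinates), mean intensity
#' over the region, and the ordered outer boundary polygon traced at the 0.5
#' iso-level of the label indicator (sub-pixel, counter-clockwise). Labels
#' smaller than `minArea` pixels are dropped.
#'
#' @param labelMask integer label matrix (0 = background).
#' @param frame intensity matrix of the same shape.
#' @param minArea minimum region size in pixels (default 50).
#' @return list with `table` (data.frame: `label`, `centroid_row`,
#'   `centroid_col`, `area`, `mean_intensity`) and `boundaries` (named list of
#'   (row, col) polygon matrices, keyed by label).
#' @export
extractRegions <- function(labelMask, frame, minArea = 50L) {
  stopifnot(identical(dim(labelMask), dim(frame)))
  labs <- sort(unique(labelMask[labelMask > 0L]))
  rows <- list(); bnds <- list()
  for (l in labs) {
    idx <- which(labelMask == l)
    if (length(idx) < minArea) next
    rc <- arrayInd(idx, dim(labelMask))
    ctr <- colMeans(rc) - 1              # 0-based pixel centres
    poly <- traceBoundary(labelMask == l, rc)
    rows[[length(rows) + 1L]] <- data.frame(
      label = l, centroid_row = ctr[1], centroid_col = ctr[2],
      area = length(idx), mean_intensity = mean(frame[idx]))
    bnds[[as.character(l)]] <- poly
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), area = integer(0),
               mean_intensity = numeric(0))
  list(table = tab, boundaries = bnds)
}

## sub-pixel outer boundary of a binary region via the 0.5 contour of its
## indicator, computed on a padded bounding-box crop; returns (row, col)
## vertices, 0-based, counter-clockwise
traceBoundary <- function(bin, rc = NULL) {
  if (is.null(rc)) rc <- which(bin, arr.ind = TRUE)
  r0 <- max(1L, min(rc[, 1]) - 2L); r1 <- min(nrow(bin), max(rc[, 1]) + 2L)
  c0 <- max(1L, min(rc[, 2]) - 2L); c1 <- min(ncol(bin), max(rc[, 2]) + 2L)
  z <- bin[r0:r1, c0:c1] * 1
  cl <- grDevices::contourLines(x = seq(r0, r1) - 1, y = seq(c0, c1) - 1,
                                z = z, levels = 0.5)
  if (!length(cl)) return(NULL)
  best <- cl[[which.max(vapply(cl, function(ct) length(ct$x), numeric(1)))]]
  poly <- cbind(row = best$x, col = best$y)
  # drop duplicated closing vertex if present
  n <- nrow(poly)
  if (n > 1 && all(abs(poly[1, ] - poly[n, ]) < 1e-12))
    poly <- poly[-n, , drop = FALSE]
  # one pass of circular 3-point averaging removes the half-pixel staircase
  # of the marching-squares contour (its zigzag inflates perimeter estimates)
  n <- nrow(poly)
  if (n >= 8) {
    prv <- poly[c(n, 1:(n - 1)), , drop = FALSE]
    nxt <- poly[c(2:n, 1), , drop = FALSE]
    poly <- (prv + poly + nxt) / 3
  }
  if (polygonArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  poly
}

#' Segment every frame of a movie
#'
#' Runs [chanVese()] then [splitTouching()] then [extractRegions()] frame by
#' frame.
#'
#' @param movie a [CellMovie-class].
#' @param lengthWeight,tol,maxIter passed to [chanVese()].
#' @param sigma,tolerance passed to [splitTouching()].
#' @param minArea passed to [extractRegions()].
#' @return list with `labels` (integer array rows x cols x frames) and
#'   `regions` (per-frame list of [extractRegions()] results).
#' @export
segmentMovie <- function(movie, lengthWeight = NULL, tol = 1e-6,
                         maxIter = 100L, sigma = 2, tolerance = 1,
                         minArea = 50L) {
  stopifnot(is(movie, "CellMovie"))
  nF <- nFrames(movie)
  d <- dim(movie@frames)
  labels <- array(0L, d)
  regions <- vector("list", nF)
  for (f in seq_len(nF)) {
    img <- getFrame(movie, f)
    lab <- splitTouching(chanVese(img, lengthWeight, tol, maxIter),
                         sigma = sigma, tolerance = tolerance)
    labels[, , f] <- lab
    regions[[f]] <- extractRegions(lab, img, minArea = minArea)
  }
  list(labels = labels, regions = regions)
}
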