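## ---- polygon geometry -----------------------------------------------------

## signed area (shoelace); polygon rows are (row, col) vertices, open or closed
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

## area centroid of a simple polygon (shoelace centroid)
polygonCentroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * A)
}

## outermost intersection radius of equiangular rays with a polygon.
## poly: (row, col) vertices; center: (row, col); angles: radians, with the
## angle measured as atan2(drow, dcol). Returns radii in the polygon's units.
polarRadiiFromPolygon <- function(poly, center, angles) {
  p1 <- sweep(poly, 2, center)            # vertices relative to the center
  n <- nrow(p1)
  j <- c(2:n, 1)
  d1 <- p1[j, 1] - p1[, 1]
  d2 <- p1[j, 2] - p1[, 2]
  u1 <- sin(angles); u2 <- cos(angles)    # ray direction in (row, col)
  # solve p1 + s*d = r*u per (angle, edge) via 2-D cross products
  denom <- outer(u1, d2) - outer(u2, d1)            # cross(u, d)
  crossP1D <- p1[, 1] * d2 - p1[, 2] * d1           # cross(p1, d), per edge
  crossP1U <- outer(u2, p1[, 1]) - outer(u1, p1[, 2])  # cross(p1, u)[angle, edge]
  R <- rep(1, length(angles)) %o% crossP1D / denom
  S <- crossP1U / denom
  eps <- 1e-12
  ok <- abs(denom) > eps & S >= -1e-9 & S <= 1 + 1e-9 & R > 0
  R[!ok] <- -Inf
  radii <- apply(R, 1, max)
  if (any(!is.finite(radii)))
    stop("center lies outside the polygon (no ray intersection)")
  radii
}

## ---- edge dynamics --------------------------------------------------------

#' Resample a cell boundary onto equiangular polar markers
#'
#' Places `M` markers at equally spaced angles around the given centre and
#' records, for each marker, the distance from the centre to the outermost
#' intersection of its ray with the boundary polygon (so protruding tips are
#' preserved for non-star-shaped outlines). Angles are measured as
#' `atan2(d_row, d_col)` in the image's (row, col) frame.
#'
#' @param boundary two-column matrix of (row, col) polygon vertices in pixel
#'   coordinates, in order (closure implied).
#' @param centroid centre of the polar frame, (row, col); defaults to the
#'   polygon's area centroid.
#' @param M number of markers (>= 8; default 360, i.e. 1 degree resolution).
#' @param pixelSize micrometres per pixel; radii are returned in um.
#' @return list with `angles` (radians, length M) and `radii` (um, length M).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 181)[-181]
#' circ <- cbind(10 * sin(th), 10 * cos(th))
#' pb <- polarResample(circ, c(0, 0), M = 36, pixelSize = 1)
#' range(pb$radii)  # all ~10
#' @export
polarResample <- function(boundary, centroid = NULL, M = 360L, pixelSize = 1) {
  M <- as.integer(M)
  if (M < 8L) stop("M must be >= 8")
  if (is.null(centroid)) centroid <- polygonCentroid(boundary)
  angles <- seq(0, 2 * pi, length.out = M + 1L)[-(M + 1L)]
  radii <- polarRadiiFromPolygon(boundary, centroid, angles) * pixelSize
  list(angles = angles, radii = radii)
}

#' Signed per-marker boundary displacement between two frames
#'
#' Difference of the centroid-aligned polar radii of the same cell at two
#' frames, per marker: positive values are protrusion, negative retraction.
#'
#' @param polarT,polarT1 outputs of [polarResample()] at times t and t + tau,
#'   each aligned on its own frame's centroid.
#' @return numeric vector of signed displacements in um, one per marker.
#' @export
boundaryDisplacement <- function(polarT, polarT1) {
  if (length(polarT$radii) != length(polarT1$radii) ||
      max(abs(polarT$angles - polarT1$angles)) > 1e-9)
    stop("polar boundaries must share the same marker grid")
  polarT1$radii - polarT$radii
}

#' Compute edge prints (protrusion/retraction velocities) for tracked cells
#'
#' For every complete track, the cell boundary at each frame is resampled onto
#' `M` equiangular polar markers about that frame's own centroid (centroid
#' alignment removes whole-cell translation). For each interval the signed
#' marker displacements are split into their positive and negative parts:
#' \deqn{p_t = \frac{1}{M\tau} \sum_m \max(\Delta_m, 0), \qquad
#'       r_t = \frac{1}{M\tau} \sum_m \max(-\Delta_m, 0),}
#' giving per-marker protrusion and retraction velocities in um/min. A movie
#' of T frames yields 2(T-1) features per cell (22 when T = 12). With
#' `normalize = FALSE` the raw summed marker displacement per interval is
#' returned instead (um, not divided by M or tau).
#'
#' Cells missing a boundary at any frame are dropped with a message.
#'
#' @param tracks a [TrackSet-class] with boundary polygons.
#' @param M markers per boundary (default 360).
#' @param lag interval in frames between compared boundaries (default 1, so
#'   tau equals the frame interval).
#' @param normalize divide by M and tau (default TRUE).
#' @param cells cell ids to process (default: all complete tracks).
#' @return an [EdgePrintSet-class].
#' @export
edgePrint <- function(tracks, M = 360L, lag = 1L, normalize = TRUE,
                      cells = NULL) {
  stopifnot(is(tracks, "TrackSet"))
  nF <- nFrames(tracks)
  lag <- as.integer(lag)
  if (lag < 1L || lag >= nF) stop("lag must be in 1..nFrames-1")
  tau <- lag * frameInterval(tracks)
  if (is.null(cells)) cells <- completeTracks(tracks)
  keep <- logical(length(cells))
  radList <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    bl <- lapply(seq_len(nF), function(f) trackBoundary(tracks, cells[i], f))
    if (any(vapply(bl, is.null, logical(1)))) {
      message("edgePrint: cell ", cells[i],
              " lacks a boundary in some frame; excluded")
      next
    }
    radList[[i]] <- vapply(bl, function(b)
      polarResample(b, M = M, pixelSize = pixelSize(tracks))$radii,
      numeric(M))
    keep[i] <- TRUE
  }
  cells <- cells[keep]; radList <- radList[keep]
  nInt <- nF - lag
  pr <- re <- matrix(0, length(cells), nInt, dimnames = list(cells, NULL))
  for (i in seq_along(cells)) {
    R <- radList[[i]]
    d <- R[, seq_len(nInt) + lag, drop = FALSE] -
         R[, seq_len(nInt), drop = FALSE]
    if (normalize) {
      pr[i, ] <- colMeans(pmax(d, 0)) / tau
      re[i, ] <- colMeans(pmax(-d, 0)) / tau
    } else {
      pr[i, ] <- colSums(pmax(d, 0))
      re[i, ] <- colSums(pmax(-d, 0))
    }
  }
  colnames(pr) <- paste0("p_", seq_len(nInt))
  colnames(re) <- paste0("r_", seq_len(nInt))
  new("EdgePrintSet", protrusion = pr, retraction = re, tau = tau,
      normalized = normalize)
}

#' Long-format per-marker displacement table
#'
#' Exports, for one cell, the signed radial displacement of every marker at
#' every interval (angle on X, radial difference on Y) for boundary-activity
#' plots.
#'
#' @inheritParams edgePrint
#' @param cell a single cell id.
#' @return data.frame with columns `interval`, `angle`, `displacement_um`.
#' @export
markerDisplacementTable <- function(tracks, cell, M = 360L, lag = 1L) {
  nF <- nFrames(tracks)
  pb <- lapply(seq_len(nF), function(f) {
    b <- trackBoundary(tracks, cell, f)
    if (is.null(b)) stop("cell ", cell, " has no boundary at frame ", f)
    polarResample(b, M = M, pixelSize = pixelSize(tracks))
  })
  out <- lapply(seq_len(nF - lag), function(t)
    data.frame(interval = t, angle = pb[[t]]$angles,
               displacement_um = boundaryDisplacement(pb[[t]], pb[[t + lag]])))
  do.call(rbind, out)
}
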