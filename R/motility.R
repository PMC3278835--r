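#' Mean squared displacement of a track
#'
#' Time-averaged MSD over all lags `1..T-1` using overlapping interval pairs:
#' at lag k there are `T - k` pairs. Coordinates are converted to micrometres
#' and lags to hours before squaring, so the curve is directly comparable to
#' the persistent-random-walk closed form [prwMSD()].
#'
#' @param xy T x 2 matrix of positions. Interpreted as micrometres when
#'   `pixelSize = 1`.
#' @param pixelSize micrometres per coordinate unit (use the movie's pixel
#'   size when `xy` is in pixels).
#' @param frameInterval minutes between rows of `xy`.
#' @return data.frame of class `MSDCurve` with columns `lag_h`, `msd_um2`,
#'   `n_pairs`.
#' @examples
#' xy <- cbind(0:10, 0) # straight line, 1 um per step
#' computeMSD(xy, 1, 60)$msd_um2 # (k)^2
#' @export
computeMSD <- function(xy, pixelSize = 1, frameInterval = 10) {
  xy <- as.matrix(xy)
  T <- nrow(xy)
  stopifnot(T >= 3L, ncol(xy) == 2L)
  um <- xy * pixelSize
  dtH <- frameInterval / 60
  lags <- seq_len(T - 1L)
  msd <- vapply(lags, function(k) {
    d <- um[(k + 1):T, , drop = FALSE] - um[1:(T - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  out <- data.frame(lag_h = lags * dtH, msd_um2 = msd, n_pairs = T - lags)
  class(out) <- c("MSDCurve", class(out))
  out
}

#' Fit the persistent-random-walk model to an MSD curve
#'
#' Weighted nonlinear least squares of
#' `MSD(t) = 2 S^2 P (t - P (1 - exp(-t/P)))` with box constraints
#' `S, P > 0`. Residuals are weighted by the number of overlapping pairs at
#' each lag (the sampling variance of a time-averaged MSD point scales as
#' `1/n_pairs`, so short lags carry more weight). Several starting points are
#' tried -- a diffusive guess from the long-lag slope and ballistic guesses
#' from the first lag over a grid of persistence values -- and the converged
#' fit with the lowest weighted residual sum of squares is returned.
#'
#' By default only the shortest `max(minLags, lagFrac * (T - 1))` lags are
#' fitted: long-lag points of a single-track time-averaged MSD are dominated
#' by realization noise (few independent pairs), and restricting the fit to
#' the early part of the curve is the standard remedy. Set `lagFrac = 1` to
#' use the whole curve.
#'
#' When the best fit pushes `P` beyond the observation window the track is
#' effectively ballistic over the experiment and the `flag` field says so;
#' when no start converges, the fallback estimates are the mean
#' frame-to-frame speed and the frame interval, flagged `"fallback"`, never a
#' silent failure.
#'
#' @param msd an `MSDCurve` from [computeMSD()] (or any data.frame with
#'   `lag_h`, `msd_um2`, `n_pairs`).
#' @param lagFrac fraction of available lags to fit (default 0.25).
#' @param minLags minimum number of lags to fit (default 5).
#' @return list with `S` (um/h), `P` (h), `converged`, `flag` (`"ok"`,
#'   `"ballistic"` or `"fallback"`) and `rss` (weighted residual sum of
#'   squares).
#' @examples
#' t <- (1:11) / 6
#' curve <- data.frame(lag_h = t, msd_um2 = prwMSD(t, 10, 1.46),
#'                     n_pairs = 11:1)
#' fitPRW(curve)[c("S", "P")]
#' @export
fitPRW <- function(msd, lagFrac = 0.25, minLags = 5L) {
  stopifnot(all(c("lag_h", "msd_um2", "n_pairs") %in% names(msd)))
  msd <- msd[msd$lag_h > 0, ]
  if (nrow(msd) < 3L) stop("need at least 3 positive-lag MSD points")
  msd <- msd[order(msd$lag_h), ]
  keep <- min(nrow(msd), max(minLags, ceiling(lagFrac * nrow(msd))))
  msd <- msd[seq_len(keep), ]
  t <- msd$lag_h; y <- msd$msd_um2; w <- msd$n_pairs
  tmax <- max(t)
  if (all(y <= 1e-12)) # stationary track
    return(list(S = 0, P = tmax, converged = TRUE, flag = "degenerate",
                rss = 0))
  # starts: ballistic S from first lag, over a grid of P; diffusive slope
  Sball <- sqrt(max(y[1], 1e-12)) / t[1]
  Dslope <- max((y[length(y)] - y[1]) / (t[length(t)] - t[1]), 1e-9)
  starts <- list()
  for (P0 in c(0.1, 0.5, 1, 5, 20) * tmax)
    starts <- c(starts, list(c(S = Sball, P = P0)),
                list(c(S = sqrt(Dslope / (2 * P0)), P = P0)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(msd_um2 ~ 2 * S^2 * P * (lag_h - P * (1 - exp(-lag_h / P))),
                        data = msd, start = as.list(st), weights = w,
                        lower = c(S = 1e-8, P = 1e-6),
                        upper = c(S = Inf, P = 1e6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      p <- coef(fit)
      best <- list(S = unname(p["S"]), P = unname(p["P"]), converged = TRUE,
                   flag = "ok", rss = rss)
    }
  }
  if (is.null(best)) {
    # fallback: mean frame-to-frame speed over the first lag, P = one interval
    dt1 <- t[1]
    return(list(S = sqrt(y[1]) / dt1, P = dt1, converged = FALSE,
                flag = "fallback", rss = NA_real_))
  }
  if (best$P > 10 * tmax) best$flag <- "ballistic"
  best
}

#' Speed times persistence: the persistence length
#'
#' Characteristic distance a cell travels before its direction decorrelates.
#'
#' @param S speed in um/h.
#' @param P persistence time in h.
#' @return persistence length in um.
#' @examples
#' persistenceLength(11.95, 10.57) # 126.31
#' @export
persistenceLength <- function(S, P) S * P

#' The eight whole-cell motility features
#'
#' Computes, per complete track, the canonical persistent-random-walk feature
#' panel: speed `S` and persistence `P` from [fitPRW()] on the track's MSD,
#' chemotactic index `CI = TD / TPL`, total path length `TPL` (sum of step
#' lengths, um), total displacement `TD` (start-to-end distance, um), random
#' motility coefficient `RMC = S^2 P / 2` (the 2-D long-time diffusion
#' coefficient of the PRW), mean path length `MPL = TPL / (T - 1)` (um per
#' step) and persistence length `PrL = S * P`.
#'
#' @param tracks a [TrackSet-class], or a T x 2 coordinate matrix for a
#'   single track.
#' @param pixelSize,frameInterval used only when `tracks` is a matrix;
#'   otherwise taken from the `TrackSet`.
#' @param cells cell ids to process (default: all complete tracks).
#' @return data.frame with one row per cell: `cell_id`, the eight features
#'   (named as in [motilityFeatureNames()]) plus `fit_converged` and
#'   `fit_flag`.
#' @examples
#' xy <- simulatePRWTrack(10, 2, 10, 100, seed = 1)
#' motilityFeatures(xy, pixelSize = 1, frameInterval = 10)
#' @export
motilityFeatures <- function(tracks, pixelSize = NULL, frameInterval = NULL,
                             cells = NULL) {
  if (is.matrix(tracks) || is.data.frame(tracks)) {
    xy <- as.matrix(tracks)
    tracksList <- list(`1` = xy)
    px <- pixelSize %||% 1
    dt <- frameInterval %||% 10
  } else {
    stopifnot(is(tracks, "TrackSet"))
    if (is.null(cells)) cells <- completeTracks(tracks)
    rec <- trackRecords(tracks)
    tracksList <- lapply(setNames(cells, cells), function(id) {
      r <- rec[rec$cell_id == id, ]
      r <- r[order(r$frame), ]
      cbind(r$centroid_col, r$centroid_row)   # (x, y) in px
    })
    px <- pixelSize(tracks)
    dt <- frameInterval(tracks)
  }
  out <- lapply(names(tracksList), function(id) {
    um <- tracksList[[id]] * px
    T <- nrow(um)
    steps <- sqrt(rowSums(diff(um)^2))
    TPL <- sum(steps)
    TD <- sqrt(sum((um[T, ] - um[1, ])^2))
    CI <- if (TPL > 0) TD / TPL else 0
    fit <- fitPRW(computeMSD(um, 1, dt))
    data.frame(cell_id = id,
               speed_um_per_h = fit$S,
               persistence_h = fit$P,
               chemotactic_index = CI,
               total_path_length_um = TPL,
               total_displacement_um = TD,
               random_motility_coeff = fit$S^2 * fit$P / 2,
               mean_path_length_um = TPL / (T - 1),
               persistence_length_um = persistenceLength(fit$S, fit$P),
               fit_converged = fit$converged,
               fit_flag = fit$flag)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
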