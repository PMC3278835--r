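# shared fixtures, all generated in code

# binary disc in an n x n matrix (1-based centre, radius in px)
mkDisc <- function(n, ctr, r) {
  rr <- outer((1:n - ctr[1])^2, (1:n - ctr[2])^2, "+")
  matrix(as.integer(rr <= r^2), n, n)
}

# polygon from a radius profile sampled at given angles ((row, col) px)
radialPolygon <- function(radii, angles, center = c(0, 0)) {
  cbind(row = center[1] + radii * sin(angles),
        col = center[2] + radii * cos(angles))
}

# TrackSet with externally supplied boundary polygons, one per frame per cell
syntheticTrackSet <- function(polysByCell, pixelSize = 1, frameInterval = 10) {
  nF <- length(polysByCell[[1]])
  recs <- list(); bnds <- list()
  for (id in names(polysByCell)) {
    bnds[[id]] <- polysByCell[[id]]
    for (f in seq_len(nF)) {
      ctr <- morphodyn:::polygonCentroid(polysByCell[[id]][[f]])
      recs[[length(recs) + 1L]] <- data.frame(
        cell_id = id, frame = f, centroid_row = ctr[1], centroid_col = ctr[2],
        area = abs(morphodyn:::polygonArea(polysByCell[[id]][[f]])),
        mean_intensity = 1000)
    }
  }
  new("TrackSet", records = do.call(rbind, recs), boundaries = bnds,
      nFrames = as.integer(nF), pixelSize = pixelSize,
      frameInterval = frameInterval,
      events = data.frame(frame = integer(0), case = character(0),
                          parent = character(0), children = character(0)))
}

# mean per-cell Dice between two label stacks, matching labels by overlap
labelDice <- function(gt, est) {
  dices <- c()
  for (f in seq_len(dim(gt)[3])) {
    g <- gt[, , f]; e <- est[, , f]
    for (id in setdiff(unique(as.vector(g)), 0L)) {
      gm <- g == id
      cand <- e[gm]; cand <- cand[cand > 0]
      if (!length(cand)) { dices <- c(dices, 0); next }
      l <- as.integer(names(which.max(table(cand))))
      em <- e == l
      dices <- c(dices, 2 * sum(gm & em) / (sum(gm) + sum(em)))
    }
  }
  dices
}

# match estimated track ids to ground-truth ids by first-frame proximity
matchTrackIds <- function(gtRecords, estRecords) {
  g1 <- gtRecords[gtRecords$frame == 1, ]
  e1 <- estRecords[estRecords$frame == 1, ]
  map <- vapply(seq_len(nrow(e1)), function(i)
    g1$cell_id[which.min((g1$centroid_row - e1$centroid_row[i])^2 +
                         (g1$centroid_col - e1$centroid_col[i])^2)],
    character(1))
  setNames(map, e1$cell_id)
}

# exact two-sided permutation p-value for Spearman correlation (all N! perms)
spearmanPermP <- function(x, y) {
  N <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  vals <- vapply(perms(seq_len(N)), function(p) abs(cor(rx, ry[p])),
                 numeric(1))
  mean(vals >= obs - 1e-12)
}
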