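regionTable <- function(rows, cols, areas = 200, ints = 1000) {
  data.frame(label = seq_along(rows), centroid_row = rows,
             centroid_col = cols, area = rep_len(areas, length(rows)),
             mean_intensity = rep_len(ints, length(rows)))
}

test_that("identical frames match one-to-one at zero cost", {
  tab <- regionTable(c(10, 40, 70), c(10, 40, 70))
  m <- matchFrames(tab, tab)
  expect_identical(m$matches$from, m$matches$to)
  expect_equal(max(m$matches$cost), 0)
  expect_length(m$lost, 0)
  expect_length(m$new, 0)
})

test_that("assignment minimizes total cost (exhaustive oracle on small frames)", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:5, 1)
    t1 <- regionTable(runif(n, 10, 90), runif(n, 10, 90),
                      areas = sample(150:250, n), ints = runif(n, 800, 1200))
    perm <- sample(n)
    t2 <- t1[perm, ]
    t2$centroid_row <- t2$centroid_row + runif(n, -4, 4)
    t2$centroid_col <- t2$centroid_col + runif(n, -4, 4)
    m <- matchFrames(t1, t2, gate = 200)
    # oracle: enumerate all permutations, minimize total cost
    costOf <- function(a, b) {
      0.5 * sqrt((t1$centroid_row[a] - t2$centroid_row[b])^2 +
                 (t1$centroid_col[a] - t2$centroid_col[b])^2) / 200 +
        0.25 * abs(t1$area[a] - t2$area[b]) / max(t1$area, t2$area) +
        0.25 * abs(t1$mean_intensity[a] - t2$mean_intensity[b]) /
          max(t1$mean_intensity, t2$mean_intensity)
    }
    allPerms <- function(v) {
      if (length(v) == 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(allPerms(v[-i]), function(p) c(v[i], p))))
    }
    bestTotal <- min(vapply(allPerms(seq_len(n)), function(p)
      sum(vapply(seq_len(n), function(a) costOf(a, p[a]), numeric(1))),
      numeric(1)))
    got <- sum(m$matches$cost)
    expect_equal(got, bestTotal, tolerance = 1e-10)
  }
})

test_that("one moved cell among static ones is matched correctly", {
  t1 <- regionTable(c(20, 50, 80), c(20, 50, 80))
  t2 <- t1
  t2$centroid_row[2] <- 55   # cell 2 moved 5 px
  m <- matchFrames(t1, t2)
  expect_identical(m$matches$from, m$matches$to)
})

test_that("a cell beyond the gate is LOST and spawns a new track", {
  t1 <- regionTable(c(20, 80), c(20, 80))
  t2 <- regionTable(c(20, 80), c(20, 80))
  t2$centroid_col[2] <- 80 + 120   # beyond the 50 px gate
  m <- matchFrames(t1, t2)
  expect_identical(m$matches$from, 1L)
  expect_identical(m$lost, 2L)
  expect_identical(m$new, 2L)

  # empty counterpart frame: everything LOST
  m0 <- matchFrames(t1, t1[0, ])
  expect_identical(m0$lost, c(1L, 2L))
})

test_that("weights must be a simplex", {
  t1 <- regionTable(20, 20)
  expect_error(matchFrames(t1, t1, weights = c(0.5, 0.5, 0.5)))
  expect_error(matchFrames(t1, t1, gate = -1))
})

test_that("tracks chain across frames; exits make incomplete tracks", {
  mk <- function(...) regionTable(...)
  regions <- list(mk(c(20, 60), c(20, 60)),
                  mk(c(22, 61), c(21, 62)),
                  mk(c(24), c(22)))          # second cell exits at frame 3
  tr <- buildTracks(regions, pixelSize = 1, frameInterval = 10)
  expect_identical(sort(unique(trackRecords(tr)$cell_id)), c("1", "2"))
  expect_identical(completeTracks(tr), "1")
  trC <- buildTracks(regions, completeOnly = TRUE,
                     pixelSize = 1, frameInterval = 10)
  expect_identical(unique(trackRecords(trC)$cell_id), "1")
  # conservation: each region belongs to at most one track
  rec <- trackRecords(tr)
  expect_false(any(duplicated(rec[, c("frame", "centroid_row")])))
})

test_that("tracking on generator masks recovers every link", {
  sim <- simulateCellMovie(simConfig(nCells = 6, imageShape = c(384, 384),
                                     seed = 13))
  regions <- lapply(seq_len(12), function(f)
    extractRegions(sim$labels[, , f], sim$movie@frames[, , f], minArea = 50))
  tr <- buildTracks(regions, labelMasks = sim$labels,
                    frames = sim$movie@frames,
                    pixelSize = 0.707, frameInterval = 10)
  expect_length(completeTracks(tr), 6)
  expect_identical(nrow(tr@events), 0L)
  map <- matchTrackIds(trackRecords(sim$tracks), trackRecords(tr))
  est <- trackRecords(tr); gt <- trackRecords(sim$tracks)
  for (eid in names(map)) {
    e <- est[est$cell_id == eid, ]; g <- gt[gt$cell_id == map[[eid]], ]
    mrg <- merge(e, g, by = "frame")
    d <- sqrt((mrg$centroid_row.x - mrg$centroid_row.y)^2 +
              (mrg$centroid_col.x - mrg$centroid_col.y)^2)
    expect_lt(max(d), 3)   # every frame-to-frame link followed the right cell
  }
})

test_that("a division event is recognized from three-frame continuity", {
  sim <- simulateCellMovie(simConfig(nCells = 4, imageShape = c(384, 384),
                                     divisionFrame = 6L, seed = 11))
  regions <- lapply(seq_len(12), function(f)
    extractRegions(sim$labels[, , f], sim$movie@frames[, , f], minArea = 50))
  tr <- buildTracks(regions, labelMasks = sim$labels,
                    frames = sim$movie@frames,
                    pixelSize = 0.707, frameInterval = 10)
  expect_true("DIVISION" %in% tr@events$case)
  expect_identical(tr@events$frame[tr@events$case == "DIVISION"], 6L)
  # divided lineage cannot be complete; the three bystanders are
  expect_length(completeTracks(tr), 3)
})

test_that("a one-frame artificial split is merged back as over-segmentation", {
  sim <- simulateCellMovie(simConfig(nCells = 4, imageShape = c(384, 384),
                                     seed = 3))
  regions <- lapply(seq_len(12), function(f)
    extractRegions(sim$labels[, , f], sim$movie@frames[, , f], minArea = 25))
  labels <- sim$labels
  f <- 6
  lab <- labels[, , f]
  l <- regions[[f]]$table$label[1]
  idx <- which(lab == l, arr.ind = TRUE)
  newl <- max(lab) + 1L
  lab[idx[idx[, 2] > median(idx[, 2]), , drop = FALSE]] <- newl
  labels[, , f] <- lab
  regions[[f]] <- extractRegions(lab, sim$movie@frames[, , f], minArea = 25)
  tr <- buildTracks(regions, labelMasks = labels, frames = sim$movie@frames,
                    pixelSize = 0.707, frameInterval = 10)
  expect_true("OVERSEG" %in% tr@events$case)
  expect_length(completeTracks(tr), 4)   # the split track is rescued

  # and without the perturbation, nothing is flagged
  regions[[f]] <- extractRegions(sim$labels[, , f], sim$movie@frames[, , f],
                                 minArea = 25)
  tr0 <- buildTracks(regions, labelMasks = sim$labels,
                     frames = sim$movie@frames,
                     pixelSize = 0.707, frameInterval = 10)
  expect_identical(nrow(tr0@events), 0L)
})
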