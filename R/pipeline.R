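#' Run the full morphodynamics pipeline
#'
#' Orchestrates movie -> segmentation -> tracking -> motility features ->
#' edge prints -> class discovery -> correlation reports, writing every
#' intermediate artifact (CSV/JSON) plus a structured log and a config echo
#' into `outputDir`. The run is deterministic given `seed`: each stochastic
#' stage draws from its own seed derived from the root.
#'
#' A tracks CSV (or [TrackSet-class]) can be supplied instead of a movie to
#' skip the imaging stages; downstream outputs are then identical to a full
#' run that produced the same tracks. Edge-print analysis requires
#' boundaries, so it is skipped for boundary-free track input.
#'
#' Class discovery fits a Gaussian mixture with MDL-selected order on the
#' standardized motility features ([selectK()]) when the sample is large
#' enough (N at least `5 * kRange[2]` and N > 8 features), otherwise it falls
#' back to [twoPhaseKmeans()] with `kRange[1]` clusters and says so in the
#' log. Within each class, edge prints are subclustered by [twoPhaseKmeans()]
#' (MDL-selected order when feasible, otherwise 2, capped at half the class
#' size). Correlation and factor-analysis reports are emitted per class when
#' the class has enough cells (N >= 4 for Spearman; N > predictors for
#' multiple correlation and factor analysis).
#'
#' @param input a [CellMovie-class], path to a multi-page TIFF, a
#'   [TrackSet-class], or path to a tracks CSV.
#' @param outputDir output directory (created if missing).
#' @param pixelSize,frameInterval movie metadata used when `input` is a path.
#' @param lengthWeight,minArea segmentation parameters (see [chanVese()],
#'   [extractRegions()]).
#' @param weights,gate,ratio tracking parameters (see [matchFrames()]).
#' @param M,lag edge-print parameters (see [edgePrint()]).
#' @param kRange candidate class counts `c(kMin, kMax)` (default `c(2, 10)`).
#' @param alpha significance level for correlation flags.
#' @param seed root seed for all stochastic stages.
#' @return invisibly, a list with the main in-memory results (`tracks`,
#'   `motility`, `edgePrints`, `classes`, `reports`) and `outputDir`.
#' @export
runPipeline <- function(input, outputDir,
                        pixelSize = 0.707, frameInterval = 10,
                        lengthWeight = NULL, minArea = 50L,
                        weights = defaultMatchWeights(), gate = 50,
                        ratio = 1.5, M = 360L, lag = 1L,
                        kRange = c(2L, 10L), alpha = 0.05, seed = 1L) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outputDir, "pipeline.log")
  logLines <- character(0)
  logStage <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    logLines <<- c(logLines, line)
    writeLines(logLines, logPath)
    message(line)
  }

  cfgEcho <- list(pixelSize = pixelSize, frameInterval = frameInterval,
                  lengthWeight = lengthWeight, minArea = minArea,
                  weights = as.list(weights), gate = gate, ratio = ratio,
                  M = M, lag = lag, kRange = kRange, alpha = alpha,
                  seed = seed)
  jsonlite::write_json(cfgEcho, file.path(outputDir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  ## ---- stages 1-2: segmentation + tracking (or tracks entry point) -------
  if (is(input, "TrackSet") ||
      (is.character(input) && grepl("\\.csv$", input, ignore.case = TRUE))) {
    tracks <- if (is(input, "TrackSet")) input else
      readTracksCSV(input, pixelSize, frameInterval)
    logStage("tracking: %d tracks loaded (imaging stages skipped)",
             length(unique(trackRecords(tracks)$cell_id)))
  } else {
    movie <- if (is(input, "CellMovie")) input else
      readCellMovie(input, pixelSize, frameInterval)
    seg <- segmentMovie(movie, lengthWeight = lengthWeight, minArea = minArea)
    nReg <- vapply(seg$regions, function(r) nrow(r$table), integer(1))
    logStage("segmentation: %d frames, %s cells per frame",
             nFrames(movie), paste(range(nReg), collapse = "-"))
    writeLabelMasks(seg$labels, file.path(outputDir, "labels.tif"))
    regAll <- do.call(rbind, lapply(seq_along(seg$regions), function(f)
      cbind(frame = f, seg$regions[[f]]$table)))
    write.csv(regAll, file.path(outputDir, "regions.csv"), row.names = FALSE)
    tracks <- buildTracks(seg$regions, weights = weights, gate = gate,
                          ratio = ratio, labelMasks = seg$labels,
                          frames = movie@frames,
                          pixelSize = pixelSize(movie),
                          frameInterval = frameInterval(movie))
    logStage("tracking: %d tracks, %d complete, %d events",
             length(unique(trackRecords(tracks)$cell_id)),
             length(completeTracks(tracks)), nrow(tracks@events))
  }
  writeTracksCSV(tracks, file.path(outputDir, "tracks.csv"))
  if (nrow(tracks@events))
    jsonlite::write_json(tracks@events, file.path(outputDir, "events.json"),
                         dataframe = "rows", digits = NA)
  full <- completeTracks(tracks)
  if (!length(full))
    stop("pipeline halted after tracking: no track spans every frame ",
         "(check gate distance and segmentation quality)")

  ## ---- stage 3: motility features ----------------------------------------
  motility <- motilityFeatures(tracks)
  write.csv(motility, file.path(outputDir, "motility.csv"), row.names = FALSE)
  logStage("motility: %d complete tracks, %d fit fallbacks",
           nrow(motility), sum(!motility$fit_converged))

  ## ---- stage 4: edge prints ----------------------------------------------
  prints <- NULL
  haveBoundaries <- length(tracks@boundaries) > 0
  if (haveBoundaries) {
    prints <- edgePrint(tracks, M = M, lag = lag)
    writeEdgePrintsCSV(prints, file.path(outputDir, "edge_prints.csv"))
    logStage("edge: %d cells x %d features",
             nrow(protrusion(prints)), 2L * ncol(protrusion(prints)))
  } else {
    logStage("edge: skipped (no boundaries in track input)")
  }

  ## ---- stage 5: class discovery ------------------------------------------
  feat <- as.matrix(motility[, motilityFeatureNames()])
  N <- nrow(feat)
  classes <- NULL
  if (N >= max(5 * kRange[1], ncol(feat) + 2)) {
    if (N >= 5 * kRange[2] && N > 2 * ncol(feat)) {
      sel <- selectK(feat, kMin = kRange[1], kMax = kRange[2],
                     seed = seed + 100L)
      classes <- sel$cluster
      logStage("profiling: MDL selected K = %d over %d..%d",
               sel$K, kRange[1], kRange[2])
      jsonlite::write_json(
        list(K = sel$K, mdl = as.list(sel$mdl),
             weights = sel$model@weights, means = sel$model@means,
             covariances = sel$model@covariances,
             logLik = sel$model@logLik),
        file.path(outputDir, "mixture_model.json"), auto_unbox = TRUE,
        digits = NA)
    } else {
      km <- twoPhaseKmeans(feat, kRange[1], seed = seed + 100L)
      classes <- km$cluster
      logStage("profiling: N = %d too small for MDL scan; two-phase K-means K = %d",
               N, kRange[1])
    }
  } else {
    classes <- rep(1L, N)
    logStage("profiling: N = %d too small to cluster; single class", N)
  }

  assign <- data.frame(cell_id = motility$cell_id, class = classes,
                       edge_subclass = NA_integer_)

  ## ---- stage 6: edge subclasses within each class ------------------------
  if (!is.null(prints)) {
    E <- edgeFeatureMatrix(prints)
    for (cl in sort(unique(classes))) {
      ids <- assign$cell_id[assign$class == cl]
      ids <- intersect(ids, rownames(E))
      if (length(ids) < 4L) next
      Ecl <- E[ids, , drop = FALSE]
      Ksub <- 2L
      if (nrow(Ecl) > 2 * ncol(Ecl)) {
        subSel <- tryCatch(selectK(Ecl, 2L, min(10L, nrow(Ecl) - 1L),
                                   seed = seed + 200L + cl),
                           error = function(e) NULL)
        if (!is.null(subSel)) Ksub <- subSel$K
      }
      Ksub <- min(Ksub, floor(length(ids) / 2))
      if (Ksub < 2L) next
      km <- twoPhaseKmeans(Ecl, Ksub, seed = seed + 300L + cl)
      assign$edge_subclass[match(ids, assign$cell_id)] <- km$cluster
      logStage("edge subclasses: class %d -> %d subclusters (%d cells)",
               cl, Ksub, length(ids))
    }
  }
  write.csv(assign, file.path(outputDir, "assignments.csv"),
            row.names = FALSE)

  ## ---- stage 7: correlation and factor analysis per class ----------------
  reports <- list()
  if (!is.null(prints)) {
    edgeSummary <- timeAverageEdge(prints)
    for (cl in sort(unique(classes))) {
      ids <- assign$cell_id[assign$class == cl]
      mot <- motility[motility$cell_id %in% ids, ]
      eds <- edgeSummary[edgeSummary$cell_id %in% ids, ]
      n <- nrow(merge(mot, eds, by = "cell_id"))
      if (n < 4L) { logStage("correlation: class %d skipped (N = %d)", cl, n); next }
      rep <- tryCatch(correlationReport(mot, eds, alpha = alpha),
                      error = function(e) NULL)
      if (is.null(rep)) { logStage("correlation: class %d failed", cl); next }
      reports[[as.character(cl)]] <- rep
      write.csv(rep$barplot_data,
                file.path(outputDir, sprintf("correlation_class%d.csv", cl)),
                row.names = FALSE)
      fa <- if (n > ncol(rep$table) - 1L)
        tryCatch(factorAnalysisFeatures(rep$table[, -1]),
                 error = function(e) NULL) else NULL
      if (!is.null(fa)) {
        write.csv(data.frame(feature = rownames(fa$loadings_suppressed),
                             fa$loadings_suppressed, check.names = FALSE),
                  file.path(outputDir, sprintf("factors_class%d.csv", cl)),
                  row.names = FALSE)
        reports[[as.character(cl)]]$factors <- fa
      }
      logStage("correlation: class %d, N = %d, R^2 = %.3f", cl, n,
               rep$r_squared)
    }
  }

  invisible(list(tracks = tracks, motility = motility, edgePrints = prints,
                 classes = assign, reports = reports, outputDir = outputDir))
}

#' Generate the bundled demo dataset and its golden manifest
#'
#' Simulates a small movie, writes the movie, ground-truth tracks and config
#' echo into `dir`, and records MD5 hashes of the deterministic artifacts in
#' `manifest.json` for integration tests.
#'
#' @param seed integer seed (default 7).
#' @param dir output directory (default a temporary directory).
#' @param config optional [SimulationConfig-class]; the default is a compact
#'   four-cell, six-frame movie.
#' @return list with `dir`, `files` and the simulation output (`sim`).
#' @export
makeDemo <- function(seed = 7L, dir = tempfile("morphodyn_demo"),
                     config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config))
    config <- simConfig(nCells = 4L, imageShape = c(256L, 256L),
                        nFrames = 6L, seed = seed)
  sim <- simulateCellMovie(config)
  moviePath <- file.path(dir, "movie.tif")
  writeCellMovie(sim$movie, moviePath)
  gtPath <- file.path(dir, "ground_truth_tracks.csv")
  gt <- trackRecords(sim$tracks)
  names(gt)[names(gt) == "cell_id"] <- "track_id"
  write.csv(gt, gtPath, row.names = FALSE)
  cfgPath <- file.path(dir, "config.json")
  jsonlite::write_json(
    list(nFrames = config@nFrames, frameInterval = config@frameInterval,
         pixelSize = config@pixelSize, imageShape = config@imageShape,
         nCells = config@nCells, seed = config@seed),
    cfgPath, auto_unbox = TRUE, digits = NA)
  files <- c(movie = moviePath, tracks = gtPath, config = cfgPath)
  manifest <- as.list(tools::md5sum(files))
  names(manifest) <- names(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  list(dir = dir, files = files, sim = sim)
}
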