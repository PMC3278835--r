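#' @import methods
#' @importFrom stats approx coef complete.cases cor cov dist dnorm ecdf kmeans
#'   lm mahalanobis median nls pchisq pnorm pt qnorm quantile rbinom residuals
#'   rnorm runif sd setNames var varimax
#' @importFrom utils head read.csv tail write.csv
#' @importFrom tools md5sum
NULL

#' Configuration of a synthetic time-lapse movie
#'
#' A `SimulationConfig` collects every parameter of the synthetic movie
#' generator: imaging geometry (frame count, frame interval, pixel size, image
#' shape, bit depth), the persistent-random-walk motility parameters of the
#' simulated cells (speed, persistence), their shape model (base radius plus a
#' set of travelling sinusoidal boundary modes), and the intensity model
#' (foreground/background levels, additive Gaussian noise).
#'
#' Boundary modes are rows of `(frequency, amplitude_um, rate_per_h)`: angular
#' frequency (integer cycles around the boundary), amplitude in micrometres and
#' temporal phase rate in radians per hour. `protrusionBias` adds a uniform
#' signed radial drift in micrometres per frame interval, so positive values
#' make every cell dilate steadily.
#'
#' @slot nFrames integer, number of frames (>= 2).
#' @slot frameInterval numeric, minutes between frames.
#' @slot pixelSize numeric, micrometres per pixel side.
#' @slot imageShape integer(2), image rows and columns.
#' @slot nCells integer, number of simulated cells.
#' @slot speed numeric, root-mean-square cell speed in um/h (recycled per cell).
#' @slot persistence numeric, velocity correlation time in hours (recycled).
#' @slot baseRadius numeric, resting cell radius in um.
#' @slot boundaryModes numeric matrix with columns `freq`, `amplitude`, `rate`.
#' @slot protrusionBias numeric, signed uniform radial drift in um per interval.
#' @slot noiseSd numeric, additive intensity noise standard deviation.
#' @slot foreground,background numeric, cell and background intensity levels.
#' @slot bitDepth integer, intensity ceiling is `2^bitDepth - 1`.
#' @slot divisionFrame integer, frame at which cell 1 divides (NA = never).
#' @slot seed integer, random seed; identical config + seed gives
#'   bit-identical output.
#' @seealso [simConfig()], [simulateCellMovie()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nFrames = "integer",
    frameInterval = "numeric",
    pixelSize = "numeric",
    imageShape = "integer",
    nCells = "integer",
    speed = "numeric",
    persistence = "numeric",
    baseRadius = "numeric",
    boundaryModes = "matrix",
    protrusionBias = "numeric",
    noiseSd = "numeric",
    foreground = "numeric",
    background = "numeric",
    bitDepth = "integer",
    divisionFrame = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nFrames < 2L) msg <- c(msg, "nFrames must be >= 2")
  for (s in c("frameInterval", "pixelSize", "baseRadius"))
    if (any(slot(object, s) <= 0)) msg <- c(msg, paste(s, "must be > 0"))
  if (any(object@speed < 0)) msg <- c(msg, "speed must be >= 0")
  if (any(object@persistence <= 0)) msg <- c(msg, "persistence must be > 0")
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    msg <- c(msg, "imageShape must be two values >= 16")
  if (ncol(object@boundaryModes) != 3L)
    msg <- c(msg, "boundaryModes needs columns (freq, amplitude, rate)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  ceiling12 <- 2^object@bitDepth - 1
  if (object@foreground > ceiling12 || object@background < 0)
    msg <- c(msg, "intensities must lie within the bit-depth range")
  if (length(msg)) msg else TRUE
})

#' A time-lapse grayscale movie
#'
#' Ordered stack of 2-D intensity frames with the physical metadata needed
#' downstream: pixel size in micrometres and frame interval in minutes.
#' Frames are stored as a rows x cols x frames numeric array; intensities are
#' on the original (e.g. 12-bit) scale.
#'
#' @slot frames numeric array, rows x cols x nFrames.
#' @slot pixelSize numeric, um per pixel side.
#' @slot frameInterval numeric, minutes between frames.
#' @slot bitDepth integer.
#' @seealso [readCellMovie()], [writeCellMovie()], [simulateCellMovie()]
#' @exportClass CellMovie
setClass("CellMovie",
  representation(
    frames = "array",
    pixelSize = "numeric",
    frameInterval = "numeric",
    bitDepth = "integer"
  )
)

setValidity("CellMovie", function(object) {
  d <- dim(object@frames)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "frames must be a 3-D array")
  else {
    if (d[3] < 2L) msg <- c(msg, "a movie needs at least 2 frames")
    if (d[1] < 16L || d[2] < 16L) msg <- c(msg, "frames must be at least 16x16")
  }
  if (any(object@frames < 0)) msg <- c(msg, "intensities must be non-negative")
  if (object@pixelSize <= 0 || object@frameInterval <= 0)
    msg <- c(msg, "pixelSize and frameInterval must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-cell tracks across a movie
#'
#' A `TrackSet` holds one row per (cell, frame) in `records` -- centroid in
#' pixel coordinates ((row, col), 0-based, pixel centres at integers), area in
#' pixels and mean intensity -- together with the ordered boundary polygon of
#' each cell at each frame and the movie metadata required to convert to
#' physical units. A track is *complete* when it spans every frame; only
#' complete tracks enter motility and edge-dynamics analysis.
#'
#' @slot records data.frame with columns `cell_id`, `frame`, `centroid_row`,
#'   `centroid_col`, `area`, `mean_intensity`.
#' @slot boundaries named list (by cell id) of lists (by frame index) of
#'   two-column matrices `(row, col)`; `NULL` where no boundary is available.
#' @slot nFrames integer, frames in the movie.
#' @slot pixelSize numeric, um per pixel.
#' @slot frameInterval numeric, minutes per frame step.
#' @slot events data.frame of tracking events (frame, case, parent, children).
#' @exportClass TrackSet
setClass("TrackSet",
  representation(
    records = "data.frame",
    boundaries = "list",
    nFrames = "integer",
    pixelSize = "numeric",
    frameInterval = "numeric",
    events = "data.frame"
  )
)

setValidity("TrackSet", function(object) {
  req <- c("cell_id", "frame", "centroid_row", "centroid_col", "area",
           "mean_intensity")
  msg <- character()
  if (!all(req %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:", paste(req, collapse = ", ")))
  if (nrow(object@records)) {
    sp <- split(object@records$frame, object@records$cell_id)
    gap <- vapply(sp, function(f) any(diff(sort(f)) != 1L), logical(1))
    if (any(gap)) msg <- c(msg, "track frames must be contiguous (no gaps)")
    dup <- vapply(sp, anyDuplicated, integer(1))
    if (any(dup > 0)) msg <- c(msg, "duplicate (cell, frame) records")
  }
  if (length(msg)) msg else TRUE
})

#' Edge prints for a set of cells
#'
#' Protrusion and retraction velocities per frame interval for each cell:
#' the "edge print". For a movie with T frames each cell contributes
#' `T - 1` protrusion and `T - 1` retraction values (22 features when T = 12),
#' in micrometres per minute by default.
#'
#' @slot protrusion numeric matrix, cells x (T-1), p_t >= 0.
#' @slot retraction numeric matrix, cells x (T-1), r_t >= 0.
#' @slot tau numeric, sampling interval in minutes.
#' @slot normalized logical, TRUE when velocities are per marker and per
#'   minute; FALSE when raw per-interval marker displacement sums.
#' @exportClass EdgePrintSet
setClass("EdgePrintSet",
  representation(
    protrusion = "matrix",
    retraction = "matrix",
    tau = "numeric",
    normalized = "logical"
  )
)

setValidity("EdgePrintSet", function(object) {
  msg <- character()
  if (!identical(dim(object@protrusion), dim(object@retraction)))
    msg <- c(msg, "protrusion and retraction must have identical shape")
  if (any(object@protrusion < 0) || any(object@retraction < 0))
    msg <- c(msg, "protrusion/retraction velocities must be non-negative")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (length(msg)) msg else TRUE
})

#' K-component Gaussian mixture model
#'
#' Weights, mean vectors and full covariance matrices of a Gaussian mixture
#' fitted by expectation-maximization, with the achieved log-likelihood and
#' convergence diagnostics. `mdlScore()` attaches the minimum description
#' length used for model-order selection.
#'
#' @slot K integer, number of components.
#' @slot weights numeric(K), mixing proportions (sum to 1).
#' @slot means K x n matrix of component means.
#' @slot covariances list of K symmetric positive-definite n x n matrices.
#' @slot logLik numeric, maximized log-likelihood.
#' @slot converged logical.
#' @slot nObs,nFeatures integer, data dimensions used in the fit.
#' @slot iterations integer, EM iterations of the returned fit.
#' @exportClass MixtureModel
setClass("MixtureModel",
  representation(
    K = "integer",
    weights = "numeric",
    means = "matrix",
    covariances = "list",
    logLik = "numeric",
    converged = "logical",
    nObs = "integer",
    nFeatures = "integer",
    iterations = "integer"
  )
)

setValidity("MixtureModel", function(object) {
  msg <- character()
  if (length(object@weights) != object@K)
    msg <- c(msg, "need K weights")
  if (abs(sum(object@weights) - 1) > 1e-8 || any(object@weights <= 0))
    msg <- c(msg, "weights must be positive and sum to 1")
  if (nrow(object@means) != object@K)
    msg <- c(msg, "means must have K rows")
  if (length(object@covariances) != object@K)
    msg <- c(msg, "need K covariance matrices")
  if (!is.finite(object@logLik)) msg <- c(msg, "log-likelihood must be finite")
  if (length(msg)) msg else TRUE
})

## ---- generics -------------------------------------------------------------

#' @describeIn CellMovie-class number of frames
#' @param object a morphodyn object
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @export
#' @rdname CellMovie-class
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @export
#' @rdname CellMovie-class
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @describeIn CellMovie-class intensity matrix of frame `i`
#' @param i frame index
#' @export
setGeneric("getFrame", function(object, i) standardGeneric("getFrame"))
#' @describeIn TrackSet-class per-(cell, frame) record table
#' @export
setGeneric("trackRecords", function(object) standardGeneric("trackRecords"))
#' @describeIn TrackSet-class boundary polygon of one cell at one frame
#' @param cell cell id
#' @param frame frame index
#' @export
setGeneric("trackBoundary",
           function(object, cell, frame) standardGeneric("trackBoundary"))
#' @describeIn TrackSet-class ids of tracks spanning every frame
#' @export
setGeneric("completeTracks", function(object) standardGeneric("completeTracks"))
#' @describeIn EdgePrintSet-class protrusion velocity matrix
#' @export
setGeneric("protrusion", function(object) standardGeneric("protrusion"))
#' @describeIn EdgePrintSet-class retraction velocity matrix
#' @export
setGeneric("retraction", function(object) standardGeneric("retraction"))
#' @describeIn EdgePrintSet-class the 2(T-1)-column combined feature matrix
#' @export
setGeneric("edgeFeatureMatrix",
           function(object) standardGeneric("edgeFeatureMatrix"))

setMethod("nFrames", "CellMovie", function(object) dim(object@frames)[3])
setMethod("nFrames", "TrackSet", function(object) object@nFrames)
setMethod("nFrames", "SimulationConfig", function(object) object@nFrames)
setMethod("pixelSize", "CellMovie", function(object) object@pixelSize)
setMethod("pixelSize", "TrackSet", function(object) object@pixelSize)
setMethod("pixelSize", "SimulationConfig", function(object) object@pixelSize)
setMethod("frameInterval", "CellMovie", function(object) object@frameInterval)
setMethod("frameInterval", "TrackSet", function(object) object@frameInterval)
setMethod("frameInterval", "SimulationConfig",
          function(object) object@frameInterval)

setMethod("getFrame", "CellMovie", function(object, i) {
  stopifnot(i >= 1, i <= dim(object@frames)[3])
  object@frames[, , i]
})

setMethod("trackRecords", "TrackSet", function(object) object@records)

setMethod("trackBoundary", "TrackSet", function(object, cell, frame) {
  b <- object@boundaries[[as.character(cell)]]
  if (is.null(b) || frame > length(b)) NULL else b[[frame]]
})

setMethod("completeTracks", "TrackSet", function(object) {
  n <- table(object@records$cell_id)
  names(n)[n == object@nFrames]
})

setMethod("protrusion", "EdgePrintSet", function(object) object@protrusion)
setMethod("retraction", "EdgePrintSet", function(object) object@retraction)
setMethod("edgeFeatureMatrix", "EdgePrintSet", function(object) {
  cbind(object@protrusion, object@retraction)
})

setMethod("show", "CellMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "CellMovie: %d frames of %dx%d px (%.3f um/px, %g min/frame, %d-bit)\n",
    d[3], d[1], d[2], object@pixelSize, object@frameInterval, object@bitDepth))
})

setMethod("show", "TrackSet", function(object) {
  ids <- unique(object@records$cell_id)
  cat(sprintf("TrackSet: %d tracks over %d frames (%d complete)\n",
              length(ids), object@nFrames, length(completeTracks(object))))
  if (nrow(object@events))
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s@f%d", object@events$case, object@events$frame),
                      collapse = ", ")))
})

setMethod("show", "EdgePrintSet", function(object) {
  cat(sprintf(
    "EdgePrintSet: %d cells x %d intervals (tau = %g min, %s)\n",
    nrow(object@protrusion), ncol(object@protrusion), object@tau,
    if (object@normalized) "um/min per marker" else "summed um per interval"))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf(
    "MixtureModel: K = %d on %d x %d data; logLik = %.3f (%s, %d EM iterations)\n",
    object@K, object@nObs, object@nFeatures, object@logLik,
    if (object@converged) "converged" else "NOT converged", object@iterations))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d cells, %d frames @ %g min, %dx%d px (%.3f um/px)\n",
    object@nCells, object@nFrames, object@frameInterval,
    object@imageShape[1], object@imageShape[2], object@pixelSize))
  cat(sprintf("  speed %s um/h, persistence %s h, radius %g um, %d boundary modes\n",
              paste(unique(object@speed), collapse = "/"),
              paste(unique(object@persistence), collapse = "/"),
              object@baseRadius, nrow(object@boundaryModes)))
})
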