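#' Read a multi-page TIFF as a CellMovie
#'
#' Frames are read from a multi-page grayscale TIFF (16-bit container holding
#' the 12-bit range) and rescaled back to integer intensity units.
#'
#' @param path TIFF file path.
#' @param pixelSize micrometres per pixel side.
#' @param frameInterval minutes between frames.
#' @param bitDepth nominal bit depth of the stored intensities (default 12).
#' @return a [CellMovie-class].
#' @export
readCellMovie <- function(path, pixelSize = 0.707, frameInterval = 10,
                          bitDepth = 12L) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path))
  if (!length(pages)) stop("empty TIFF: ", path)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    arr[, , i] <- p * 65535
  }
  new("CellMovie", frames = arr, pixelSize = pixelSize,
      frameInterval = frameInterval, bitDepth = as.integer(bitDepth))
}

#' Write a CellMovie as a multi-page 16-bit TIFF
#'
#' @param movie a [CellMovie-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCellMovie <- function(movie, path) {
  stopifnot(is(movie, "CellMovie"))
  # intensities are stored as rounded 16-bit levels (the writer truncates,
  # so pre-rounding keeps the round trip exact on integer data)
  pages <- lapply(seq_len(nFrames(movie)), function(f)
    pmin(pmax(round(getFrame(movie, f)), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write label masks as a multi-page 16-bit TIFF
#' @param labels integer array rows x cols x frames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLabelMasks <- function(labels, path) {
  pages <- lapply(seq_len(dim(labels)[3]), function(f)
    labels[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write tracks to CSV
#'
#' One row per (cell, frame): `track_id`, `frame`, `centroid_row`,
#' `centroid_col`, `area`, `mean_intensity`. Boundaries are not serialized.
#'
#' @param tracks a [TrackSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTracksCSV <- function(tracks, path) {
  rec <- trackRecords(tracks)
  names(rec)[names(rec) == "cell_id"] <- "track_id"
  # full 17-digit precision so a re-read run reproduces downstream fits
  # bit-for-bit (nonlinear fits can amplify last-digit differences)
  for (cn in names(rec))
    if (is.double(rec[[cn]]))
      rec[[cn]] <- formatC(rec[[cn]], digits = 17, format = "g")
  write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' Inverse of [writeTracksCSV()] (boundaries are absent, so edge analysis is
#' unavailable on re-read tracks; motility analysis is unaffected).
#'
#' @param path CSV path.
#' @param pixelSize,frameInterval physical metadata of the source movie.
#' @return a [TrackSet-class] without boundaries.
#' @export
readTracksCSV <- function(path, pixelSize = 0.707, frameInterval = 10) {
  rec <- read.csv(path)
  names(rec)[names(rec) == "track_id"] <- "cell_id"
  rec$cell_id <- as.character(rec$cell_id)
  new("TrackSet", records = rec, boundaries = list(),
      nFrames = as.integer(max(rec$frame)), pixelSize = pixelSize,
      frameInterval = frameInterval,
      events = data.frame(frame = integer(0), case = character(0),
                          parent = character(0), children = character(0)))
}

#' Write an edge-print set to CSV
#'
#' Columns `cell_id`, `p_1..p_{T-1}`, `r_1..r_{T-1}`.
#' @param prints an [EdgePrintSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEdgePrintsCSV <- function(prints, path) {
  df <- data.frame(cell_id = rownames(protrusion(prints)),
                   protrusion(prints), retraction(prints), row.names = NULL,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
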