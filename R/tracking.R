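## default spatiotemporal matching weights: position dominates at 10-min
## sampling; size and intensity refine ties
defaultMatchWeights <- function() c(pos = 0.5, size = 0.25, int = 0.25)

#' Match cell regions between two consecutive frames
#'
#' Builds the pairwise matching cost
#' \deqn{c(a, b) = w_{pos} \frac{\|x_a - x_b\|}{g} +
#'   w_{size} \frac{|A_a - A_b|}{\max A} +
#'   w_{int} \frac{|I_a - I_b|}{\max I}}
#' over centroid distance, area and mean intensity, excludes pairs whose
#' centroid distance exceeds the gate `g`, and solves the minimum-total-cost
#' one-to-one assignment. Regions with no admissible counterpart are flagged
#' LOST (frame t) or NEW (frame t+1). In addition to the optimal assignment,
#' every admissible pair whose cost is within `ratio` times its row's
#' assigned cost is returned as a candidate, so that one-to-many links
#' (division / over-segmentation) can be resolved downstream with the
#' three-frame heuristic of [resolveAmbiguities()].
#'
#' @param regionsT,regionsT1 region tables (data.frames with `label`,
#'   `centroid_row`, `centroid_col`, `area`, `mean_intensity`) for frames t
#'   and t+1, e.g. from [extractRegions()].
#' @param weights numeric(3) `(w_pos, w_size, w_int)`, non-negative, sum 1.
#' @param gate maximum centroid displacement in pixels (default 50).
#' @param ratio extra candidates are kept when within this factor of the
#'   assigned cost (default 1.5).
#' @return list with `matches` (data.frame `from`, `to`, `cost`; row indices
#'   into the two tables), `lost` (indices in t), `new` (indices in t+1) and
#'   `candidates` (admissible near-optimal extra pairs).
#' @export
matchFrames <- function(regionsT, regionsT1, weights = defaultMatchWeights(),
                        gate = 50, ratio = 1.5) {
  stopifnot(length(weights) == 3, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8, gate > 0)
  nA <- nrow(regionsT); nB <- nrow(regionsT1)
  empty <- list(matches = data.frame(from = integer(0), to = integer(0),
                                     cost = numeric(0)),
                lost = seq_len(nA), new = seq_len(nB),
                candidates = data.frame(from = integer(0), to = integer(0),
                                        cost = numeric(0)))
  if (nA == 0L || nB == 0L) return(empty)
  D <- sqrt(outer(regionsT$centroid_row, regionsT1$centroid_row, "-")^2 +
            outer(regionsT$centroid_col, regionsT1$centroid_col, "-")^2)
  maxA <- max(regionsT$area, regionsT1$area)
  maxI <- max(regionsT$mean_intensity, regionsT1$mean_intensity)
  C <- weights[1] * D / gate +
    weights[2] * abs(outer(regionsT$area, regionsT1$area, "-")) / maxA +
    weights[3] * abs(outer(regionsT$mean_intensity,
                           regionsT1$mean_intensity, "-")) / maxI
  admissible <- D <= gate
  BIG <- 1e6
  Cpad <- matrix(BIG, max(nA, nB), max(nA, nB))
  Cpad[seq_len(nA), seq_len(nB)] <- ifelse(admissible, C, BIG)
  sol <- as.integer(clue::solve_LSAP(Cpad))
  from <- to <- integer(0); cost <- numeric(0)
  for (a in seq_len(nA)) {
    b <- sol[a]
    if (b <= nB && admissible[a, b]) {
      from <- c(from, a); to <- c(to, b); cost <- c(cost, C[a, b])
    }
  }
  matches <- data.frame(from = from, to = to, cost = cost)
  lost <- setdiff(seq_len(nA), matches$from)
  newb <- setdiff(seq_len(nB), matches$to)
  cand <- data.frame(from = integer(0), to = integer(0), cost = numeric(0))
  for (k in seq_len(nrow(matches))) {
    a <- matches$from[k]
    thr <- max(ratio * matches$cost[k], 1e-6)
    extra <- which(admissible[a, ] & C[a, ] <= thr)
    extra <- setdiff(extra, matches$to[k])
    if (length(extra))
      cand <- rbind(cand, data.frame(from = a, to = extra, cost = C[a, extra]))
  }
  # unassigned frame-t regions keep all admissible pairs as candidates so a
  # two-to-one contest (over-segmentation in frame t) remains detectable
  for (a in lost) {
    extra <- which(admissible[a, ])
    if (length(extra))
      cand <- rbind(cand, data.frame(from = a, to = extra, cost = C[a, extra]))
  }
  list(matches = matches, lost = lost, new = newb, candidates = cand)
}

#' Resolve one-to-many links with the three-frame heuristic
#'
#' Four cases arise in frame-to-frame matching: a clean MATCH, a LOST cell
#' (no counterpart), a possible DIVISION (one region in frame t matches two in
#' frame t+1) and possible over-segmentation (OVERSEG). A one-to-two link is
#' only accepted as a division when both frame-t+1 children have their own
#' matches into frame t+2; otherwise the children are declared an
#' over-segmentation of one cell and are merged back for the middle frame.
#' Symmetrically, two regions of frame t competing for one region of frame
#' t+1 are labelled OVERSEG in frame t. When no third frame is available
#' (ambiguity at the final transition) the conservative default is a plain
#' MATCH to the cheaper counterpart, and the decision is logged.
#'
#' @param m12 output of [matchFrames()] for frames t and t+1.
#' @param m23 output of [matchFrames()] for frames t+1 and t+2, or `NULL`
#'   when frame t+2 does not exist.
#' @param ratio a two-to-one contest is only accepted when the competing
#'   region's cost is within this factor of the assigned cost (default 1.5).
#' @return data.frame with columns `case` (`"DIVISION"` or `"OVERSEG"`),
#'   `parent` (region index in the earlier of the two frames involved),
#'   `a`, `b` (the two sibling region indices) and `frame_offset` (0 when the
#'   siblings live in frame t, 1 when in frame t+1).
#' @export
resolveAmbiguities <- function(m12, m23 = NULL, ratio = 1.5) {
  out <- data.frame(case = character(0), parent = integer(0),
                    a = integer(0), b = integer(0), frame_offset = integer(0))
  # one-to-two: assigned child plus an unmatched near-cost candidate in t+1
  for (k in seq_len(nrow(m12$matches))) {
    a <- m12$matches$from[k]; b1 <- m12$matches$to[k]
    cc <- m12$candidates[m12$candidates$from == a &
                         m12$candidates$to %in% m12$new, , drop = FALSE]
    if (!nrow(cc)) next
    b2 <- cc$to[which.min(cc$cost)]
    if (is.null(m23)) {
      message("resolveAmbiguities: ambiguity at final frame for region ", a,
              "; defaulting to MATCH with nearest counterpart")
      next
    }
    both <- all(c(b1, b2) %in% m23$matches$from)
    out <- rbind(out, data.frame(
      case = if (both) "DIVISION" else "OVERSEG",
      parent = a, a = b1, b = b2, frame_offset = 1L))
  }
  # two-to-one: an unmatched frame-t region competing for an assigned target
  if (length(m12$lost) && nrow(m12$matches)) {
    for (a2 in m12$lost) {
      # a2 had no assignment; does it closely contest someone's target?
      hit <- m12$candidates[m12$candidates$from == a2, , drop = FALSE]
      hit <- hit[hit$to %in% m12$matches$to, , drop = FALSE]
      if (nrow(hit)) {
        b <- hit$to[which.min(hit$cost)]
        assigned <- m12$matches$cost[m12$matches$to == b]
        if (min(hit$cost) > ratio * max(assigned, 1e-6)) next
        a1 <- m12$matches$from[m12$matches$to == b]
        out <- rbind(out, data.frame(case = "OVERSEG", parent = b,
                                     a = a1, b = a2, frame_offset = 0L))
      }
    }
  }
  out
}

## merge two regions (and their masks/boundaries if available)
mergeRegions <- function(tab, i, j, labelMask = NULL) {
  w <- tab$area[c(i, j)]
  merged <- tab[i, ]
  merged$centroid_row <- sum(tab$centroid_row[c(i, j)] * w) / sum(w)
  merged$centroid_col <- sum(tab$centroid_col[c(i, j)] * w) / sum(w)
  merged$mean_intensity <- sum(tab$mean_intensity[c(i, j)] * w) / sum(w)
  merged$area <- sum(w)
  merged
}

#' Build cell tracks across all frames
#'
#' Chains [matchFrames()] assignments into tracks, applying the three-frame
#' division / over-segmentation heuristic of [resolveAmbiguities()] at every
#' transition. A division closes the parent track and opens two child tracks;
#' an over-segmentation in the middle frame merges the two fragments back
#' into one region (recomputed from the label masks when provided, otherwise
#' by area-weighted pooling). With `completeOnly = TRUE` (the default
#' downstream convention) only tracks spanning every frame are returned, so
#' divided lineages and cells that leave the field are excluded.
#'
#' @param regionsPerFrame list (one element per frame) of [extractRegions()]
#'   results, or of plain region tables.
#' @param weights,gate,ratio passed to [matchFrames()].
#' @param completeOnly keep only tracks spanning all frames (default FALSE;
#'   the filter is also available through [completeTracks()]).
#' @param labelMasks optional rows x cols x frames label array used to
#'   re-extract merged regions and their boundaries exactly.
#' @param frames optional intensity array matching `labelMasks`.
#' @param pixelSize,frameInterval physical metadata stored in the result.
#' @return a [TrackSet-class]; tracking events (DIVISION/OVERSEG) are in its
#'   `events` slot.
#' @export
buildTracks <- function(regionsPerFrame, weights = defaultMatchWeights(),
                        gate = 50, ratio = 1.5, completeOnly = FALSE,
                        labelMasks = NULL, frames = NULL,
                        pixelSize = 1, frameInterval = 10) {
  nF <- length(regionsPerFrame)
  stopifnot(nF >= 2L)
  tabs <- lapply(regionsPerFrame, function(r) if (is.data.frame(r)) r else r$table)
  bnds <- lapply(regionsPerFrame, function(r) if (is.data.frame(r)) NULL else r$boundaries)

  # pairwise matches, then ambiguity resolution with the following transition
  M <- vector("list", nF - 1L)
  for (f in seq_len(nF - 1L))
    M[[f]] <- matchFrames(tabs[[f]], tabs[[f + 1L]], weights, gate, ratio)

  events <- data.frame(frame = integer(0), case = character(0),
                       parent = character(0), children = character(0))
  divisions <- vector("list", nF - 1L)
  for (f in seq_len(nF - 1L)) {
    res <- resolveAmbiguities(M[[f]], if (f + 1L < nF) M[[f + 1L]] else NULL)
    if (!nrow(res)) next
    for (k in seq_len(nrow(res))) {
      if (res$case[k] == "OVERSEG") {
        if (res$frame_offset[k] == 1L) {
          # merge fragments a, b of frame f+1 and rematch that transition
          g <- f + 1L
          ij <- c(res$a[k], res$b[k])
          if (!is.null(labelMasks)) {
            lm <- labelMasks[, , g]
            l1 <- tabs[[g]]$label[ij[1]]; l2 <- tabs[[g]]$label[ij[2]]
            lm[lm == l2] <- l1
            labelMasks[, , g] <- lm
            img <- if (!is.null(frames)) frames[, , g] else (lm > 0) * 1
            reg <- extractRegions(lm, img, minArea = 0L)
            tabs[[g]] <- reg$table
            bnds[[g]] <- reg$boundaries
          } else {
            keep <- setdiff(seq_len(nrow(tabs[[g]])), ij)
            mrg <- mergeRegions(tabs[[g]], ij[1], ij[2])
            if (!is.null(bnds[[g]])) {
              big <- ij[which.max(tabs[[g]]$area[ij])]
              bnds[[g]] <- c(bnds[[g]][as.character(tabs[[g]]$label[keep])],
                             setNames(bnds[[g]][as.character(tabs[[g]]$label[big])],
                                      as.character(mrg$label)))
            }
            tabs[[g]] <- rbind(tabs[[g]][keep, ], mrg)
          }
          M[[f]] <- matchFrames(tabs[[f]], tabs[[g]], weights, gate, ratio)
          if (g <= nF - 1L)
            M[[g]] <- matchFrames(tabs[[g]], tabs[[g + 1L]], weights, gate, ratio)
          events <- rbind(events, data.frame(
            frame = g, case = "OVERSEG",
            parent = as.character(res$parent[k]),
            children = paste(ij, collapse = "+")))
        } else {
          events <- rbind(events, data.frame(
            frame = f, case = "OVERSEG",
            parent = as.character(res$parent[k]),
            children = paste(c(res$a[k], res$b[k]), collapse = "+")))
        }
      } else { # DIVISION
        divisions[[f]] <- rbind(divisions[[f]],
                                data.frame(parent = res$parent[k],
                                           a = res$a[k], b = res$b[k]))
        events <- rbind(events, data.frame(
          frame = f + 1L, case = "DIVISION", parent = as.character(res$parent[k]),
          children = paste(c(res$a[k], res$b[k]), collapse = "+")))
      }
    }
  }

  # chain assignments into tracks
  nextId <- 1L
  active <- list()   # cell id -> region index in current frame
  recs <- list(); boundaries <- list()
  addRecord <- function(id, f, idx) {
    tb <- tabs[[f]][idx, ]
    recs[[length(recs) + 1L]] <<- data.frame(
      cell_id = id, frame = f,
      centroid_row = tb$centroid_row, centroid_col = tb$centroid_col,
      area = tb$area, mean_intensity = tb$mean_intensity)
    if (!is.null(bnds[[f]])) {
      if (is.null(boundaries[[id]])) boundaries[[id]] <<- vector("list", nF)
      boundaries[[id]][[f]] <<- bnds[[f]][[as.character(tb$label)]]
    }
  }
  for (idx in seq_len(nrow(tabs[[1L]]))) {
    id <- as.character(nextId); nextId <- nextId + 1L
    active[[id]] <- idx
    addRecord(id, 1L, idx)
  }
  for (f in seq_len(nF - 1L)) {
    m <- M[[f]]
    div <- divisions[[f]]
    nextActive <- list()
    claimed <- integer(0)
    for (id in names(active)) {
      a <- active[[id]]
      dv <- if (!is.null(div)) div[div$parent == a, , drop = FALSE] else NULL
      if (!is.null(dv) && nrow(dv)) {
        for (childIdx in c(dv$a[1], dv$b[1])) {
          cid <- as.character(nextId); nextId <- nextId + 1L
          nextActive[[cid]] <- childIdx
          addRecord(cid, f + 1L, childIdx)
          claimed <- c(claimed, childIdx)
        }
        next   # parent track closes
      }
      b <- m$matches$to[m$matches$from == a]
      if (length(b) == 1L && !(b %in% claimed)) {
        nextActive[[id]] <- b
        addRecord(id, f + 1L, b)
        claimed <- c(claimed, b)
      }                                   # else LOST: track ends
    }
    for (b in setdiff(seq_len(nrow(tabs[[f + 1L]])), claimed)) {
      id <- as.character(nextId); nextId <- nextId + 1L
      nextActive[[id]] <- b
      addRecord(id, f + 1L, b)
    }
    active <- nextActive
  }

  records <- do.call(rbind, recs)
  records <- records[order(as.integer(records$cell_id), records$frame), ]
  rownames(records) <- NULL
  if (completeOnly) {
    full <- names(which(table(records$cell_id) == nF))
    records <- records[records$cell_id %in% full, ]
    boundaries <- boundaries[names(boundaries) %in% full]
  }
  new("TrackSet", records = records, boundaries = boundaries,
      nFrames = as.integer(nF), pixelSize = pixelSize,
      frameInterval = frameInterval, events = events)
}
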