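# Time-lapse focus tracking: scale-normalized Laplacian-of-Gaussian spot
# detection, nearest-assignment linking with gap closing, trajectory
# filters, lifespans, dissolution intensities and inheritance ratios.

#' Laplacian-of-Gaussian spot detection
#'
#' Detects bright blobs as strict local maxima of the scale-normalized
#' (negative) Laplacian-of-Gaussian response at the scale matched to the
#' requested blob diameter, sd = diameter / (2 * sqrt(2)).  The response
#' amplitude at each maximum is reported as the spot quality; maxima below
#' \code{qualityThreshold} are discarded.
#'
#' @param image numeric matrix (single frame).
#' @param blobDiameter expected blob diameter in um.
#' @param qualityThreshold minimum LoG response amplitude.
#' @param pixelSize um per pixel.
#' @return data.frame with \code{row_px}, \code{col_px} (refined by an
#'   intensity-weighted 3x3 centroid of the response), \code{quality}.
#' @export
logDetect <- function(image, blobDiameter = 0.6, qualityThreshold = 0,
                      pixelSize = 0.066) {
  sigma <- blobDiameter / pixelSize / (2 * sqrt(2))
  if (blobDiameter <= 2 * pixelSize)
    stop("blobDiameter must exceed two pixels")
  resp <- .convolve2(image, .logKernel(sigma))
  mx <- .localMaxima(resp)
  if (nrow(mx) == 0L)
    return(data.frame(row_px = numeric(), col_px = numeric(),
                      quality = numeric()))
  q <- resp[mx]
  keep <- q >= qualityThreshold
  mx <- mx[keep, , drop = FALSE]; q <- q[keep]
  # sub-pixel refinement: response-weighted centroid over the 3x3 patch
  ref <- t(vapply(seq_len(nrow(mx)), function(i) {
    r <- mx[i, 1]; c <- mx[i, 2]
    patch <- resp[(r - 1):(r + 1), (c - 1):(c + 1)]
    patch <- pmax(patch, 0)
    w <- sum(patch)
    if (w == 0) return(c(r, c))
    rows <- matrix((r - 1):(r + 1), 3, 3)
    cols <- matrix((c - 1):(c + 1), 3, 3, byrow = TRUE)
    c(sum(rows * patch) / w, sum(cols * patch) / w)
  }, numeric(2)))
  out <- data.frame(row_px = ref[, 1], col_px = ref[, 2], quality = q)
  out[order(-out$quality), , drop = FALSE]
}

#' Link per-frame spots into tracks with gap closing
#'
#' Frame-to-frame spots are matched by minimum total squared displacement
#' subject to a maximum linking distance; track ends and later track starts
#' are then joined when they fall within the gap-closing distance and the
#' maximum frame gap.
#'
#' @param spots data.frame with \code{frame}, \code{row_px}, \code{col_px}
#'   (additional columns are carried along).
#' @param maxLink maximum frame-to-frame linking distance in px.
#' @param maxGapDist maximum gap-closing distance in px.
#' @param maxGap maximum number of missing frames bridged by gap closing.
#' @return the spots data.frame with a \code{track_id} column, ordered by
#'   track and frame.
#' @export
linkSpots <- function(spots, maxLink = 3, maxGapDist = 3, maxGap = 2) {
  if (nrow(spots) == 0L) {
    spots$track_id <- integer(0)
    return(spots)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  spots$track_id <- NA_integer_
  nextTrack <- 1L
  prevIdx <- which(spots$frame == frames[1])
  spots$track_id[prevIdx] <- seq_len(length(prevIdx))
  nextTrack <- length(prevIdx) + 1L
  for (fi in seq_along(frames)[-1]) {
    curIdx <- which(spots$frame == frames[fi])
    contiguous <- frames[fi] == frames[fi - 1] + 1
    if (length(prevIdx) && length(curIdx) && contiguous) {
      a <- cbind(spots$row_px[prevIdx], spots$col_px[prevIdx])
      b <- cbind(spots$row_px[curIdx], spots$col_px[curIdx])
      m <- .gatedMatch(a, b, maxLink)
      for (i in seq_along(prevIdx)) {
        if (!is.na(m[i]))
          spots$track_id[curIdx[m[i]]] <- spots$track_id[prevIdx[i]]
      }
    }
    new <- curIdx[is.na(spots$track_id[curIdx])]
    if (length(new)) {
      spots$track_id[new] <- seq.int(nextTrack, length.out = length(new))
      nextTrack <- nextTrack + length(new)
    }
    prevIdx <- curIdx
  }
  spots <- .closeGaps(spots, maxGapDist, maxGap)
  spots[order(spots$track_id, spots$frame), , drop = FALSE]
}

# Join track segments across detection gaps: an end at frame f may connect
# to a start at frame f + g + 1 for 1 <= g <= maxGap if within maxGapDist.
# Candidates are merged greedily by (frame gap, distance, track ids), which
# is deterministic.
.closeGaps <- function(spots, maxGapDist, maxGap) {
  if (maxGap < 1) return(spots)
  repeat {
    ids <- unique(spots$track_id)
    ends <- do.call(rbind, lapply(ids, function(id) {
      s <- spots[spots$track_id == id, ]
      s[which.max(s$frame), c("track_id", "frame", "row_px", "col_px")]
    }))
    starts <- do.call(rbind, lapply(ids, function(id) {
      s <- spots[spots$track_id == id, ]
      s[which.min(s$frame), c("track_id", "frame", "row_px", "col_px")]
    }))
    cand <- NULL
    for (i in seq_len(nrow(ends))) for (j in seq_len(nrow(starts))) {
      if (ends$track_id[i] == starts$track_id[j]) next
      gap <- starts$frame[j] - ends$frame[i] - 1
      if (gap < 1 || gap > maxGap) next
      d <- sqrt((ends$row_px[i] - starts$row_px[j])^2 +
                (ends$col_px[i] - starts$col_px[j])^2)
      if (d > maxGapDist) next
      cand <- rbind(cand, data.frame(endId = ends$track_id[i],
                                     startId = starts$track_id[j],
                                     gap = gap, d = d))
    }
    if (is.null(cand) || nrow(cand) == 0L) break
    cand <- cand[order(cand$gap, cand$d, cand$endId, cand$startId), ]
    merged <- FALSE
    usedEnd <- usedStart <- integer()
    for (k in seq_len(nrow(cand))) {
      if (cand$endId[k] %in% usedEnd || cand$startId[k] %in% usedStart ||
          cand$endId[k] %in% usedStart || cand$startId[k] %in% usedEnd) next
      spots$track_id[spots$track_id == cand$startId[k]] <- cand$endId[k]
      usedEnd <- c(usedEnd, cand$endId[k])
      usedStart <- c(usedStart, cand$startId[k])
      merged <- TRUE
    }
    if (!merged) break
  }
  # renumber tracks consecutively in order of first appearance
  ord <- unique(spots$track_id[order(spots$frame, spots$track_id)])
  spots$track_id <- match(spots$track_id, ord)
  spots
}

#' Apply the four focus-trajectory filters
#'
#' Filters, in order: (i) keep only trajectories present in the first
#' frame; (ii) drop trajectories of foci in cells that leave the field of
#' view; (iii) drop presumed false-positive first-frame detections
#' (trajectories shorter than \code{minLength} detections); (iv) drop
#' trajectories in cells that did not grow or divide, as required by the
#' dilution mode under analysis.
#'
#' @param tracks data.frame from \code{\link{linkSpots}} (needs
#'   \code{track_id}, \code{frame}, optionally \code{cell_id}).
#' @param lineage optional data.frame with \code{cell_id},
#'   \code{out_of_view} (logical) and \code{grew_or_divided} (logical).
#' @param minLength minimum detections for a first-frame trajectory to be
#'   considered real.
#' @return filtered tracks; the removal reason per dropped track is in
#'   attribute \code{"removed"}.
#' @export
applyTrackFilters <- function(tracks, lineage = NULL, minLength = 2) {
  removed <- data.frame(track_id = integer(), reason = character())
  firstFrame <- min(tracks$frame)
  info <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(s) {
    data.frame(track_id = s$track_id[1], start = min(s$frame),
               n = nrow(s),
               cell_id = if ("cell_id" %in% names(s)) s$cell_id[1]
                         else NA_integer_)
  }))
  drop <- function(ids, reason) {
    if (length(ids))
      removed <<- rbind(removed,
                        data.frame(track_id = ids, reason = reason))
  }
  # (i) present in the first frame
  bad <- info$track_id[info$start > firstFrame]
  drop(bad, "not_in_first_frame")
  # (iii) false positives in the first frame
  bad3 <- info$track_id[info$start == firstFrame & info$n < minLength]
  drop(bad3, "first_frame_false_positive")
  if (!is.null(lineage)) {
    li <- lineage[match(info$cell_id, lineage$cell_id), ]
    # (ii) cells moving out of the field of view
    bad2 <- info$track_id[!is.na(li$out_of_view) & li$out_of_view]
    drop(bad2, "cell_out_of_view")
    # (iv) cells that did not grow or divide
    bad4 <- info$track_id[!is.na(li$grew_or_divided) & !li$grew_or_divided]
    drop(bad4, "cell_did_not_grow_or_divide")
  } else if ("cell_id" %in% names(tracks)) {
    warning("no lineage metadata: filters (ii) and (iv) skipped")
  }
  out <- tracks[!tracks$track_id %in% removed$track_id, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Focus lifespans and dissolution statistics
#'
#' Lifespan is the time between a track's first and last detection.  A
#' focus is dissolved when its track ends before the analysis horizon;
#' persisting (censored) foci are excluded from the mean lifespan but count
#' in the percent-dissolved denominator.
#'
#' @param tracks filtered tracks data.frame (\code{track_id}, \code{frame}).
#' @param frameInterval time between frames, in hours.
#' @param horizonFrame last frame of the analysis window; defaults to the
#'   maximum frame present.
#' @return list with \code{per_track} (track_id, lifespan_h, dissolved),
#'   \code{percent_dissolved}, \code{mean_lifespan_h}, \code{sd_lifespan_h}
#'   (dissolved foci only).
#' @export
focusLifespans <- function(tracks, frameInterval, horizonFrame = NULL) {
  if (nrow(tracks) == 0L) stop("no tracks to analyze")
  if (is.null(horizonFrame)) horizonFrame <- max(tracks$frame)
  per <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(s) {
    data.frame(track_id = s$track_id[1],
               lifespan_h = (max(s$frame) - min(s$frame)) * frameInterval,
               dissolved = max(s$frame) < horizonFrame)
  }))
  rownames(per) <- NULL
  dis <- per$lifespan_h[per$dissolved]
  list(per_track = per,
       percent_dissolved = 100 * mean(per$dissolved),
       mean_lifespan_h = if (length(dis)) mean(dis) else NA_real_,
       sd_lifespan_h = if (length(dis) > 1) stats::sd(dis) else NA_real_)
}

#' Cell intensity around a focus dissolution event
#'
#' Mean background-corrected intensity of the cell at the frames
#' immediately before and immediately after the focus disappears.
#'
#' @param movie numeric array (rows x cols x frames).
#' @param masks integer label array matching \code{movie}.
#' @param cellId label of the cell of interest.
#' @param eventFrame first frame at which the focus is absent.
#' @return named numeric vector \code{c(pre = ..., post = ...)}.
#' @export
dissolutionIntensity <- function(movie, masks, cellId, eventFrame) {
  nT <- dim(movie)[3]
  if (eventFrame <= 1 || eventFrame > nT)
    stop("event frame must be interior to the movie")
  grab <- function(t) {
    img <- movie[, , t]; msk <- masks[, , t]
    if (!any(msk == cellId)) stop("cell ", cellId, " missing at frame ", t)
    corr <- backgroundCorrect(img, msk)
    mean(corr[msk == cellId])
  }
  c(pre = grab(eventFrame - 1), post = grab(eventFrame))
}

#' Daughter-cell fluorescence inheritance at division
#'
#' Integrated background-corrected fluorescence of each daughter cell,
#' normalized to that of the mother in the preceding frame.
#'
#' @param motherImage,motherMask frame and label mask before division.
#' @param daughterImage,daughterMask frame and label mask after division.
#' @param motherId mother cell label.
#' @param daughterIds labels of the two daughter cells.
#' @param focusDaughter optional label of the daughter that re-formed a
#'   focus (NA when none did).
#' @return list with \code{mother_total}, \code{daughter_totals},
#'   \code{fractions} and \code{focus_daughter}.
#' @export
inheritanceRatio <- function(motherImage, motherMask, daughterImage,
                             daughterMask, motherId, daughterIds,
                             focusDaughter = NA) {
  if (length(daughterIds) != 2L) stop("exactly two daughters required")
  mcorr <- backgroundCorrect(motherImage, motherMask)
  dcorr <- backgroundCorrect(daughterImage, daughterMask)
  motherTotal <- sum(mcorr[motherMask == motherId])
  if (motherTotal <= 0) stop("mother total intensity must be positive")
  dTotals <- vapply(daughterIds,
                    function(id) sum(dcorr[daughterMask == id]), numeric(1))
  list(mother_total = motherTotal,
       daughter_totals = stats::setNames(dTotals, daughterIds),
       fractions = stats::setNames(dTotals / motherTotal, daughterIds),
       focus_daughter = focusDaughter)
}
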