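# Per-cell condensation statistics, focus detection, partition ratios,
# population focus fractions, and FRAP curve normalization.

#' Condensation coefficient of a cell
#'
#' The fraction of a cell's min-max normalized pixels strictly below an
#' intensity threshold.  A spatially homogeneous signal gives about 50 (on
#' the percent scale, threshold 0.5); a strongly punctate signal pushes most
#' pixels toward the dim end and the coefficient toward 100.
#'
#' @param normPixels result of \code{\link{minmaxNormalize}} on one cell's
#'   (background-corrected, blurred) pixels, or a numeric vector of
#'   normalized values.
#' @param threshold normalized intensity threshold, conventionally 0.3, 0.5
#'   or 0.7.
#' @param percent logical; report the fraction times 100.
#' @return numeric scalar, or NA for a degenerate (constant-intensity) cell.
#' @examples
#' condensationCoefficient(c(rep(0, 5), rep(1, 5)), 0.5)  # 50
#' @export
condensationCoefficient <- function(normPixels, threshold = 0.5,
                                    percent = TRUE) {
  if (is.list(normPixels)) {
    if (isTRUE(normPixels$degenerate)) return(NA_real_)
    v <- as.numeric(normPixels$values)
  } else v <- as.numeric(normPixels)
  frac <- mean(v < threshold)
  if (percent) 100 * frac else frac
}

#' Normalize condensation coefficients to a reference population
#'
#' Divides each coefficient by the mean coefficient of a reference
#' population (cells expressing the fluorophore alone, i.e. a homogeneous
#' distribution), so the reference maps to mean 1.
#'
#' @param values numeric vector of raw coefficients.
#' @param reference numeric vector of reference-population coefficients.
#' @return numeric vector of normalized coefficients.
#' @export
normalizeToReference <- function(values, reference) {
  reference <- reference[!is.na(reference)]
  if (length(reference) == 0L) stop("reference population is empty")
  m <- mean(reference)
  if (m == 0) stop("reference mean is zero")
  values / m
}

#' Detect fluorescent foci within one cell
#'
#' The cell ROI is smoothed with a masked Gaussian blur, min-max normalized
#' within the cell, and thresholded; connected components are then filtered
#' by area and by the eccentricity of their equal-second-moment ellipse.
#' Reported mean intensities are taken from the unblurred input pixels.
#'
#' @param image numeric matrix of background-corrected counts (full frame or
#'   ROI).
#' @param cellMask logical or 0/1 matrix delimiting the cell.
#' @param intensityThreshold normalized intensity threshold for the binary
#'   image.
#' @param minArea minimum focus area in pixels.
#' @param maxEccentricity maximum eccentricity (0 = circle).
#' @param minContrast intensity filter: minimum ratio of the component's
#'   mean raw intensity to the mean of the rest of the cell.  Min-max
#'   normalization stretches even pure noise to [0, 1], so a raw-contrast
#'   floor is what separates a real focus from the brightest noise blob in
#'   a homogeneous cell.
#' @param blurSd Gaussian blur sd in um applied before normalization.
#' @param pixelSize um per pixel.
#' @return data.frame with one row per focus: \code{centroid_row},
#'   \code{centroid_col}, \code{area}, \code{eccentricity},
#'   \code{mean_intensity}; zero rows when no focus survives the filters.
#'   Attribute \code{"degenerate"} is TRUE for constant-intensity cells.
#' @export
detectFoci <- function(image, cellMask, intensityThreshold = 0.5,
                       minArea = 4, maxEccentricity = 0.9, minContrast = 1.3,
                       blurSd = 0.066, pixelSize = 0.066) {
  mFull <- cellMask != 0
  empty <- data.frame(centroid_row = numeric(), centroid_col = numeric(),
                      area = integer(), eccentricity = numeric(),
                      mean_intensity = numeric())
  if (!any(mFull)) stop("cell mask is empty")
  # crop to the cell bounding box (plus the blur kernel support) for speed
  idx <- which(mFull, arr.ind = TRUE)
  pad <- ceiling(4 * blurSd / pixelSize) + 2
  r1 <- max(1, min(idx[, 1]) - pad); r2 <- min(nrow(image), max(idx[, 1]) + pad)
  c1 <- max(1, min(idx[, 2]) - pad); c2 <- min(ncol(image), max(idx[, 2]) + pad)
  img <- image[r1:r2, c1:c2, drop = FALSE]
  m <- mFull[r1:r2, c1:c2, drop = FALSE]
  blurred <- gaussianBlur(img, blurSd, pixelSize, mask = m)
  norm <- minmaxNormalize(blurred[m])
  if (norm$degenerate) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  nimg <- matrix(0, nrow(img), ncol(img))
  nimg[m] <- norm$values
  bin <- matrix(0L, nrow(img), ncol(img))
  bin[m & nimg >= intensityThreshold] <- 1L
  lab <- EBImage::imageData(EBImage::bwlabel(bin))
  comps <- .labelPixels(lab)
  rows <- lapply(comps, function(pix) {
    pr <- .regionProps(pix, img[pix])
    data.frame(centroid_row = pr$centroidRow + r1 - 1,
               centroid_col = pr$centroidCol + c1 - 1,
               area = pr$area, eccentricity = pr$eccentricity,
               mean_intensity = pr$meanIntensity)
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty
  contrast <- vapply(seq_along(comps), function(i) {
    rest <- img[m]
    restMean <- (sum(rest) - sum(img[comps[[i]]])) /
      (length(rest) - nrow(comps[[i]]))
    if (restMean <= 0) Inf else mean(img[comps[[i]]]) / restMean
  }, numeric(1))
  keep <- out$area >= minArea & out$eccentricity <= maxEccentricity &
    contrast >= minContrast
  lab[!(lab %in% which(keep))] <- 0L
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- FALSE
  attr(out, "focus_label") <- lab
  attr(out, "bbox") <- c(r1, c1, r2, c2)
  out
}

#' Partition ratio of focus to cytoplasm intensity
#'
#' Ratio of the mean background-corrected intensity within the focus region
#' to the mean over the rest of the cell.  With two or more foci, the
#' per-focus mean intensities are first averaged.
#'
#' @param image numeric matrix of background-corrected counts.
#' @param cellMask logical/0-1 matrix delimiting the cell.
#' @param foci data.frame from \code{\link{detectFoci}} (its
#'   \code{"focus_label"} attribute identifies the focus pixels), or a
#'   logical matrix marking focus pixels directly.
#' @return numeric ratio, with attribute \code{"unreliable"} = TRUE when the
#'   cytoplasm mean is not positive.
#' @export
partitionRatio <- function(image, cellMask, foci) {
  m <- cellMask != 0
  if (is.matrix(foci)) {
    fmask <- foci != 0
    if (!any(fmask)) stop("no focus pixels supplied")
    focusMean <- mean(image[fmask & m])
  } else {
    if (nrow(foci) == 0L) stop("no foci supplied")
    lab <- attr(foci, "focus_label")
    if (is.null(lab)) stop("foci table lacks the focus_label attribute")
    fmask <- matrix(FALSE, nrow(image), ncol(image))
    bb <- attr(foci, "bbox")
    if (is.null(bb)) bb <- c(1, 1, nrow(lab), ncol(lab))
    fmask[bb[1]:bb[3], bb[2]:bb[4]] <- lab > 0
    fmask <- fmask & m
    focusMean <- mean(foci$mean_intensity)
  }
  cyto <- image[m & !fmask]
  if (length(cyto) == 0L) stop("cytoplasm region is empty")
  cytoMean <- mean(cyto)
  out <- focusMean / cytoMean
  attr(out, "unreliable") <- cytoMean <= 0
  out
}

#' Percent of cells with a detected focus
#'
#' @param hasFocus logical vector, one element per cell.
#' @param replicate optional factor of replicate labels; when present the
#'   per-replicate percentages and their mean and sd are also returned.
#' @return numeric percentage; with replicates, a list with \code{percent},
#'   \code{by_replicate}, \code{mean}, \code{sd}.
#' @examples
#' populationFocusFraction(c(rep(TRUE, 8), rep(FALSE, 2)))  # 80
#' @export
populationFocusFraction <- function(hasFocus, replicate = NULL) {
  if (length(hasFocus) == 0L) stop("empty population")
  overall <- 100 * mean(hasFocus)
  if (is.null(replicate)) return(overall)
  byRep <- tapply(hasFocus, replicate, function(x) 100 * mean(x))
  list(percent = overall, by_replicate = byRep,
       mean = mean(byRep), sd = stats::sd(byRep))
}

#' Normalize a FRAP recovery trace
#'
#' Scales a background-corrected focus intensity trace so the pre-bleach
#' mean is one and the first post-bleach frame is zero.  When an unbleached
#' reference focus trace is supplied, acquisition photobleaching is first
#' corrected by dividing by the reference normalized to its own pre-bleach
#' mean.
#'
#' @param trace numeric vector of background-corrected focus intensities.
#' @param bleachFrame index of the first post-bleach frame.
#' @param reference optional trace of an unbleached focus in the same cell.
#' @return list with \code{time_index}, \code{value} (normalized trace) and
#'   \code{bleach_frame}.
#' @export
normalizeFrap <- function(trace, bleachFrame, reference = NULL) {
  n <- length(trace)
  if (bleachFrame < 2 || bleachFrame > n)
    stop("need at least one pre-bleach and one post-bleach frame")
  if (!is.null(reference)) {
    refPre <- mean(reference[seq_len(bleachFrame - 1)])
    if (refPre <= 0) stop("reference pre-bleach mean must be positive")
    trace <- trace / (reference / refPre)
  }
  pre <- mean(trace[seq_len(bleachFrame - 1)])
  post0 <- trace[bleachFrame]
  if (pre == post0) stop("no bleach depth: pre-bleach mean equals the first ",
                         "post-bleach value")
  list(time_index = seq_len(n), value = (trace - post0) / (pre - post0),
       bleach_frame = bleachFrame)
}

#' Per-cell condensation coefficients for a whole frame
#'
#' Convenience wrapper applying the per-cell pipeline (masked blur within
#' the cell, min-max normalization, threshold fraction) to every labelled
#' cell of a frame, cropping each cell's bounding box for speed.
#'
#' @param image background-corrected intensity matrix.
#' @param mask integer label mask.
#' @param thresholds numeric vector of normalized-intensity thresholds.
#' @param blurSd Gaussian blur sd in um.
#' @param pixelSize um per pixel.
#' @param percent logical; report percent rather than fractions.
#' @return data.frame with \code{cell_id}, one column per threshold
#'   (\code{coef_<threshold>}) and \code{degenerate}.
#' @export
condensationTable <- function(image, mask, thresholds = c(0.3, 0.5, 0.7),
                              blurSd = 0.066, pixelSize = 0.066,
                              percent = TRUE) {
  ids <- sort(unique(mask[mask > 0]))
  pad <- ceiling(4 * blurSd / pixelSize) + 2
  rows <- lapply(ids, function(id) {
    idx <- which(mask == id, arr.ind = TRUE)
    r1 <- max(1, min(idx[, 1]) - pad); r2 <- min(nrow(image), max(idx[, 1]) + pad)
    c1 <- max(1, min(idx[, 2]) - pad); c2 <- min(ncol(image), max(idx[, 2]) + pad)
    img <- image[r1:r2, c1:c2, drop = FALSE]
    m <- mask[r1:r2, c1:c2, drop = FALSE] == id
    norm <- minmaxNormalize(gaussianBlur(img, blurSd, pixelSize, mask = m)[m])
    vals <- vapply(thresholds, function(th)
      condensationCoefficient(norm, th, percent), numeric(1))
    out <- data.frame(cell_id = id, degenerate = norm$degenerate)
    out[paste0("coef_", thresholds)] <- as.list(vals)
    out
  })
  do.call(rbind, rows)
}
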