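# Two-channel chaperone colocalization: reference-focus detection, 23x23
# ROI pairs, averaged projections and 2D Gaussian FWHM-ratio fitting.

#' Detect reference-channel foci by fractional intensity threshold
#'
#' Connected components above 30 percent of the image maximum, filtered by
#' minimum area and maximum eccentricity.
#'
#' @param image background-corrected reference-channel matrix.
#' @param thresholdFrac intensity threshold as a fraction of the image max.
#' @param minArea minimum component area (px).
#' @param maxEccentricity maximum eccentricity of the component ellipse.
#' @return data.frame with \code{centroid_row}, \code{centroid_col},
#'   \code{area}, \code{eccentricity}.
#' @export
detectReferenceFoci <- function(image, thresholdFrac = 0.30, minArea = 4,
                                maxEccentricity = 0.75) {
  thr <- thresholdFrac * max(image)
  lab <- EBImage::imageData(EBImage::bwlabel((image > thr) * 1L))
  comps <- .labelPixels(lab)
  rows <- lapply(comps, function(pix) {
    pr <- .regionProps(pix, image[pix])
    data.frame(centroid_row = pr$centroidRow, centroid_col = pr$centroidCol,
               area = pr$area, eccentricity = pr$eccentricity)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(centroid_row = numeric(), centroid_col = numeric(),
               area = integer(), eccentricity = numeric())
  out <- out[out$area >= minArea & out$eccentricity <= maxEccentricity, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract paired two-channel ROIs around reference foci
#'
#' Cuts a square patch (default 23 x 23 px) from both channels at identical
#' coordinates centred on each reference-focus centroid, normalizes both
#' patches to the reference-patch maximum, and records the centre-row
#' intensity profile of each channel.  Centroids too close to a border are
#' discarded.
#'
#' @param ref,probe numeric matrices (background-corrected channels).
#' @param centroids data.frame from \code{\link{detectReferenceFoci}}.
#' @param size odd patch edge length in px.
#' @return list of ROI pairs, each a list with \code{ref}, \code{probe}
#'   (normalized patches), \code{profile_ref}, \code{profile_probe},
#'   \code{norm} (the reference max used) and \code{center}; the number of
#'   border-discarded foci is in attribute \code{"discarded"}.
#' @export
extractRoiPairs <- function(ref, probe, centroids, size = 23) {
  stopifnot(size %% 2 == 1, all(dim(ref) == dim(probe)))
  half <- (size - 1) / 2
  out <- list(); discarded <- 0L
  for (i in seq_len(nrow(centroids))) {
    r <- round(centroids$centroid_row[i])
    c <- round(centroids$centroid_col[i])
    if (r - half < 1 || r + half > nrow(ref) ||
        c - half < 1 || c + half > ncol(ref)) {
      discarded <- discarded + 1L
      next
    }
    pr <- ref[(r - half):(r + half), (c - half):(c + half)]
    pp <- probe[(r - half):(r + half), (c - half):(c + half)]
    m <- max(pr)
    if (m <= 0) {
      discarded <- discarded + 1L
      next
    }
    out[[length(out) + 1L]] <- list(
      ref = pr / m, probe = pp / m,
      profile_ref = pr[half + 1, ] / m, profile_probe = pp[half + 1, ] / m,
      norm = m, center = c(row = r, col = c))
  }
  if (length(out) == 0L) warning("all centroids discarded near borders")
  attr(out, "discarded") <- discarded
  out
}

#' Average normalized ROI pairs into projection images
#'
#' @param rois list from \code{\link{extractRoiPairs}}.
#' @return list with \code{ref} and \code{probe} mean patches.
#' @export
averageProjection <- function(rois) {
  if (length(rois) == 0L) stop("no ROIs to average")
  list(ref = Reduce(`+`, lapply(rois, `[[`, "ref")) / length(rois),
       probe = Reduce(`+`, lapply(rois, `[[`, "probe")) / length(rois))
}

# Anisotropic 2D Gaussian + offset fit for projection images.
.fitGaussian2D <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # initialize from a lightly smoothed patch so single noise pixels cannot
  # seed a collapsed fit
  sm <- .convolve2(img, .gaussKernel(1))
  off0 <- min(sm); amp0 <- max(sm) - off0
  w <- pmax(sm - off0, 0)
  r0 <- sum(rows * w) / sum(w); c0 <- sum(cols * w) / sum(w)
  sr0 <- min(max(sqrt(sum((rows - r0)^2 * w) / sum(w)), 1), nr / 2)
  sc0 <- min(max(sqrt(sum((cols - c0)^2 * w) / sum(w)), 1), nc / 2)
  res <- function(p) {
    model <- p[6] + p[1] * exp(-((rows - p[2])^2 / (2 * p[4]^2) +
                                 (cols - p[3])^2 / (2 * p[5]^2)))
    as.vector(model - img)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(amp0, r0, c0, sr0, sc0, off0), fn = res,
                       lower = c(0, 1, 1, 0.7, 0.7, -Inf),
                       upper = c(Inf, nr, nc, 2 * nr, 2 * nc, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  ss <- sum(res(p)^2); st <- sum((img - mean(img))^2)
  list(amplitude = p[1], row = p[2], col = p[3], sigmaRow = abs(p[4]),
       sigmaCol = abs(p[5]), offset = p[6],
       r2 = if (st > 0) 1 - ss / st else NA_real_)
}

#' FWHM ratio and relative amplitude of a projection pair
#'
#' Fits an anisotropic 2D Gaussian with offset to each channel's projection
#' image.  The FWHM per channel is 2 sqrt(2 ln 2) times the geometric mean
#' of the fitted sigmas; the reported ratio is FWHM(probe) / FWHM(ref) and
#' the relative maximum intensity is the probe projection peak as percent
#' of the reference peak.  A rosette-shaped probe is poorly described by a
#' single Gaussian, so the probe fit R^2 is reported and low values are
#' flagged rather than hidden.
#'
#' @param projection list with \code{ref} and \code{probe} matrices, as
#'   returned by \code{\link{averageProjection}}.
#' @param pixelSize um per pixel (for the um-scale FWHM).
#' @param r2Flag probe-fit R^2 below which \code{"probe_fit_poor"} is set.
#' @return a \linkS4class{FwhmResult}.
#' @export
fitFwhmRatio <- function(projection, pixelSize = 0.066, r2Flag = 0.8) {
  fr <- .fitGaussian2D(projection$ref)
  fp <- .fitGaussian2D(projection$probe)
  if (is.null(fr) || is.null(fp) || fr$amplitude <= 0 || fp$amplitude <= 0)
    return(new("FwhmResult", flags = "fit_failed"))
  k <- 2 * sqrt(2 * log(2))
  fwhmRef <- k * sqrt(fr$sigmaRow * fr$sigmaCol)
  fwhmProbe <- k * sqrt(fp$sigmaRow * fp$sigmaCol)
  flags <- character()
  if (!is.na(fp$r2) && fp$r2 < r2Flag) flags <- c(flags, "probe_fit_poor")
  relMax <- 100 * (max(projection$probe) - fp$offset) /
    (max(projection$ref) - fr$offset)
  new("FwhmResult", fwhmRef = fwhmRef, fwhmProbe = fwhmProbe,
      ratio = fwhmProbe / fwhmRef, relMaxPct = relMax,
      fitRef = fr, fitProbe = fp, contourLevels = c(0.25, 0.5, 0.75),
      flags = flags)
}
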