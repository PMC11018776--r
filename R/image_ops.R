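#' Subtract the out-of-cell median background from an image
#'
#' The background level is estimated as the median of all pixels outside the
#' segmented cell regions and subtracted from every pixel.  Values are not
#' clipped, so corrected intensities may be negative.
#'
#' @param image numeric matrix of intensity counts.
#' @param mask integer label mask of the same dimensions; 0 marks background.
#' @return The corrected matrix, with the estimated background in attribute
#'   \code{"background"}.
#' @examples
#' img <- matrix(110, 8, 8); img[1, ] <- 10
#' msk <- matrix(1L, 8, 8); msk[1, ] <- 0L
#' backgroundCorrect(img, msk)[2, 2]  # 100
#' @export
backgroundCorrect <- function(image, mask) {
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)))
  outside <- image[mask == 0]
  if (length(outside) == 0L)
    stop("mask covers the entire frame; no background pixels to estimate from")
  bg <- stats::median(outside)
  out <- image - bg
  attr(out, "background") <- bg
  out
}

#' Min-max normalize the pixels of one cell
#'
#' Rescales intensities to I_n = (I - Imin) / (Imax - Imin) using the
#' minimum and maximum over that cell only.  Cells whose pixels are all
#' equal cannot be normalized and are flagged degenerate so downstream
#' statistics can exclude them explicitly.
#'
#' @param values numeric vector or matrix of one cell's (background
#'   corrected) pixel intensities.
#' @return A list with elements \code{values} (normalized, same shape),
#'   \code{imin}, \code{imax} and \code{degenerate}.
#' @examples
#' minmaxNormalize(c(0, 5, 10))$values  # 0 0.5 1
#' @export
minmaxNormalize <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 2L) stop("need at least two pixels to normalize")
  imin <- min(v); imax <- max(v)
  if (imax == imin) {
    return(list(values = values * NA_real_, imin = imin, imax = imax,
                degenerate = TRUE))
  }
  out <- (values - imin) / (imax - imin)
  list(values = out, imin = imin, imax = imax, degenerate = FALSE)
}

#' Gaussian blur with physical-unit bandwidth
#'
#' Convolves the image with an isotropic Gaussian of standard deviation
#' \code{sd} micrometres (converted to pixels via \code{pixelSize}), using a
#' reflective boundary.  When \code{mask} is supplied, a normalized (masked)
#' convolution is used: only in-mask pixels contribute, so cell interiors
#' are not darkened by the empty background beyond the cell edge.
#'
#' @param image numeric matrix.
#' @param sd Gaussian standard deviation in micrometres (0 is the identity).
#' @param pixelSize micrometres per pixel.
#' @param mask optional logical/integer matrix; non-zero marks pixels that
#'   participate in the smoothing.
#' @return Blurred matrix of the same dimensions.
#' @export
gaussianBlur <- function(image, sd, pixelSize = 0.066, mask = NULL) {
  stopifnot(sd >= 0, pixelSize > 0)
  if (sd == 0) return(image)
  k <- .gaussKernel(sd / pixelSize)
  if (is.null(mask)) return(.convolve2(image, k))
  m <- (mask != 0) * 1
  num <- .convolve2(image * m, k)
  den <- .convolve2(m, k)
  out <- image
  inmask <- m > 0 & den > 0
  out[inmask] <- num[inmask] / den[inmask]
  out
}

#' Otsu-threshold fallback segmenter
#'
#' A convenience segmenter for demonstration: global Otsu threshold,
#' connected-component labelling, then removal of components touching the
#' image border (border-touching cells are excluded from all analyses) and
#' of specks below \code{minArea}.  Not a substitute for a trained cell
#' segmenter; simulated inputs come with exact ground-truth masks.
#'
#' @param image numeric matrix.
#' @param minArea minimum component area in pixels.
#' @return Integer label matrix (0 = background), labels made consecutive.
#' @export
segmentFallback <- function(image, minArea = 20) {
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("blank image: no foreground found")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  sc <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(sc))
  lab <- EBImage::bwlabel(sc > thr)
  lab <- EBImage::imageData(lab)
  # drop border-touching components
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  lab[lab %in% border] <- 0
  # drop specks
  tab <- table(lab[lab > 0])
  small <- as.integer(names(tab)[tab < minArea])
  lab[lab %in% small] <- 0
  # relabel consecutively
  labs <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(labs)) out[lab == labs[i]] <- i
  if (length(labs) == 0L) warning("no foreground components after filtering")
  out
}
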