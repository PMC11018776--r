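# Absolute-concentration photon counting: camera gain calibrations, count
# to photon conversion, single-molecule brightness, copy numbers,
# spherocylinder volumes, molar concentrations and the apparent saturation
# concentration.

#' Fit the conversion gain from a flat-field calibration series
#'
#' For each exposure, the two bias-subtracted flat-field frames give the
#' mean signal and, from half the variance of their difference (which
#' removes pixel-to-pixel nonuniformity), the shot-noise variance.  The
#' least-squares slope of mean versus variance is the conversion gain in
#' electrons per intensity count; additive read-noise variance is absorbed
#' by the intercept.
#'
#' @param calib calibration series as produced by
#'   \code{\link{simulateCalibrationSeries}}: a list with \code{flatfield}
#'   (per exposure, a list of two frames) and \code{bias} (list of bias
#'   frames).
#' @return a \linkS4class{GainCalibration} with \code{conversionGain} set;
#'   diagnostics hold the per-exposure points and fit R^2.
#' @export
fitConversionGain <- function(calib) {
  if (length(calib$flatfield) < 3)
    stop("need at least three exposure levels")
  biasFrame <- Reduce(`+`, calib$bias) / length(calib$bias)
  pts <- do.call(rbind, lapply(calib$flatfield, function(pair) {
    f1 <- pair[[1]] - biasFrame
    f2 <- pair[[2]] - biasFrame
    data.frame(mean = mean((f1 + f2) / 2),
               variance = stats::var(as.vector(f1 - f2)) / 2)
  }))
  if (any(pts$variance <= 0)) stop("zero-variance flat-field input")
  fit <- stats::lm(mean ~ variance, data = pts)
  g <- unname(stats::coef(fit)[2])
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    max(sum((pts$mean - mean(pts$mean))^2), .Machine$double.eps)
  new("GainCalibration", conversionGain = g, emGainFactor = NA_real_,
      diagnostics = list(points = pts, r2 = r2,
                         intercept = unname(stats::coef(fit)[1])))
}

#' Fit the EM-gain conversion factor
#'
#' Each nominal gain contributes a multiplication factor: the ratio of
#' bias-subtracted signal per unit exposure between the EM image and the
#' no-EM image.  The factor is fit linearly against the nominal gain
#' through the origin over nominal gains 5-600; the slope is the EM-gain
#' conversion factor.
#'
#' @param calib calibration series with an \code{em} element as produced by
#'   \code{\link{simulateCalibrationSeries}}.
#' @param gainRange nominal gains outside this range are excluded.
#' @return a \linkS4class{GainCalibration} with \code{emGainFactor} set.
#' @export
fitEmGainFactor <- function(calib, gainRange = c(5, 600)) {
  biasFrame <- Reduce(`+`, calib$bias) / length(calib$bias)
  pts <- do.call(rbind, lapply(calib$em, function(e) {
    sigNo <- mean(e$noEm - biasFrame) / e$exposureNoEm
    if (sigNo <= 0) stop("no-EM signal must be positive")
    sigEm <- mean(e$em - biasFrame) / e$exposureEm
    data.frame(nominal = e$nominalGain, factor = sigEm / sigNo)
  }))
  out <- pts$nominal < gainRange[1] | pts$nominal > gainRange[2]
  if (any(out)) {
    warning("excluding nominal gain(s) outside [", gainRange[1], ", ",
            gainRange[2], "]: ", paste(pts$nominal[out], collapse = ", "))
    pts <- pts[!out, , drop = FALSE]
  }
  if (nrow(pts) < 3) stop("need at least three nominal gains within range")
  fit <- stats::lm(factor ~ 0 + nominal, data = pts)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    max(sum(pts$factor^2), .Machine$double.eps)
  new("GainCalibration", conversionGain = NA_real_,
      emGainFactor = unname(stats::coef(fit)[1]),
      diagnostics = list(points = pts, r2 = r2))
}

#' Convert intensity counts to photons
#'
#' photons = counts * conversion_gain / (nominal_EM_gain * EM_gain_factor).
#'
#' @param counts numeric vector of (bias-subtracted) intensity counts.
#' @param camera optional \linkS4class{CameraModel} supplying all three
#'   calibration constants.
#' @param conversionGain electrons per count.
#' @param nominalEmGain software EM gain during acquisition.
#' @param emGainFactor EM-gain conversion factor.
#' @return numeric photons.
#' @examples
#' countsToPhotons(900, conversionGain = 1.40, nominalEmGain = 600,
#'                 emGainFactor = 0.15)  # 14
#' @export
countsToPhotons <- function(counts, camera = NULL, conversionGain = 1.40,
                            nominalEmGain = 10, emGainFactor = 0.15) {
  if (!is.null(camera)) {
    conversionGain <- camera@conversionGain
    nominalEmGain <- camera@nominalEmGain
    emGainFactor <- camera@emGainFactor
  }
  div <- nominalEmGain * emGainFactor
  if (div <= 0) stop("nominal EM gain times EM-gain factor must be positive")
  counts * conversionGain / div
}

#' Gamma fit of per-molecule photon counts
#'
#' Maximum-likelihood Gamma fit to the distribution of photons detected
#' per molecule per imaging frame; the reported single-molecule brightness
#' is the distribution mode (k - 1) * theta.
#'
#' @param samples numeric vector of per-molecule photon counts (> 0).
#' @return a \linkS4class{GammaFit}.  The mode is flagged undefined when
#'   the fitted shape is <= 1, and degenerate samples (all equal) return
#'   that value as the mode with a flag.
#' @export
photonsPerMolecule <- function(samples) {
  x <- samples[is.finite(samples)]
  if (any(x <= 0)) stop("photon samples must be positive")
  if (length(x) < 100)
    warning("fewer than 100 samples; Gamma fit may be unstable")
  if (stats::sd(x) == 0)
    return(new("GammaFit", shape = Inf, scale = 0, mode = x[1],
               method = "degenerate", flags = "degenerate"))
  fit <- tryCatch(suppressWarnings(MASS::fitdistr(x, "gamma")),
                  error = function(e) NULL)
  if (!is.null(fit)) {
    k <- unname(fit$estimate["shape"])
    theta <- 1 / unname(fit$estimate["rate"])
    method <- "mle"
  } else {
    k <- mean(x)^2 / stats::var(x)
    theta <- stats::var(x) / mean(x)
    method <- "moments"
  }
  flags <- character()
  mode <- if (k > 1) (k - 1) * theta else NA_real_
  if (k <= 1) flags <- "mode_undefined"
  new("GammaFit", shape = k, scale = theta, mode = mode, method = method,
      flags = flags)
}

#' Pre-bleach integrated cell intensity
#'
#' Integrated background-corrected intensity of one cell per frame,
#' averaged over the five brightest frames of the movie (the cell
#' brightness before photobleaching has degraded the signal).
#'
#' @param movie numeric array (rows x cols x frames), at least 5 frames.
#' @param mask integer label matrix (static) or array matching the movie.
#' @param cellId cell label; NULL integrates over all labelled pixels.
#' @param nBrightest number of brightest frames averaged.
#' @param backgroundCorrected logical; TRUE when the movie frames have
#'   already been background corrected (saves recomputing the correction
#'   per cell when many cells share a frame).
#' @return numeric scalar, counts per frame.
#' @export
prebleachCellIntensity <- function(movie, mask, cellId = NULL,
                                   nBrightest = 5,
                                   backgroundCorrected = FALSE) {
  nT <- dim(movie)[3]
  if (is.na(nT) || nT < nBrightest)
    stop("movie must have at least ", nBrightest, " frames")
  maskIsArray <- length(dim(mask)) == 3
  perFrame <- vapply(seq_len(nT), function(t) {
    m <- if (maskIsArray) mask[, , t] else mask
    sel <- if (is.null(cellId)) m > 0 else m == cellId
    corr <- if (backgroundCorrected) movie[, , t] else
      backgroundCorrect(movie[, , t], m)
    sum(corr[sel])
  }, numeric(1))
  mean(sort(perFrame, decreasing = TRUE)[seq_len(nBrightest)])
}

#' Spherocylinder volume of a rod-shaped cell
#'
#' Models the cell as a cylinder of length L - w capped by two hemispheres
#' of diameter w: V = pi r^2 (L - 2r) + (4/3) pi r^3 with r = w / 2.
#'
#' @param length cell length L in um (tip to tip).
#' @param width cell width w in um.
#' @return volume in um^3 (vectorized).
#' @examples
#' spherocylinderVolume(1, 1)  # sphere: 0.5236
#' spherocylinderVolume(3, 1)  # 2.0944
#' @export
spherocylinderVolume <- function(length, width) {
  if (any(length < width)) stop("length must be >= width")
  if (any(width <= 0)) stop("width must be positive")
  r <- width / 2
  pi * r^2 * (length - 2 * r) + (4 / 3) * pi * r^3
}

#' Copy number and molar concentration of a cell
#'
#' Copy number is the cell's integrated photons per frame divided by the
#' single-molecule brightness (photons per molecule per frame); the molar
#' concentration is copy number over Avogadro's number times the cell
#' volume.
#'
#' @param photonsPerFrame integrated photons per imaging frame (vectorized).
#' @param photonsPerMoleculeMode single-molecule brightness, e.g. the mode
#'   of \code{\link{photonsPerMolecule}}.
#' @param volume cell volume in um^3.
#' @return data.frame with \code{copy_number} and \code{concentration_uM}.
#' @examples
#' cellularConcentration(1000 * 90, 90, 1)  # 1000 copies, 1.66 uM
#' @export
cellularConcentration <- function(photonsPerFrame, photonsPerMoleculeMode,
                                  volume) {
  if (any(photonsPerMoleculeMode <= 0))
    stop("photons per molecule must be positive")
  if (any(volume <= 0)) stop("volume must be positive")
  n <- photonsPerFrame / photonsPerMoleculeMode
  conc <- n / (6.02214076e23 * volume * 1e-15) * 1e6
  data.frame(copy_number = n, concentration_uM = conc)
}

#' Apparent saturation concentration from focus-classified cells
#'
#' Summarizes per-cell concentrations by focus status and reports the
#' apparent saturation-concentration range as
#' [no-focus mean - no-focus sd, focus mean + focus sd] (an interpretation,
#' flagged as such in the output), plus a two-sided Welch t-test on the
#' replicate means when replicate labels are available.
#'
#' @param records data.frame with \code{concentration_uM}, \code{has_focus}
#'   and optionally \code{replicate}.
#' @return list with \code{no_focus} and \code{focus} (mean, sd, n),
#'   \code{csat_range} (with attribute \code{"interpreted"} = TRUE),
#'   \code{welch} (htest or NULL).
#' @export
estimateCsat <- function(records) {
  stopifnot(all(c("concentration_uM", "has_focus") %in% names(records)))
  g0 <- records$concentration_uM[!records$has_focus]
  g1 <- records$concentration_uM[records$has_focus]
  if (!length(g0) || !length(g1)) stop("both groups must be non-empty")
  summ <- function(x) list(mean = mean(x), sd = stats::sd(x), n = length(x))
  s0 <- summ(g0); s1 <- summ(g1)
  rng <- c(lower = s0$mean - s0$sd, upper = s1$mean + s1$sd)
  attr(rng, "interpreted") <- TRUE
  welch <- NULL
  if ("replicate" %in% names(records)) {
    m0 <- tapply(g0, records$replicate[!records$has_focus], mean)
    m1 <- tapply(g1, records$replicate[records$has_focus], mean)
    if (length(m0) >= 2 && length(m1) >= 2) {
      welch <- stats::t.test(m1, m0, var.equal = FALSE)
    } else warning("fewer than two replicates; Welch test skipped")
  }
  list(no_focus = s0, focus = s1, csat_range = rng, welch = welch)
}

#' Measure cell geometry from a label mask
#'
#' Per-label principal-axis extents: length and width are the pixel extents
#' along the major and minor axis (plus one pixel for the half-pixel border
#' on each side), converted to micrometres.
#'
#' @param mask integer label matrix.
#' @param pixelSize um per pixel.
#' @return data.frame with \code{cell_id}, \code{row_px}, \code{col_px},
#'   \code{theta}, \code{length_um}, \code{width_um}, \code{area_px}.
#' @export
measureCellGeometry <- function(mask, pixelSize = 0.066) {
  comps <- .labelPixels(mask)
  out <- lapply(names(comps), function(lab) {
    pix <- comps[[lab]]
    cr <- mean(pix[, 1]); cc <- mean(pix[, 2])
    dr <- pix[, 1] - cr; dc <- pix[, 2] - cc
    cv <- stats::cov(cbind(dc, dr))
    if (nrow(pix) < 3 || !all(is.finite(cv))) {
      ev <- list(vectors = diag(2))
    } else ev <- eigen(cv, symmetric = TRUE)
    major <- ev$vectors[, 1]
    u <- dc * major[1] + dr * major[2]
    v <- -dc * major[2] + dr * major[1]
    data.frame(cell_id = as.integer(lab), row_px = cr, col_px = cc,
               theta = atan2(major[2], major[1]),
               length_um = (diff(range(u)) + 1) * pixelSize,
               width_um = (diff(range(v)) + 1) * pixelSize,
               area_px = nrow(pix))
  })
  do.call(rbind, out)
}
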