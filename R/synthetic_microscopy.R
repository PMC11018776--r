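# Synthetic-microscopy generator: renders rod-shaped (spherocylindrical)
# bacterial cells with cytoplasmic fluorescence and optional polar foci,
# applies an EMCCD camera model, and emits exact ground truth for every
# quantity the analysis pipeline later estimates.

## ---- geometry ------------------------------------------------------------

# Logical footprint of a spherocylinder on the pixel grid.
# (cr, cc) centre in px, theta radians from the column (x) axis,
# lengthUm >= widthUm in micrometres.
.spherocylFootprint <- function(nr, nc, cr, cc, theta, lengthUm, widthUm,
                                pixelSize) {
  Lpx <- lengthUm / pixelSize
  wpx <- widthUm / pixelSize
  h <- max((Lpx - wpx) / 2, 0)
  ur <- sin(theta); uc <- cos(theta)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- rows - cr; dc <- cols - cc
  t <- pmax(pmin(dr * ur + dc * uc, h), -h)
  d2 <- (dr - t * ur)^2 + (dc - t * uc)^2
  d2 <= (wpx / 2)^2
}

# Pole positions (row, col) of a cell, at `inset` px in from each tip.
.polePositions <- function(cr, cc, theta, lengthUm, widthUm, pixelSize,
                           inset = NULL) {
  Lpx <- lengthUm / pixelSize; wpx <- widthUm / pixelSize
  if (is.null(inset)) inset <- wpx / 2
  h <- Lpx / 2 - inset
  ur <- sin(theta); uc <- cos(theta)
  rbind(c(cr + h * ur, cc + h * uc), c(cr - h * ur, cc - h * uc))
}

## ---- camera forward model ------------------------------------------------

# photons (matrix) -> digitized counts under the camera model.
.applyCamera <- function(photons, camera, noise = TRUE) {
  M <- camera@nominalEmGain * camera@emGainFactor
  g <- camera@conversionGain
  if (noise) {
    pe <- matrix(stats::rpois(length(photons), pmax(photons, 0)),
                 nrow(photons), ncol(photons))
    counts <- pe * M / g + camera@biasCounts
    if (camera@readNoiseSD > 0)
      counts <- counts + matrix(stats::rnorm(length(counts), 0,
                                             camera@readNoiseSD),
                                nrow(counts), ncol(counts))
  } else {
    counts <- photons * M / g + camera@biasCounts
  }
  counts
}

## ---- ground-truth tables -------------------------------------------------

#' Generate a ground-truth cell population on a non-overlapping grid
#'
#' Cells are laid out on a regular grid with a margin of at least 3 px
#' between footprints, with sub-pixel positional jitter so pixel
#' discretization does not align across the population.  Copy numbers can
#' be given directly or derived from a target molar concentration and each
#' cell's spherocylinder volume.
#'
#' @param n number of cells.
#' @param camera a \linkS4class{CameraModel} (for the pixel size).
#' @param meanLength,sdLength cell length distribution (um).
#' @param meanWidth,sdWidth cell width distribution (um).
#' @param copyNumber molecules per cell: scalar, vector of length n, or NULL
#'   to derive from \code{concentration}.
#' @param concentration target concentration in uM (used when
#'   \code{copyNumber} is NULL); per-cell copy number is then
#'   concentration * Avogadro * volume.
#' @param sdConcentration per-cell sd of the concentration draw (uM).
#' @param focusFraction fraction of cells carrying a focus.
#' @param partitionRatio dense/dilute intensity ratio for focus-bearing
#'   cells (scalar or vector); must be >= 1.
#' @param focusSigmaPx Gaussian focus sd in pixels.
#' @param marginPx margin around each cell's grid slot.
#' @param horizontal logical; TRUE lays all cells along the x axis,
#'   otherwise orientations are drawn uniformly.
#' @param seed optional RNG seed.
#' @return A data.frame with one row per cell (columns \code{cell_id},
#'   \code{row_px}, \code{col_px}, \code{theta}, \code{length_um},
#'   \code{width_um}, \code{copy_number}, \code{focus_present},
#'   \code{partition_ratio}, \code{focus_sigma_px}, \code{lineage_id}) and
#'   attribute \code{"fieldDim"} giving the frame size that fits the grid.
#' @export
makeCellTruth <- function(n, camera = CameraModel(), meanLength = 2.5,
                          sdLength = 0.3, meanWidth = 1.0, sdWidth = 0.05,
                          copyNumber = 50000, concentration = NULL,
                          sdConcentration = 0, focusFraction = 0,
                          partitionRatio = 5, focusSigmaPx = 1.6,
                          marginPx = 4, horizontal = TRUE, seed = NULL) {
  .withSeed(seed)
  p <- camera@pixelSize
  len <- pmax(stats::rnorm(n, meanLength, sdLength), meanWidth * 1.2)
  wid <- pmax(stats::rnorm(n, meanWidth, sdWidth), 0.5)
  len <- pmax(len, wid)
  theta <- if (horizontal) rep(0, n) else stats::runif(n, 0, pi)
  slot <- ceiling(max(len) / p) + 2 * marginPx
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  idx <- seq_len(n) - 1L
  cr <- (idx %/% ncols) * slot + slot / 2 + stats::runif(n, -0.5, 0.5)
  cc <- (idx %% ncols) * slot + slot / 2 + stats::runif(n, -0.5, 0.5)
  vol <- spherocylinderVolume(len, wid)
  if (is.null(copyNumber)) {
    stopifnot(!is.null(concentration))
    conc <- stats::rnorm(n, concentration, sdConcentration)
    copyNumber <- conc * 1e-6 * 6.02214076e23 * vol * 1e-15
  }
  copyNumber <- rep_len(copyNumber, n)
  focus <- seq_len(n) <= round(focusFraction * n)
  focus <- sample(focus)  # random placement of focus carriers
  pr <- rep_len(partitionRatio, n)
  pr[!focus] <- 1
  if (any(pr[focus] < 1)) stop("partition_ratio must be >= 1 for foci")
  out <- data.frame(
    cell_id = seq_len(n), row_px = cr, col_px = cc, theta = theta,
    length_um = len, width_um = wid, copy_number = copyNumber,
    volume_um3 = vol, focus_present = focus, partition_ratio = pr,
    focus_sigma_px = focusSigmaPx, lineage_id = seq_len(n))
  attr(out, "fieldDim") <- c(nrows * slot, ncols * slot)
  out
}

## ---- single-frame renderer -----------------------------------------------

# Photon field + mask for one truth table.  The focus is a 2D Gaussian at
# one pole whose amplitude is calibrated numerically so that the intensity
# ratio between the focus region (as the default detection pipeline would
# delineate it: masked blur, min-max normalization, threshold) and the rest
# of the cell equals the requested partition ratio.  Total photons per cell
# equal copy_number * photonsPerMolecule exactly (photon conservation).
.renderPhotonField <- function(truth, dims, config,
                               camera, focusThreshold = 0.5,
                               blurSdUm = 0.066) {
  nr <- dims[1]; nc <- dims[2]
  photons <- matrix(config@backgroundPhotons, nr, nc)
  mask <- matrix(0L, nr, nc)
  p <- camera@pixelSize
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    # work on a local window around the cell for speed
    halfPx <- tr$length_um / 2 / p + tr$width_um / p + 2
    r1 <- max(1, floor(tr$row_px - halfPx)); r2 <- min(nr, ceiling(tr$row_px + halfPx))
    c1 <- max(1, floor(tr$col_px - halfPx)); c2 <- min(nc, ceiling(tr$col_px + halfPx))
    wr <- r2 - r1 + 1; wc <- c2 - c1 + 1
    fp <- .spherocylFootprint(wr, wc, tr$row_px - r1 + 1, tr$col_px - c1 + 1,
                              tr$theta, tr$length_um, tr$width_um, p)
    if (!any(fp)) stop("cell ", tr$cell_id, " falls outside the frame")
    sub <- mask[r1:r2, c1:c2]
    if (any(sub != 0 & fp))
      stop("cell footprints overlap at cell ", tr$cell_id)
    total <- tr$copy_number * config@photonsPerMolecule
    shape <- matrix(0, wr, wc)
    shape[fp] <- 1
    if (isTRUE(tr$focus_present) && tr$partition_ratio > 1) {
      pole <- .polePositions(tr$row_px - r1 + 1, tr$col_px - c1 + 1, tr$theta,
                             tr$length_um, tr$width_um, p)[1, ]
      rows <- matrix(seq_len(wr), wr, wc)
      cols <- matrix(seq_len(wc), wr, wc, byrow = TRUE)
      d2 <- (rows - pole[1])^2 + (cols - pole[2])^2
      gg <- exp(-d2 / (2 * tr$focus_sigma_px^2))
      gg[!fp] <- 0
      beta <- .focusAmplitude(gg, fp, tr$partition_ratio, focusThreshold,
                              blurSdUm / p)
      shape[fp] <- 1 + beta * gg[fp]
    }
    scale <- total / sum(shape[fp])
    win <- photons[r1:r2, c1:c2]
    win[fp] <- win[fp] + shape[fp] * scale
    photons[r1:r2, c1:c2] <- win
    sub[fp] <- tr$cell_id
    mask[r1:r2, c1:c2] <- sub
  }
  list(photons = photons, mask = mask)
}

# Solve for the focus amplitude (relative to the cytoplasm level) that
# makes mean(focus region) / mean(rest of cell) equal the target ratio.
# The detection region is computed on the blurred, normalized relative
# profile, which is amplitude-independent in the noise-free limit.
.focusAmplitude <- function(gg, fp, ratio, threshold, blurSdPx) {
  gb <- if (blurSdPx > 0) {
    k <- .gaussKernel(blurSdPx)
    m <- fp * 1
    num <- .convolve2(gg * m, k)
    den <- .convolve2(m, k)
    out <- gg
    out[fp] <- num[fp] / pmax(den[fp], .Machine$double.eps)
    out
  } else gg
  v <- gb[fp]
  vn <- (v - min(v)) / (max(v) - min(v))
  inRegion <- vn >= threshold
  if (!any(inRegion) || all(inRegion)) inRegion <- gg[fp] >= 0.5
  mIn <- mean(gg[fp][inRegion])
  mOut <- mean(gg[fp][!inRegion])
  denom <- mIn - ratio * mOut
  if (denom <= 0)
    stop("partition ratio ", ratio, " not renderable: focus amplitude ",
         "would be negative or infinite")
  (ratio - 1) / denom
}

#' Render a synthetic cell population
#'
#' Renders each ground-truth cell as a spherocylindrical footprint of
#' cytoplasmic photons plus an optional 2D-Gaussian polar focus whose
#' dense/dilute intensity ratio equals the requested partition ratio, then
#' digitizes the photon field through the EMCCD camera model (Poisson shot
#' noise, EM gain, conversion gain, bias, Gaussian read noise).  The label
#' mask matches the rendered footprints exactly.
#'
#' @param config a \linkS4class{SimConfig}; \code{nFrames > 1} renders a
#'   movie with identical signal and independent noise per frame, times an
#'   optional bleaching decay.
#' @param truth ground-truth table from \code{\link{makeCellTruth}}.
#' @param camera a \linkS4class{CameraModel}.
#' @param dims frame dimensions (rows, cols); defaults to the truth table's
#'   \code{"fieldDim"} attribute.
#' @param bleachPerFrame multiplicative signal retention per frame
#'   (1 = no photobleaching).
#' @return list with \code{image} (counts matrix, or array when
#'   \code{nFrames > 1}), \code{photons} (noise-free photon field),
#'   \code{mask} (integer label matrix), \code{truth}, \code{config},
#'   \code{camera}.
#' @examples
#' tr <- makeCellTruth(4, seed = 1)
#' sim <- renderCellPopulation(SimConfig(seed = 1), tr)
#' dim(sim$image)
#' @export
renderCellPopulation <- function(config, truth, camera = CameraModel(),
                                 dims = attr(truth, "fieldDim"),
                                 bleachPerFrame = 1) {
  stopifnot(is(config, "SimConfig"), is(camera, "CameraModel"))
  if (is.null(dims)) stop("frame dimensions not given and truth table has ",
                          "no fieldDim attribute")
  .withSeed(config@seed)
  field <- .renderPhotonField(truth, dims, config, camera)
  nT <- config@nFrames
  if (nT == 1L) {
    img <- .applyCamera(field$photons, camera, config@noise)
  } else {
    img <- array(0, c(dims[1], dims[2], nT))
    bg <- config@backgroundPhotons
    sig <- field$photons - bg
    for (t in seq_len(nT)) {
      ph <- bg + sig * bleachPerFrame^(t - 1)
      img[, , t] <- .applyCamera(ph, camera, config@noise)
    }
  }
  list(image = img, photons = field$photons, mask = field$mask,
       truth = truth, config = config, camera = camera)
}

## ---- time-lapse ----------------------------------------------------------

#' Simulate a dissolution, elongation or division time lapse
#'
#' Renders a movie of cells whose polar foci dissolve at exponentially
#' distributed ground-truth times, while the cells optionally elongate
#' (cephalexin-like, no division) or undergo a single division event with a
#' configurable fluorescence asymmetry.  Total fluorescence is conserved:
#' when a focus dissolves its photons return to the cytoplasm (scaled by
#' \code{intensityDrop}), and daughter copy numbers sum exactly to the
#' mother's.
#'
#' @param config a \linkS4class{SimConfig} (\code{nFrames}, \code{frameInterval}
#'   in seconds, noise toggle, seed).
#' @param mode one of \code{"dissolution"}, \code{"elongation"},
#'   \code{"division"}.
#' @param truth table from \code{\link{makeCellTruth}} (one lineage per row);
#'   in division/elongation modes slot sizes must accommodate growth, so
#'   generate it with a suitably large \code{marginPx}.
#' @param camera a \linkS4class{CameraModel}.
#' @param focusLifespanMeanH mean of the exponential focus lifespan (hours);
#'   ignored when \code{truth$focus_death_frame} is present.
#' @param growthRate elongation rate in um/h (elongation and division modes);
#'   must be > 0 in elongation mode.
#' @param divisionFrame frame index (1-based) at which division-mode cells
#'   divide.
#' @param asymmetry fraction of the mother's fluorescence inherited by
#'   daughter 1 (division mode).
#' @param intensityDrop factor applied to a cell's total fluorescence at the
#'   dissolution event (1 = photon conserving).
#' @return list with \code{movie} (array rows x cols x frames), \code{masks}
#'   (integer label array; daughters get new cell ids), \code{cells}
#'   (per-frame truth: frame, cell_id, lineage_id, parent_id, geometry, copy
#'   number, focus flags), \code{events} (lineage_id, type, frame),
#'   \code{truth}, \code{config}, \code{camera}.
#' @export
simulateTimelapse <- function(config, mode = c("dissolution", "elongation",
                                               "division"),
                              truth, camera = CameraModel(),
                              focusLifespanMeanH = 1.4, growthRate = 0.4,
                              divisionFrame = NULL, asymmetry = 0.5,
                              intensityDrop = 1) {
  mode <- match.arg(mode)
  stopifnot(is(config, "SimConfig"))
  if (mode == "elongation" && growthRate <= 0)
    stop("elongation mode requires a positive growth rate")
  .withSeed(config@seed)
  nT <- config@nFrames
  dtH <- config@frameInterval / 3600
  dims <- attr(truth, "fieldDim")
  n <- nrow(truth)
  if (is.null(truth$focus_death_frame)) {
    life <- stats::rexp(n, rate = 1 / focusLifespanMeanH)
    # focus present on frames 1 .. deathFrame-1 (first frame is t = 0)
    truth$focus_death_frame <- ifelse(truth$focus_present,
                                      2 + floor(life / dtH), NA_integer_)
  }
  if (mode == "division" && is.null(divisionFrame))
    divisionFrame <- max(2L, nT %/% 2L)

  movie <- array(0, c(dims[1], dims[2], nT))
  masks <- array(0L, c(dims[1], dims[2], nT))
  cells <- list(); events <- list()
  nextId <- max(truth$cell_id) + 1L

  if (is.null(truth$parent_id)) truth$parent_id <- NA_integer_
  for (t in seq_len(nT)) {
    tt <- truth
    tH <- (t - 1) * dtH
    if (mode %in% c("elongation", "division"))
      tt$length_um <- truth$length_um + growthRate * tH
    # focus dissolution
    dies <- !is.na(tt$focus_death_frame) & t >= tt$focus_death_frame
    newDeath <- !is.na(tt$focus_death_frame) & t == tt$focus_death_frame
    for (i in which(newDeath))
      events[[length(events) + 1L]] <- data.frame(
        lineage_id = tt$lineage_id[i], type = "dissolution", frame = t)
    tt$focus_present <- tt$focus_present & !dies
    tt$partition_ratio[!tt$focus_present] <- 1
    tt$copy_number <- ifelse(dies, truth$copy_number * intensityDrop,
                             truth$copy_number)
    if (mode == "division" && t >= divisionFrame) {
      tt <- .divideCells(tt, asymmetry, nextId, camera@pixelSize)
      if (t == divisionFrame) {
        nextId <- max(tt$cell_id) + 1L
        for (l in unique(truth$lineage_id))
          events[[length(events) + 1L]] <- data.frame(
            lineage_id = l, type = "division", frame = t)
      }
    }
    fr <- .renderPhotonField(tt, dims, config, camera)
    movie[, , t] <- .applyCamera(fr$photons, camera, config@noise)
    masks[, , t] <- fr$mask
    tt$frame <- t
    cells[[t]] <- tt
  }
  cells <- do.call(rbind, cells)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(lineage_id = integer(), type = character(), frame = integer())
  list(movie = movie, masks = masks, cells = cells, events = events,
       truth = truth, config = config, camera = camera)
}

# Split every cell of a truth table into two daughters placed end to end
# along the mother's axis; daughter 1 receives `asymmetry` of the
# fluorescence (and proportional length).  The focus, if alive, goes to
# daughter 1 (the pole daughter).
.divideCells <- function(tt, asymmetry, nextId, p) {
  out <- list()
  for (i in seq_len(nrow(tt))) {
    m <- tt[i, ]
    l1 <- m$length_um * asymmetry
    l2 <- m$length_um * (1 - asymmetry)
    ur <- sin(m$theta); uc <- cos(m$theta)
    gapPx <- 1.5
    d1 <- m; d1$length_um <- max(l1 - 0.05, m$width_um)
    d2 <- m; d2$length_um <- max(l2 - 0.05, m$width_um)
    # place daughters so they tile the mother with a small gap
    d1$row_px <- m$row_px + (m$length_um - l1) / 2 / p * ur + gapPx / 2 * ur
    d1$col_px <- m$col_px + (m$length_um - l1) / 2 / p * uc + gapPx / 2 * uc
    d2$row_px <- m$row_px - (m$length_um - l2) / 2 / p * ur - gapPx / 2 * ur
    d2$col_px <- m$col_px - (m$length_um - l2) / 2 / p * uc - gapPx / 2 * uc
    d1$copy_number <- m$copy_number * asymmetry
    d2$copy_number <- m$copy_number * (1 - asymmetry)
    d2$cell_id <- nextId; nextId <- nextId + 1L
    d1$parent_id <- m$cell_id; d2$parent_id <- m$cell_id
    d2$focus_present <- FALSE
    d2$partition_ratio <- 1
    out[[length(out) + 1L]] <- rbind(d1, d2)
  }
  do.call(rbind, out)
}

## ---- Brownian tracks -----------------------------------------------------

#' Simulate motion-blurred Brownian trajectories
#'
#' Draws each track's diffusion coefficient from a mixture of components,
#' simulates Brownian motion at \code{nSubsteps} positions per frame, and
#' reports per-frame positions as the within-frame mean of those positions
#' (camera motion blur) plus Gaussian localization noise.
#'
#' @param Dcomponents data.frame or matrix with columns \code{D} (um^2/s)
#'   and \code{weight} (summing to 1).
#' @param nTracks number of trajectories.
#' @param nSteps number of frames per trajectory.
#' @param frameTime frame time in seconds.
#' @param nSubsteps sub-frame positions averaged per frame (>= 1; 1 means
#'   no blur).
#' @param locSd localization noise sd in um.
#' @param seed optional RNG seed.
#' @return list with \code{tracks} (track_id, frame, x_um, y_um) and
#'   \code{truth} (track_id, component, D).
#' @export
simulateBrownianTracks <- function(Dcomponents, nTracks, nSteps,
                                   frameTime = 0.04, nSubsteps = 1,
                                   locSd = 0, seed = NULL) {
  Dc <- as.data.frame(Dcomponents)
  stopifnot(all(c("D", "weight") %in% names(Dc)))
  if (any(Dc$D < 0)) stop("diffusion coefficients must be >= 0")
  if (abs(sum(Dc$weight) - 1) > 1e-8) stop("component weights must sum to 1")
  stopifnot(nSubsteps >= 1)
  .withSeed(seed)
  comp <- sample.int(nrow(Dc), nTracks, replace = TRUE, prob = Dc$weight)
  dtSub <- frameTime / nSubsteps
  nSub <- nSteps * nSubsteps
  stepSd <- sqrt(2 * Dc$D[comp] * dtSub)
  # one column per track; first substep position is the origin
  simAxis <- function() {
    inc <- matrix(stats::rnorm((nSub - 1) * nTracks), nSub - 1, nTracks)
    inc <- sweep(inc, 2, stepSd, `*`)
    pos <- rbind(0, apply(inc, 2, cumsum))
    grp <- rep(seq_len(nSteps), each = nSubsteps)
    frame <- rowsum(pos, grp) / nSubsteps
    if (locSd > 0)
      frame <- frame + matrix(stats::rnorm(nSteps * nTracks, 0, locSd),
                              nSteps, nTracks)
    frame
  }
  fx <- simAxis(); fy <- simAxis()
  list(tracks = data.frame(track_id = rep(seq_len(nTracks), each = nSteps),
                           frame = rep(seq_len(nSteps), nTracks),
                           x_um = as.vector(fx), y_um = as.vector(fy)),
       truth = data.frame(track_id = seq_len(nTracks), component = comp,
                          D = Dc$D[comp]))
}

## ---- calibration series --------------------------------------------------

#' Simulate a camera gain calibration series
#'
#' Emulates the two standard EMCCD calibrations: (i) flat-field frame pairs
#' at increasing exposure (Poisson photoelectron statistics, no EM gain)
#' for the mean-variance conversion-gain fit, and (ii) per-nominal-gain
#' image pairs (long exposure without EM gain, short exposure with EM gain)
#' for the EM-gain factor fit, plus bias frames.
#'
#' @param camera a \linkS4class{CameraModel} holding the ground-truth gains.
#' @param exposures flat-field exposure times in ms.
#' @param nominalEmGains nominal EM gain settings for the EM series.
#' @param photonFluxPerMs mean photons per pixel per ms of exposure.
#' @param dims frame dimensions.
#' @param nBias number of bias frames.
#' @param longExposure,shortExposure EM-series exposures in ms.
#' @param emFlux photons per pixel per ms for the EM series.
#' @param noise logical; FALSE renders every frame at its exact expectation.
#' @param seed optional RNG seed.
#' @return list with \code{flatfield} (per exposure: list of two count
#'   matrices), \code{exposures}, \code{bias} (list of matrices), \code{em}
#'   (per nominal gain: \code{noEm}, \code{em} matrices and their
#'   exposures), \code{nominalEmGains}, \code{camera}.
#' @export
simulateCalibrationSeries <- function(camera = CameraModel(),
                                      exposures = c(10, 20, 40, 80, 160, 320),
                                      nominalEmGains = c(5, 50, 100, 300, 600),
                                      photonFluxPerMs = 20, dims = c(64, 64),
                                      nBias = 10, longExposure = 1000,
                                      shortExposure = 10, emFlux = 2,
                                      noise = TRUE, seed = NULL) {
  if (length(exposures) == 0L) stop("need at least one exposure time")
  .withSeed(seed)
  g <- camera@conversionGain; f <- camera@emGainFactor
  bias <- camera@biasCounts
  npx <- prod(dims)
  draw <- function(lambda, M = 1) {
    pe <- if (noise) stats::rpois(npx, lambda) else rep(lambda, npx)
    counts <- pe * M / g + bias
    if (noise && camera@readNoiseSD > 0)
      counts <- counts + stats::rnorm(npx, 0, camera@readNoiseSD)
    matrix(counts, dims[1], dims[2])
  }
  flat <- lapply(exposures, function(e)
    list(draw(photonFluxPerMs * e), draw(photonFluxPerMs * e)))
  names(flat) <- as.character(exposures)
  biasFrames <- lapply(seq_len(nBias), function(i) draw(0))
  em <- lapply(nominalEmGains, function(G) list(
    noEm = draw(emFlux * longExposure, M = 1),
    em = draw(emFlux * shortExposure, M = G * f),
    exposureNoEm = longExposure, exposureEm = shortExposure,
    nominalGain = G))
  names(em) <- as.character(nominalEmGains)
  list(flatfield = flat, exposures = exposures, bias = biasFrames, em = em,
       nominalEmGains = nominalEmGains, camera = camera)
}

## ---- two-channel colocalization ------------------------------------------

#' Simulate a two-channel chaperone colocalization image pair
#'
#' Channel 1 carries reference (mCherry-like) Gaussian foci; channel 2
#' carries the probe (IbpA-like) signal arranged per pattern: a ring around
#' each focus (\code{rosette}), a narrower spot inside it (\code{punctate}),
#' or a spot of matched width and amplitude (\code{amorphous}).
#'
#' @param pattern \code{"rosette"}, \code{"punctate"} or \code{"amorphous"}.
#' @param nFoci number of foci.
#' @param camera a \linkS4class{CameraModel}.
#' @param refSigmaPx reference focus Gaussian sd (px).
#' @param refAmplitude reference peak photons above background.
#' @param probeRelAmp probe peak amplitude relative to the reference peak
#'   (ignored for \code{amorphous}, which uses 1).
#' @param ringRadiusFactor rosette ring radius as a multiple of
#'   \code{refSigmaPx}.
#' @param ringSigmaPx rosette ring thickness sd (px).
#' @param punctateFactor probe sd as a fraction of the reference sd for the
#'   punctate pattern.
#' @param background background photons per pixel.
#' @param noise logical camera noise toggle.
#' @param seed optional RNG seed.
#' @return list with \code{ref} and \code{probe} count matrices and
#'   \code{truth} (focus_id, row_px, col_px, pattern, expected_regime,
#'   rel_amplitude).
#' @export
simulateColocPair <- function(pattern = c("rosette", "punctate", "amorphous"),
                              nFoci = 9, camera = CameraModel(),
                              refSigmaPx = 2, refAmplitude = 2000,
                              probeRelAmp = 0.5, ringRadiusFactor = 3,
                              ringSigmaPx = 1.5, punctateFactor = 0.5,
                              background = 20, noise = TRUE, seed = NULL) {
  pattern <- match.arg(pattern)
  .withSeed(seed)
  slot <- 2 * (ceiling(ringRadiusFactor * refSigmaPx) + 16) + 1
  ncols <- ceiling(sqrt(nFoci)); nrows <- ceiling(nFoci / ncols)
  dims <- c(nrows * slot, ncols * slot)
  refPh <- matrix(background, dims[1], dims[2])
  prPh <- matrix(background, dims[1], dims[2])
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  truth <- list()
  if (pattern == "amorphous") probeRelAmp <- 1
  for (i in seq_len(nFoci)) {
    r0 <- ((i - 1) %/% ncols) * slot + (slot + 1) / 2 + stats::runif(1, -.5, .5)
    c0 <- ((i - 1) %% ncols) * slot + (slot + 1) / 2 + stats::runif(1, -.5, .5)
    d <- sqrt((rows - r0)^2 + (cols - c0)^2)
    refPh <- refPh + refAmplitude * exp(-d^2 / (2 * refSigmaPx^2))
    probe <- switch(pattern,
      rosette = probeRelAmp * refAmplitude *
        exp(-(d - ringRadiusFactor * refSigmaPx)^2 / (2 * ringSigmaPx^2)),
      punctate = probeRelAmp * refAmplitude *
        exp(-d^2 / (2 * (punctateFactor * refSigmaPx)^2)),
      amorphous = refAmplitude * exp(-d^2 / (2 * refSigmaPx^2)))
    prPh <- prPh + probe
    truth[[i]] <- data.frame(
      focus_id = i, row_px = r0, col_px = c0, pattern = pattern,
      expected_regime = switch(pattern, rosette = ">1", punctate = "<1",
                               amorphous = "~1"),
      rel_amplitude = probeRelAmp)
  }
  list(ref = .applyCamera(refPh, camera, noise),
       probe = .applyCamera(prPh, camera, noise),
       truth = do.call(rbind, truth), camera = camera)
}

## ---- single-molecule movie rendering -------------------------------------

#' Render point emitters into camera frames
#'
#' Draws each localization as an isotropic Gaussian point-spread function
#' carrying a fixed number of photons, on a flat background, and digitizes
#' the result through the camera model.  Used to turn simulated Brownian
#' trajectories into single-molecule movies.
#'
#' @param positions data.frame with \code{frame}, \code{row_px},
#'   \code{col_px} (or \code{x_um}, \code{y_um}, converted via the camera
#'   pixel size).
#' @param dims frame dimensions (rows, cols).
#' @param camera a \linkS4class{CameraModel}.
#' @param psfSigmaPx PSF sd in pixels.
#' @param photonsPerFrame photons emitted per emitter per frame.
#' @param background background photons per pixel.
#' @param noise logical camera noise toggle.
#' @param seed optional RNG seed.
#' @return numeric array (rows x cols x frames) of counts.
#' @export
renderEmitterFrames <- function(positions, dims, camera = CameraModel(),
                                psfSigmaPx = 1.6, photonsPerFrame = 500,
                                background = 5, noise = TRUE, seed = NULL) {
  .withSeed(seed)
  if (!all(c("row_px", "col_px") %in% names(positions))) {
    positions$row_px <- positions$y_um / camera@pixelSize
    positions$col_px <- positions$x_um / camera@pixelSize
  }
  nT <- if (nrow(positions)) max(positions$frame) else 1L
  out <- array(0, c(dims[1], dims[2], nT))
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  peak <- photonsPerFrame / (2 * pi * psfSigmaPx^2)
  for (t in seq_len(nT)) {
    ph <- matrix(background, dims[1], dims[2])
    sel <- which(positions$frame == t)
    for (i in sel) {
      d2 <- (rows - positions$row_px[i])^2 + (cols - positions$col_px[i])^2
      ph <- ph + peak * exp(-d2 / (2 * psfSigmaPx^2))
    }
    out[, , t] <- .applyCamera(ph, camera, noise)
  }
  out
}
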