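# Single-molecule localization and tracking: 2D Gaussian localization,
# Hungarian-assignment linking, time-averaged MSD curves, motion-blur-aware
# diffusion fitting, two-state log-D mixture modelling and normalized-cell
# localization heat maps.

# Isotropic 2D Gaussian + offset least-squares fit on a small patch.
# Returns NULL when the optimizer fails.
.fitGaussianSpot <- function(patch) {
  nr <- nrow(patch); nc <- ncol(patch)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  off0 <- min(patch); amp0 <- max(patch) - off0
  w <- pmax(patch - off0, 0)
  r0 <- sum(rows * w) / sum(w); c0 <- sum(cols * w) / sum(w)
  s0 <- sqrt(max((sum(((rows - r0)^2 + (cols - c0)^2) * w) / sum(w)) / 2, 0.25))
  res <- function(p) {
    model <- p[5] + p[1] * exp(-((rows - p[2])^2 + (cols - p[3])^2) /
                                 (2 * p[4]^2))
    as.vector(model - patch)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(amp0, r0, c0, s0, off0), fn = res,
                       lower = c(0, 1, 1, 0.5, -Inf),
                       upper = c(Inf, nr, nc, nr, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  if (p[1] <= 0 || p[4] <= 0) return(NULL)
  ss <- sum(res(p)^2); st <- sum((patch - mean(patch))^2)
  list(amplitude = p[1], row = p[2], col = p[3], sigma = abs(p[4]),
       offset = p[5], integrated = 2 * pi * p[1] * p[4]^2,
       r2 = if (st > 0) 1 - ss / st else NA_real_)
}

#' Detect and localize isolated single molecules
#'
#' Candidate emitters are strict local maxima of a lightly smoothed frame
#' above a robust noise threshold; emitters closer together than
#' \code{minSeparation} are both discarded.  Each survivor is localized by
#' least-squares fitting of an isotropic 2D Gaussian with a local offset,
#' and its integrated intensity counts are converted to photons via the
#' camera calibration.
#'
#' @param frames numeric matrix or array (rows x cols x frames).
#' @param camera a \linkS4class{CameraModel}.
#' @param minSeparation minimum emitter separation in px.
#' @param thresholdSd detection threshold in robust noise sds above the
#'   frame median.
#' @param patchRadius half-size of the fitting patch in px.
#' @return data.frame with \code{frame}, \code{row_px}, \code{col_px},
#'   \code{x_um}, \code{y_um}, \code{photons}, \code{amplitude},
#'   \code{sigma_px}, \code{fit_r2}.  The number of detections discarded
#'   for crowding is in attribute \code{"discarded_crowded"}.
#' @export
detectAndLocalize <- function(frames, camera = CameraModel(),
                              minSeparation = 5, thresholdSd = 5,
                              patchRadius = 5) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1))
  nT <- dim(frames)[3]
  out <- list(); nCrowded <- 0L
  for (t in seq_len(nT)) {
    img <- frames[, , t]
    sm <- .convolve2(img, .gaussKernel(1))
    bg <- stats::median(sm)
    noise <- stats::mad(sm)
    mx <- .localMaxima(sm)
    if (nrow(mx) == 0L) next
    keep <- sm[mx] > bg + thresholdSd * noise
    mx <- mx[keep, , drop = FALSE]
    if (nrow(mx) == 0L) next
    if (nrow(mx) > 1L) {
      d <- as.matrix(stats::dist(mx))
      diag(d) <- Inf
      crowded <- apply(d < minSeparation, 1, any)
      nCrowded <- nCrowded + sum(crowded)
      mx <- mx[!crowded, , drop = FALSE]
    }
    for (i in seq_len(nrow(mx))) {
      r <- mx[i, 1]; c <- mx[i, 2]
      if (r - patchRadius < 1 || r + patchRadius > nrow(img) ||
          c - patchRadius < 1 || c + patchRadius > ncol(img)) next
      patch <- img[(r - patchRadius):(r + patchRadius),
                   (c - patchRadius):(c + patchRadius)]
      fit <- .fitGaussianSpot(patch)
      if (is.null(fit)) next
      rowPx <- r - patchRadius - 1 + fit$row
      colPx <- c - patchRadius - 1 + fit$col
      out[[length(out) + 1L]] <- data.frame(
        frame = t, row_px = rowPx, col_px = colPx,
        x_um = colPx * camera@pixelSize, y_um = rowPx * camera@pixelSize,
        photons = countsToPhotons(fit$integrated, camera = camera),
        amplitude = fit$amplitude, sigma_px = fit$sigma, fit_r2 = fit$r2)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(), row_px = numeric(), col_px = numeric(),
               x_um = numeric(), y_um = numeric(), photons = numeric(),
               amplitude = numeric(), sigma_px = numeric(),
               fit_r2 = numeric())
  attr(res, "discarded_crowded") <- nCrowded
  res
}

#' Link localizations into trajectories
#'
#' Frame-pair minimum-cost assignment (Hungarian algorithm on squared
#' displacements) with a hard step cap and no gap closing: a molecule that
#' disappears terminates its trajectory.
#'
#' @param locs data.frame with \code{frame}, \code{x_um}, \code{y_um}.
#' @param maxStep maximum frame-to-frame displacement in um.
#' @return \code{locs} with a \code{track_id} column, ordered by track and
#'   frame.
#' @export
linkLocalizations <- function(locs, maxStep = 0.8) {
  if (nrow(locs) == 0L) {
    locs$track_id <- integer(0)
    return(locs)
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  locs$track_id <- NA_integer_
  frames <- sort(unique(locs$frame))
  prevIdx <- which(locs$frame == frames[1])
  locs$track_id[prevIdx] <- seq_along(prevIdx)
  nextTrack <- length(prevIdx) + 1L
  for (fi in seq_along(frames)[-1]) {
    curIdx <- which(locs$frame == frames[fi])
    if (length(prevIdx) && frames[fi] == frames[fi - 1] + 1) {
      m <- .gatedMatch(cbind(locs$x_um[prevIdx], locs$y_um[prevIdx]),
                       cbind(locs$x_um[curIdx], locs$y_um[curIdx]), maxStep)
      for (i in seq_along(prevIdx))
        if (!is.na(m[i]))
          locs$track_id[curIdx[m[i]]] <- locs$track_id[prevIdx[i]]
    }
    new <- curIdx[is.na(locs$track_id[curIdx])]
    if (length(new)) {
      locs$track_id[new] <- seq.int(nextTrack, length.out = length(new))
      nextTrack <- nextTrack + length(new)
    }
    prevIdx <- curIdx
  }
  locs[order(locs$track_id, locs$frame), , drop = FALSE]
}

#' Time-averaged mean-square-displacement curve of one trajectory
#'
#' MSD at each lag is averaged over all (overlapping) ordered position
#' pairs at that lag.  Trajectories with fewer than \code{minSteps}
#' displacements are rejected.
#'
#' @param traj data.frame with \code{frame}, \code{x_um}, \code{y_um} for
#'   one trajectory.
#' @param frameTime frame time in seconds.
#' @param minSteps minimum number of displacements.
#' @param maxLag largest lag (frames) to evaluate; defaults to the track
#'   length minus one.
#' @return data.frame with \code{lag}, \code{tau} (s), \code{msd} (um^2),
#'   \code{n} pairs per lag.
#' @export
msdCurve <- function(traj, frameTime = 0.04, minSteps = 6, maxLag = NULL) {
  traj <- traj[order(traj$frame), , drop = FALSE]
  nSteps <- nrow(traj) - 1L
  if (nSteps < minSteps)
    stop("trajectory has ", nSteps, " steps; at least ", minSteps,
         " required")
  if (is.null(maxLag)) maxLag <- nSteps
  # positions must be consecutive frames for a simple lag structure
  stopifnot(all(diff(traj$frame) == 1))
  x <- traj$x_um; y <- traj$y_um
  lags <- seq_len(min(maxLag, nSteps))
  msd <- vapply(lags, function(l) {
    dx <- x[-seq_len(l)] - x[seq_len(length(x) - l)]
    dy <- y[-seq_len(l)] - y[seq_len(length(y) - l)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  n <- vapply(lags, function(l) length(x) - l, numeric(1))
  data.frame(lag = lags, tau = lags * frameTime, msd = msd, n = n)
}

#' Fit the motion-blur diffusion model to an MSD curve
#'
#' Ordinary least squares of MSD on tau over the fit range, interpreted
#' under the blurred-acquisition model MSD = (8/3) D_app tau + 4 sigma^2:
#' D_app = slope * 3/8 and sigma = sqrt(intercept / 4).  Fits with
#' R^2 below \code{r2Min} or a non-positive slope are rejected; a negative
#' intercept yields sigma = 0 with a flag.
#'
#' @param msd data.frame from \code{\link{msdCurve}}.
#' @param fitRange numeric length-2, tau window in seconds (inclusive).
#' @param r2Min acceptance threshold on R^2.
#' @return a \linkS4class{DiffusionFit}.
#' @examples
#' msd <- data.frame(lag = 1:5, tau = (1:5) * 0.04,
#'                   msd = (8 / 3) * 1.0 * (1:5) * 0.04 + 4 * 0.02^2, n = 10)
#' fitDiffusion(msd)
#' @export
fitDiffusion <- function(msd, fitRange = c(0.04, 0.2), r2Min = 0.7) {
  sel <- msd$tau >= fitRange[1] - 1e-12 & msd$tau <= fitRange[2] + 1e-12
  if (sum(sel) < 2) stop("need at least two lags inside the fit range")
  fit <- stats::lm(msd ~ tau, data = msd[sel, ])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  sst <- sum((msd$msd[sel] - mean(msd$msd[sel]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  flags <- character()
  Dapp <- slope * 3 / 8
  if (slope <= 0) flags <- c(flags, "negative_slope")
  if (intercept < 0) {
    sigma <- 0
    flags <- c(flags, "negative_intercept")
  } else sigma <- sqrt(intercept / 4)
  new("DiffusionFit", Dapp = Dapp, sigma = sigma, r2 = r2,
      accepted = (r2 >= r2Min) && slope > 0, flags = flags)
}

#' Two-state Gaussian mixture fit of log10 diffusion coefficients
#'
#' Expectation-maximization with deterministic initialization (component
#' means at the 25th and 75th sample percentiles, equal weights and a
#' common sd), so repeated fits of the same data agree exactly.  Components
#' are reported sorted slow then fast.
#'
#' @param logD numeric vector of log10 apparent diffusion coefficients.
#' @param maxIter maximum EM iterations.
#' @param tol convergence tolerance on the log-likelihood.
#' @return a \linkS4class{MixtureFit}; the per-iteration log-likelihood
#'   trace is in attribute \code{"logLikTrace"}.
#' @export
fitLogDMixture <- function(logD, maxIter = 500, tol = 1e-8) {
  x <- logD[is.finite(logD)]
  if (length(x) < 20) stop("need at least 20 values for a mixture fit")
  mu <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (mu[1] == mu[2]) mu[2] <- mu[2] + stats::sd(x) / 2 + 1e-6
  sd2 <- rep(max(stats::sd(x) / 2, 1e-4), 2)
  w <- c(0.5, 0.5)
  trace <- numeric(0)
  llOld <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd2[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd2[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(llOld) && ll - llOld < tol && ll >= llOld) {
      converged <- TRUE
      break
    }
    llOld <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sd2 <- sqrt(pmax(c(sum(g1 * (x - mu[1])^2) / n1,
                       sum((1 - g1) * (x - mu[2])^2) / n2), 1e-8))
    w <- c(n1, n2) / length(x)
  }
  ord <- order(mu)
  flags <- character()
  if (!converged) flags <- c(flags, "not_converged")
  if (min(w) < 0.02 || abs(mu[1] - mu[2]) < 1e-3)
    flags <- c(flags, "degenerate")
  # a two-component fit of a genuinely unimodal sample splits it into two
  # overlapping halves; compare against the single-Gaussian fit by BIC and
  # flag when one component suffices
  ll1 <- sum(stats::dnorm(x, mean(x),
                          stats::sd(x) * sqrt((length(x) - 1) / length(x)),
                          log = TRUE))
  bic2 <- -2 * trace[length(trace)] + 5 * log(length(x))
  bic1 <- -2 * ll1 + 2 * log(length(x))
  if (bic1 <= bic2) flags <- unique(c(flags, "degenerate"))
  out <- new("MixtureFit", means = mu[ord], sds = sd2[ord],
             weights = w[ord] / sum(w), logLik = trace[length(trace)],
             iterations = it, converged = converged, flags = flags)
  attr(out, "logLikTrace") <- trace
  out
}

#' Localization heat map on the normalized cell
#'
#' Maps each localization into its cell's normalized frame (long axis and
#' short axis each scaled to [-1, 1]), bins the coordinates, averages over
#' the four-fold quadrant symmetrization, and normalizes the histogram to
#' unit mass.  Cells without a defined long axis (length equal to width)
#' are skipped with a warning.
#'
#' @param locs data.frame with \code{cell_id}, \code{row_px}, \code{col_px}.
#' @param cells data.frame with \code{cell_id}, \code{row_px}, \code{col_px}
#'   (centre), \code{theta}, \code{length_um}, \code{width_um}.
#' @param bins integer length-2: bins along the long and short axis.
#' @param pixelSize um per pixel.
#' @return numeric matrix (short-axis bins x long-axis bins) summing to 1,
#'   with the localization count used in attribute \code{"n"}.
#' @export
localizationHeatmap <- function(locs, cells, bins = c(40, 20),
                                pixelSize = 0.066) {
  h <- matrix(0, bins[2], bins[1])
  n <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    if (cell$length_um <= cell$width_um) {
      skipped <- skipped + 1L
      next
    }
    sel <- locs$cell_id == cell$cell_id
    if (!any(sel)) next
    dr <- (locs$row_px[sel] - cell$row_px) * pixelSize
    dc <- (locs$col_px[sel] - cell$col_px) * pixelSize
    u <- dc * cos(cell$theta) + dr * sin(cell$theta)
    v <- -dc * sin(cell$theta) + dr * cos(cell$theta)
    lu <- u / (cell$length_um / 2)
    lv <- v / (cell$width_um / 2)
    ok <- abs(lu) <= 1 & abs(lv) <= 1
    bu <- pmin(pmax(ceiling((lu[ok] + 1) / 2 * bins[1]), 1), bins[1])
    bv <- pmin(pmax(ceiling((lv[ok] + 1) / 2 * bins[2]), 1), bins[2])
    for (k in seq_along(bu)) h[bv[k], bu[k]] <- h[bv[k], bu[k]] + 1
    n <- n + sum(ok)
  }
  if (skipped) warning(skipped, " cell(s) without a defined long axis ",
                       "skipped")
  if (n == 0L) stop("no localizations fell inside any cell")
  h <- (h + h[bins[2]:1, ] + h[, bins[1]:1] + h[bins[2]:1, bins[1]:1]) / 4
  h / sum(h)
}
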