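#' Camera model for an EMCCD detector
#'
#' Describes the forward model of the camera used to digitize fluorescence:
#' photoelectrons are generated by Poisson statistics, multiplied by the
#' realized EM gain (nominal software gain times the EM-gain conversion
#' factor), divided by the conversion gain (electrons per intensity count),
#' and offset by a bias with additive Gaussian read noise.
#'
#' @slot biasCounts numeric, camera bias offset in intensity counts.
#' @slot readNoiseSD numeric, Gaussian read noise standard deviation (counts).
#' @slot conversionGain numeric, electrons per intensity count (> 0).
#' @slot emGainFactor numeric, realized EM gain per unit nominal gain (> 0).
#' @slot nominalEmGain numeric, software EM gain setting used for imaging.
#' @slot pixelSize numeric, micrometres per pixel (> 0).
#'
#' @export
setClass("CameraModel",
  representation(
    biasCounts     = "numeric",
    readNoiseSD    = "numeric",
    conversionGain = "numeric",
    emGainFactor   = "numeric",
    nominalEmGain  = "numeric",
    pixelSize      = "numeric"
  ),
  prototype(
    biasCounts     = 100,
    readNoiseSD    = 2,
    conversionGain = 1.40,
    emGainFactor   = 0.15,
    nominalEmGain  = 10,
    pixelSize      = 0.066
  )
)

setValidity("CameraModel", function(object) {
  msg <- NULL
  if (object@conversionGain <= 0) msg <- c(msg, "conversionGain must be > 0")
  if (object@emGainFactor <= 0)   msg <- c(msg, "emGainFactor must be > 0")
  if (object@pixelSize <= 0)      msg <- c(msg, "pixelSize must be > 0")
  if (object@biasCounts < 0)      msg <- c(msg, "biasCounts must be >= 0")
  if (object@readNoiseSD < 0)     msg <- c(msg, "readNoiseSD must be >= 0")
  if (object@nominalEmGain <= 0)  msg <- c(msg, "nominalEmGain must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CameraModel
#'
#' @param biasCounts bias offset in counts.
#' @param readNoiseSD read noise sd in counts.
#' @param conversionGain electrons per intensity count.
#' @param emGainFactor realized EM gain per nominal gain unit.
#' @param nominalEmGain software EM gain setting.
#' @param pixelSize micrometres per pixel.
#' @return A \linkS4class{CameraModel}.
#' @examples
#' cam <- CameraModel()
#' conversionGain(cam)
#' @export
CameraModel <- function(biasCounts = 100, readNoiseSD = 2,
                        conversionGain = 1.40, emGainFactor = 0.15,
                        nominalEmGain = 10, pixelSize = 0.066) {
  new("CameraModel", biasCounts = biasCounts, readNoiseSD = readNoiseSD,
      conversionGain = conversionGain, emGainFactor = emGainFactor,
      nominalEmGain = nominalEmGain, pixelSize = pixelSize)
}

#' Simulation configuration
#'
#' Holds the acquisition parameters shared by the synthetic-microscopy
#' generators.  With \code{noise = FALSE} all stochastic camera stages
#' (shot noise, read noise) are disabled and rendering is deterministic
#' given the truth table.
#'
#' @slot frameInterval numeric, time between frames in seconds.
#' @slot exposure numeric, exposure time in milliseconds.
#' @slot nFrames integer, number of frames to render.
#' @slot nSubsteps integer, sub-frame displacement steps used to emulate
#'   motion blur (>= 1).
#' @slot seed integer or NA, RNG seed recorded with every output.
#' @slot noise logical, master toggle for shot and read noise.
#' @slot photonsPerMolecule numeric, photons emitted per fluorophore per
#'   frame (the single-molecule brightness the photon-counting pipeline
#'   later estimates).
#' @slot psfSigmaPx numeric, isotropic Gaussian PSF sd in pixels.
#' @slot backgroundPhotons numeric, out-of-cell photon level per pixel.
#'
#' @export
setClass("SimConfig",
  representation(
    frameInterval      = "numeric",
    exposure           = "numeric",
    nFrames            = "integer",
    nSubsteps          = "integer",
    seed               = "integer",
    noise              = "logical",
    photonsPerMolecule = "numeric",
    psfSigmaPx         = "numeric",
    backgroundPhotons  = "numeric"
  ),
  prototype(
    frameInterval      = 900,
    exposure           = 20,
    nFrames            = 1L,
    nSubsteps          = 1L,
    seed               = NA_integer_,
    noise              = TRUE,
    photonsPerMolecule = 90,
    psfSigmaPx         = 1.6,
    backgroundPhotons  = 20
  )
)

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@nSubsteps < 1L)     msg <- c(msg, "nSubsteps must be >= 1")
  if (object@nFrames < 1L)       msg <- c(msg, "nFrames must be >= 1")
  if (object@photonsPerMolecule < 0)
    msg <- c(msg, "photonsPerMolecule must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SimConfig
#'
#' @param frameInterval seconds between frames.
#' @param exposure exposure in ms.
#' @param nFrames number of frames.
#' @param nSubsteps sub-frame steps for motion blur.
#' @param seed RNG seed (NA to use the current RNG state).
#' @param noise logical, enable camera noise.
#' @param photonsPerMolecule photons per fluorophore per frame.
#' @param psfSigmaPx PSF sd in pixels.
#' @param backgroundPhotons background photon level per pixel.
#' @return A \linkS4class{SimConfig}.
#' @export
SimConfig <- function(frameInterval = 900, exposure = 20, nFrames = 1,
                      nSubsteps = 1, seed = NA, noise = TRUE,
                      photonsPerMolecule = 90, psfSigmaPx = 1.6,
                      backgroundPhotons = 20) {
  new("SimConfig", frameInterval = frameInterval, exposure = exposure,
      nFrames = as.integer(nFrames), nSubsteps = as.integer(nSubsteps),
      seed = as.integer(seed), noise = noise,
      photonsPerMolecule = photonsPerMolecule, psfSigmaPx = psfSigmaPx,
      backgroundPhotons = backgroundPhotons)
}

#' Camera gain calibration result
#'
#' @slot conversionGain fitted conversion gain (electrons per count).
#' @slot emGainFactor fitted EM-gain conversion factor.
#' @slot diagnostics list with fit details (R squared, residuals, points).
#' @export
setClass("GainCalibration",
  representation(conversionGain = "numeric", emGainFactor = "numeric",
                 diagnostics = "list"),
  prototype(conversionGain = NA_real_, emGainFactor = NA_real_,
            diagnostics = list())
)

#' Gamma fit to single-molecule photon counts
#'
#' @slot shape Gamma shape k.
#' @slot scale Gamma scale theta.
#' @slot mode distribution mode (k - 1) * theta; the "photons per molecule
#'   per frame" figure used by the concentration pipeline.
#' @slot method "mle" or "moments".
#' @slot flags character vector of quality flags.
#' @export
setClass("GammaFit",
  representation(shape = "numeric", scale = "numeric", mode = "numeric",
                 method = "character", flags = "character"),
  prototype(shape = NA_real_, scale = NA_real_, mode = NA_real_,
            method = "mle", flags = character())
)

#' Motion-blur-aware diffusion fit
#'
#' Parameters of the linear model MSD = (8/3) * D_app * tau + 4 * sigma^2
#' fitted to a trajectory's mean-square-displacement curve.
#'
#' @slot Dapp apparent diffusion coefficient (um^2/s).
#' @slot sigma localization precision term (um).
#' @slot r2 coefficient of determination of the linear fit.
#' @slot accepted logical, TRUE iff r2 >= the acceptance threshold and the
#'   slope is positive.
#' @slot flags character vector ("negative_intercept", "negative_slope").
#' @export
setClass("DiffusionFit",
  representation(Dapp = "numeric", sigma = "numeric", r2 = "numeric",
                 accepted = "logical", flags = "character"),
  prototype(Dapp = NA_real_, sigma = NA_real_, r2 = NA_real_,
            accepted = FALSE, flags = character())
)

#' Two-state Gaussian mixture fit of log10 diffusion coefficients
#'
#' @slot means component means (log10 um^2/s), sorted slow then fast.
#' @slot sds component standard deviations.
#' @slot weights component weights (sum to 1), same order.
#' @slot logLik final log-likelihood.
#' @slot iterations EM iterations used.
#' @slot converged logical.
#' @slot flags character vector ("degenerate" when one weight ~ 0).
#' @export
setClass("MixtureFit",
  representation(means = "numeric", sds = "numeric", weights = "numeric",
                 logLik = "numeric", iterations = "integer",
                 converged = "logical", flags = "character"),
  prototype(means = c(NA_real_, NA_real_), sds = c(NA_real_, NA_real_),
            weights = c(NA_real_, NA_real_), logLik = NA_real_,
            iterations = 0L, converged = FALSE, flags = character())
)

setValidity("MixtureFit", function(object) {
  msg <- NULL
  if (length(object@weights) == 2L && !anyNA(object@weights)) {
    if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
    if (abs(sum(object@weights) - 1) > 1e-6)
      msg <- c(msg, "weights must sum to 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Two-channel FWHM colocalization result
#'
#' @slot fwhmRef reference-channel FWHM in pixels.
#' @slot fwhmProbe probe-channel FWHM in pixels.
#' @slot ratio fwhmProbe / fwhmRef.
#' @slot relMaxPct probe maximum as percent of the reference maximum.
#' @slot fitRef list of 2D Gaussian parameters for the reference channel.
#' @slot fitProbe list of 2D Gaussian parameters for the probe channel.
#' @slot contourLevels amplitude fractions at which contour ellipses are
#'   reported.
#' @slot flags character vector ("probe_fit_poor" etc).
#' @export
setClass("FwhmResult",
  representation(fwhmRef = "numeric", fwhmProbe = "numeric", ratio = "numeric",
                 relMaxPct = "numeric", fitRef = "list", fitProbe = "list",
                 contourLevels = "numeric", flags = "character"),
  prototype(fwhmRef = NA_real_, fwhmProbe = NA_real_, ratio = NA_real_,
            relMaxPct = NA_real_, fitRef = list(), fitProbe = list(),
            contourLevels = c(0.25, 0.50, 0.75), flags = character())
)

## ---- accessors -----------------------------------------------------------

#' @describeIn CameraModel-class conversion gain accessor
#' @param object a CameraModel
#' @export
setGeneric("conversionGain", function(object) standardGeneric("conversionGain"))
#' @export
setMethod("conversionGain", "CameraModel", function(object) object@conversionGain)
#' @export
setMethod("conversionGain", "GainCalibration", function(object) object@conversionGain)

#' @describeIn CameraModel-class EM-gain factor accessor
#' @export
setGeneric("emGainFactor", function(object) standardGeneric("emGainFactor"))
#' @export
setMethod("emGainFactor", "CameraModel", function(object) object@emGainFactor)
#' @export
setMethod("emGainFactor", "GainCalibration", function(object) object@emGainFactor)

#' @describeIn CameraModel-class pixel size accessor (um/px)
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @export
setMethod("pixelSize", "CameraModel", function(object) object@pixelSize)

#' Apparent diffusion coefficient accessor
#' @param object a DiffusionFit
#' @export
setGeneric("Dapp", function(object) standardGeneric("Dapp"))
#' @export
setMethod("Dapp", "DiffusionFit", function(object) object@Dapp)

#' Mixture component weights accessor
#' @param object a MixtureFit
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))
#' @export
setMethod("mixtureWeights", "MixtureFit", function(object) {
  stats::setNames(object@weights, c("slow", "fast"))
})

#' Mixture component means accessor (log10 um^2/s)
#' @param object a MixtureFit
#' @export
setGeneric("mixtureMeans", function(object) standardGeneric("mixtureMeans"))
#' @export
setMethod("mixtureMeans", "MixtureFit", function(object) {
  stats::setNames(object@means, c("slow", "fast"))
})

#' FWHM ratio accessor
#' @param object a FwhmResult
#' @export
setGeneric("fwhmRatio", function(object) standardGeneric("fwhmRatio"))
#' @export
setMethod("fwhmRatio", "FwhmResult", function(object) object@ratio)

## ---- show methods --------------------------------------------------------

setMethod("show", "CameraModel", function(object) {
  cat("CameraModel\n",
      "  bias: ", object@biasCounts, " counts,  read noise sd: ",
      object@readNoiseSD, " counts\n",
      "  conversion gain: ", object@conversionGain, " e-/count\n",
      "  EM gain: nominal ", object@nominalEmGain, " x factor ",
      object@emGainFactor, "\n",
      "  pixel size: ", object@pixelSize, " um\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nFrames, " frame(s) @ ", object@frameInterval,
      " s, exposure ", object@exposure, " ms, ", object@nSubsteps,
      " substep(s), noise ", ifelse(object@noise, "on", "off"),
      ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "GainCalibration", function(object) {
  cat("GainCalibration\n  conversion gain: ",
      format(object@conversionGain, digits = 4), " e-/count\n",
      "  EM-gain factor: ", format(object@emGainFactor, digits = 4), "\n",
      sep = "")
})

setMethod("show", "GammaFit", function(object) {
  cat("GammaFit (", object@method, "): shape ",
      format(object@shape, digits = 4), ", scale ",
      format(object@scale, digits = 4), ", mode ",
      format(object@mode, digits = 4), " photons/molecule/frame\n", sep = "")
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

setMethod("show", "DiffusionFit", function(object) {
  cat("DiffusionFit: D_app ", format(object@Dapp, digits = 4),
      " um^2/s, sigma ", format(object@sigma, digits = 4),
      " um, R2 ", format(object@r2, digits = 3),
      if (object@accepted) " [accepted]" else " [rejected]", "\n", sep = "")
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit (2-state log10 D)\n")
  lab <- c("slow", "fast")
  for (i in 1:2)
    cat(sprintf("  %s: mean %.3f, sd %.3f, weight %.3f\n",
                lab[i], object@means[i], object@sds[i], object@weights[i]))
  cat(sprintf("  logLik %.2f after %d iterations%s\n", object@logLik,
              object@iterations,
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "FwhmResult", function(object) {
  cat(sprintf(
    "FwhmResult: ref %.2f px, probe %.2f px, ratio %.3f, rel. max %.1f%%\n",
    object@fwhmRef, object@fwhmProbe, object@ratio, object@relMaxPct))
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})
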