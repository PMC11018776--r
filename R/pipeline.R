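# End-to-end orchestration: one configuration object drives simulation,
# condensation/focus analysis and the concentration pipeline, with every
# parameter and seed serialized next to the outputs so a rerun with the
# same configuration reproduces them exactly.

#' Default pipeline configuration
#'
#' @param seed integer RNG seed for the whole run.
#' @param nCells number of synthetic cells.
#' @param focusFraction fraction of cells with a focus.
#' @param partitionRatio focus partition ratio.
#' @param concentration mean cellular concentration (uM) of the simulated
#'   population, or NULL to use a fixed copy number.
#' @param stages character vector of stages to run, in dependency order:
#'   \code{"simulate"}, \code{"condensation"}, \code{"foci"},
#'   \code{"concentration"}.
#' @return named list of parameters.
#' @export
pipelineConfig <- function(seed = 1, nCells = 50, focusFraction = 0.5,
                           partitionRatio = 5, concentration = NULL,
                           stages = c("simulate", "condensation", "foci",
                                      "concentration")) {
  list(seed = seed, nCells = nCells, focusFraction = focusFraction,
       partitionRatio = partitionRatio, concentration = concentration,
       stages = stages, threshold = 0.5, photonsPerMolecule = 90,
       nFrames = if ("concentration" %in% stages) 6L else 1L,
       bias = 100, readNoise = 2, conversionGain = 1.40,
       emGainFactor = 0.15, nominalEmGain = 10, pixelSize = 0.066)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order on a synthetic
#' population: simulation, per-cell condensation coefficients, focus
#' detection with partition ratios, and the photon-counting concentration
#' pipeline.  Writes per-cell CSV tables and a flat key-value copy of the
#' configuration into \code{outDir} when given.
#'
#' @param config list from \code{\link{pipelineConfig}}.
#' @param outDir optional output directory; created if missing.
#' @return list with \code{cells} (per-cell table), \code{summary} (named
#'   numeric summary statistics) and \code{config}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(is.list(config))
  set.seed(config$seed)
  camera <- CameraModel(biasCounts = config$bias,
                        readNoiseSD = config$readNoise,
                        conversionGain = config$conversionGain,
                        emGainFactor = config$emGainFactor,
                        nominalEmGain = config$nominalEmGain,
                        pixelSize = config$pixelSize)
  simCfg <- SimConfig(nFrames = config$nFrames, seed = NA,
                      photonsPerMolecule = config$photonsPerMolecule)
  if (!"simulate" %in% config$stages)
    stop("missing dependency: the 'simulate' stage provides all inputs")
  truth <- makeCellTruth(config$nCells, camera,
                         copyNumber = if (is.null(config$concentration))
                           50000 else NULL,
                         concentration = config$concentration,
                         sdConcentration = if (is.null(config$concentration))
                           0 else config$concentration * 0.07,
                         focusFraction = config$focusFraction,
                         partitionRatio = config$partitionRatio)
  sim <- renderCellPopulation(simCfg, truth, camera)
  frame1 <- if (length(dim(sim$image)) == 3) sim$image[, , 1] else sim$image
  corr <- backgroundCorrect(frame1, sim$mask)
  cells <- truth[, c("cell_id", "length_um", "width_um", "copy_number",
                     "focus_present")]
  summary <- c(n_cells = nrow(cells))

  if ("condensation" %in% config$stages) {
    cells$condensation <- vapply(cells$cell_id, function(id) {
      condensationCoefficient(minmaxNormalize(
        gaussianBlur(corr, 0.066, config$pixelSize,
                     mask = sim$mask == id)[sim$mask == id]),
        config$threshold)
    }, numeric(1))
    ref <- cells$condensation[!cells$focus_present]
    if (length(ref))
      cells$condensation_norm <- normalizeToReference(cells$condensation, ref)
    summary <- c(summary,
                 mean_condensation = mean(cells$condensation, na.rm = TRUE))
    if (length(ref))
      summary <- c(summary, mean_condensation_norm =
                     mean(cells$condensation_norm[!cells$focus_present],
                          na.rm = TRUE))
  }
  if ("foci" %in% config$stages) {
    det <- lapply(cells$cell_id, function(id) {
      detectFoci(corr, sim$mask == id, pixelSize = config$pixelSize)
    })
    cells$n_foci <- vapply(det, nrow, integer(1))
    cells$partition_ratio <- vapply(seq_along(det), function(i) {
      if (nrow(det[[i]]) == 0) return(NA_real_)
      as.numeric(partitionRatio(corr, sim$mask == cells$cell_id[i],
                                det[[i]]))
    }, numeric(1))
    summary <- c(summary,
                 percent_with_focus = populationFocusFraction(cells$n_foci > 0))
  }
  if ("concentration" %in% config$stages) {
    if (length(dim(sim$image)) != 3 || dim(sim$image)[3] < 5)
      stop("missing dependency: concentration stage needs a movie of >= 5 ",
           "frames from the simulate stage")
    ppm <- config$photonsPerMolecule
    geom <- measureCellGeometry(sim$mask, config$pixelSize)
    corrMovie <- sim$image
    for (t in seq_len(dim(corrMovie)[3]))
      corrMovie[, , t] <- backgroundCorrect(sim$image[, , t], sim$mask)
    cells$concentration_uM <- vapply(cells$cell_id, function(id) {
      counts <- prebleachCellIntensity(corrMovie, sim$mask, id,
                                       backgroundCorrected = TRUE)
      ph <- countsToPhotons(counts, camera = camera)
      g <- geom[geom$cell_id == id, ]
      cellularConcentration(ph, ppm,
                            spherocylinderVolume(g$length_um, g$width_um)
                            )$concentration_uM
    }, numeric(1))
    summary <- c(summary,
                 mean_concentration_uM = mean(cells$concentration_uM))
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(outDir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(key = names(summary), value = summary),
                     file.path(outDir, "summary.csv"), row.names = FALSE)
    writePipelineConfig(config, file.path(outDir, "config.txt"))
  }
  list(cells = cells, summary = summary, config = config)
}

#' Serialize a pipeline configuration as flat key-value text
#'
#' @param config list of scalar parameters (vectors are comma-joined).
#' @param path output file.
#' @export
writePipelineConfig <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", if (is.null(v)) "" else paste(v, collapse = ","))
  }, character(1))
  writeLines(lines, path)
}

#' Read a flat key-value pipeline configuration
#'
#' @param path file written by \code{\link{writePipelineConfig}}.
#' @return named list with numeric values restored where possible.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, " = ", fixed = TRUE)[[1]]
    key <- kv[1]
    val <- if (length(kv) < 2 || kv[2] == "") NULL else
      strsplit(kv[2], ",", fixed = TRUE)[[1]]
    if (!is.null(val)) {
      num <- suppressWarnings(as.numeric(val))
      if (!anyNA(num)) val <- num
    }
    out[[key]] <- val
  }
  out
}

#' Write a simulation to TIFF images and CSV truth tables
#'
#' Images are written as (multi-page) 32-bit float TIFF, the label mask as
#' 16-bit TIFF, and the truth table as CSV.
#'
#' @param sim list from \code{\link{renderCellPopulation}} or
#'   \code{\link{simulateTimelapse}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF output")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- if (!is.null(sim$image)) sim$image else sim$movie
  msk <- if (!is.null(sim$mask)) sim$mask else sim$masks
  truth <- if (!is.null(sim$truth)) sim$truth else sim$cells
  asList <- function(a) {
    if (length(dim(a)) == 3)
      lapply(seq_len(dim(a)[3]), function(t) a[, , t]) else list(a)
  }
  paths <- c(image = file.path(dir, "image.tif"),
             mask = file.path(dir, "mask.tif"),
             truth = file.path(dir, "truth.csv"))
  scale <- max(unlist(lapply(asList(img), max)), 1)
  tiff::writeTIFF(lapply(asList(img), function(m) m / scale),
                  paths["image"], bits.per.sample = 32)
  tiff::writeTIFF(lapply(asList(msk), function(m) m / 65535),
                  paths["mask"], bits.per.sample = 16)
  utils::write.csv(cbind(truth, image_scale = scale), paths["truth"],
                   row.names = FALSE)
  invisible(paths)
}

#' Read back a simulation written by \code{writeSimulation}
#'
#' @param dir directory written by \code{\link{writeSimulation}}.
#' @return list with \code{image} (matrix or array, rescaled to original
#'   counts), \code{mask} (integer labels) and \code{truth}.
#' @export
readSimulation <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF output")
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  scale <- truth$image_scale[1]
  fromList <- function(x) {
    if (length(x) == 1) x[[1]] else
      array(unlist(x), c(dim(x[[1]]), length(x)))
  }
  img <- tiff::readTIFF(file.path(dir, "image.tif"), all = TRUE)
  msk <- tiff::readTIFF(file.path(dir, "mask.tif"), all = TRUE)
  list(image = fromList(img) * scale,
       mask = round(fromList(msk) * 65535),
       truth = truth[, setdiff(names(truth), "image_scale")])
}
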