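test_that("conversion gain is recovered across fixture gains", {
  for (g in c(1.0, 1.40, 2.0)) {
    cam <- CameraModel(conversionGain = g)
    cal <- simulateCalibrationSeries(cam, dims = c(96, 96), seed = 51)
    fit <- fitConversionGain(cal)
    expect_equal(conversionGain(fit), g, tolerance = 0.03)
    expect_gt(fit@diagnostics$r2, 0.99)
  }
  cam <- CameraModel(readNoiseSD = 0)
  flatCal <- simulateCalibrationSeries(cam, noise = FALSE)
  expect_error(fitConversionGain(flatCal), "variance")
  shortCal <- simulateCalibrationSeries(cam, exposures = c(10, 20), seed = 1)
  expect_error(fitConversionGain(shortCal), "three exposure")
})

test_that("EM-gain factor fit honors the 5-600 range rule", {
  cam <- CameraModel(emGainFactor = 0.15)
  cal <- simulateCalibrationSeries(cam, nominalEmGains = c(5, 50, 300, 600),
                                   dims = c(96, 96), seed = 52)
  fit <- fitEmGainFactor(cal)
  expect_equal(emGainFactor(fit), 0.15, tolerance = 0.03)
  # unit factor is the identity case
  cam1 <- CameraModel(emGainFactor = 1)
  cal1 <- simulateCalibrationSeries(cam1, nominalEmGains = c(5, 50, 300),
                                    noise = FALSE)
  expect_equal(emGainFactor(fitEmGainFactor(cal1)), 1, tolerance = 1e-6)
  # a nominal gain of 1000 is excluded with a warning
  cal2 <- simulateCalibrationSeries(cam, nominalEmGains = c(5, 50, 300, 1000),
                                    dims = c(96, 96), seed = 53)
  expect_warning(fit2 <- fitEmGainFactor(cal2), "1000")
  expect_equal(nrow(fit2@diagnostics$points), 3L)
})

test_that("counts-to-photons conversion matches the calibration arithmetic", {
  expect_equal(countsToPhotons(900, conversionGain = 1.40,
                               nominalEmGain = 600, emGainFactor = 0.15), 14)
  expect_equal(countsToPhotons(0, conversionGain = 1.4, nominalEmGain = 10,
                               emGainFactor = 0.15), 0)
  # nominal gain equal to 1/f cancels the EM stage
  expect_equal(countsToPhotons(70, conversionGain = 1.4,
                               nominalEmGain = 1 / 0.15,
                               emGainFactor = 0.15), 70 * 1.4)
  expect_error(countsToPhotons(1, conversionGain = 1.4, nominalEmGain = 0,
                               emGainFactor = 0.15), "positive")
})

test_that("camera forward model and photon conversion invert in expectation", {
  for (g in c(1.0, 1.4, 2.0)) {
    cam <- CameraModel(conversionGain = g, nominalEmGain = 10,
                       readNoiseSD = 1)
    cal <- simulateCalibrationSeries(cam, exposures = 100,
                                     photonFluxPerMs = 20,
                                     dims = c(128, 128), seed = 54)
    fr <- cal$flatfield[["100"]][[1]]
    # flat fields are rendered without EM gain, so invert with G*f = 1
    ph <- countsToPhotons(mean(fr) - cam@biasCounts, conversionGain = g,
                          nominalEmGain = 1, emGainFactor = 1)
    expect_equal(ph, 2000, tolerance = 0.01)
  }
})

test_that("Gamma brightness fit finds the mode and flags edge cases", {
  set.seed(55)
  fit <- photonsPerMolecule(rgamma(5000, shape = 10, scale = 10))
  expect_equal(fit@mode, 90, tolerance = 0.05)
  expect_equal(fit@method, "mle")
  deg <- photonsPerMolecule(rep(42, 200))
  expect_equal(deg@mode, 42)
  expect_true("degenerate" %in% deg@flags)
  set.seed(56)
  expfit <- photonsPerMolecule(rexp(2000, 1 / 50))
  expect_lt(expfit@shape, 1.1)
  expect_true(is.na(expfit@mode) || expfit@mode < 10)
  expect_error(photonsPerMolecule(c(-1, 2, 3)), "positive")
})

test_that("pre-bleach intensity uses the five brightest frames", {
  mov <- array(0, c(6, 6, 8))
  msk <- matrix(0L, 6, 6); msk[3:4, 3:4] <- 1L
  for (t in 1:8) mov[3:4, 3:4, t] <- 25  # constant: 4 px * 25 = 100
  expect_equal(prebleachCellIntensity(mov, msk), 100)
  # monotone bleaching ramp: the five brightest are the first five
  ramp <- array(0, c(6, 6, 8))
  for (t in 1:8) ramp[3:4, 3:4, t] <- 25 * 0.8^(t - 1)
  expect_equal(prebleachCellIntensity(ramp, msk),
               mean(100 * 0.8^(0:4)))
  expect_error(prebleachCellIntensity(mov[, , 1:3], msk), "at least")
})

test_that("bleached noisy movies recover the initial brightness within 5%", {
  cam <- CameraModel()
  cfg <- SimConfig(nFrames = 8, noise = TRUE, photonsPerMolecule = 90,
                   seed = 57)
  tr <- makeCellTruth(4, cam, copyNumber = 50000, seed = 58)
  sim <- renderCellPopulation(cfg, tr, cam, bleachPerFrame = 0.98)
  M <- cam@nominalEmGain * cam@emGainFactor / cam@conversionGain
  for (id in tr$cell_id) {
    counts <- prebleachCellIntensity(sim$image, sim$mask, id)
    expect_equal(counts, 50000 * 90 * M, tolerance = 0.05)
  }
})

test_that("spherocylinder volume matches closed forms and scaling", {
  expect_equal(spherocylinderVolume(1, 1), 4 / 3 * pi * 0.5^3,
               tolerance = 1e-12)
  expect_equal(round(spherocylinderVolume(1, 1), 4), 0.5236)
  expect_equal(round(spherocylinderVolume(3, 1), 4), 2.0944)
  expect_equal(spherocylinderVolume(6, 2), 8 * spherocylinderVolume(3, 1))
  # cylinder + sphere additivity: V(L, w) - V(w, w) is the cylinder part
  expect_equal(spherocylinderVolume(3, 1) - spherocylinderVolume(1, 1),
               pi * 0.5^2 * 2)
  expect_error(spherocylinderVolume(0.5, 1), "length")
  expect_error(spherocylinderVolume(1, 0), "width")
})

test_that("concentration arithmetic matches Avogadro bookkeeping", {
  out <- cellularConcentration(1000 * 90, 90, 1)
  expect_equal(out$copy_number, 1000)
  expect_equal(out$concentration_uM, 1.6606, tolerance = 1e-4)
  expect_equal(cellularConcentration(0, 90, 1)$concentration_uM, 0)
  expect_error(cellularConcentration(10, 0, 1), "positive")
  expect_error(cellularConcentration(10, 90, 0), "positive")
})

test_that("apparent c_sat range and Welch test follow their definitions", {
  mk <- function(m, s, focus) data.frame(
    concentration_uM = c(m - s, m, m + s), has_focus = focus)
  rec <- rbind(mk(98, 9, FALSE), mk(113, 8, TRUE))
  est <- estimateCsat(rec)
  expect_equal(est$no_focus$mean, 98)
  expect_equal(est$no_focus$sd, 9)
  expect_equal(as.numeric(est$csat_range), c(89, 121))
  expect_true(attr(est$csat_range, "interpreted"))
  # identical groups: the test cannot distinguish them
  set.seed(59)
  same <- data.frame(concentration_uM = rnorm(60, 50, 5),
                     has_focus = rep(c(TRUE, FALSE), 30),
                     replicate = rep(1:3, each = 20))
  expect_gt(estimateCsat(same)$welch$p.value, 0.05)
  # Welch statistic against the textbook formula on a tiny two-sample toy
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  tw <- stats::t.test(y, x, var.equal = FALSE)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  tHand <- (mean(y) - mean(x)) / se
  dfHand <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(unname(tw$statistic), tHand, tolerance = 1e-12)
  expect_equal(unname(tw$parameter), dfHand, tolerance = 1e-12)
  expect_equal(tw$p.value, 2 * stats::pt(-abs(tHand), dfHand),
               tolerance = 1e-12)
})

test_that("mask-derived geometry matches the generator truth", {
  cam <- CameraModel()
  tr <- makeCellTruth(20, cam, seed = 60)
  sim <- renderCellPopulation(SimConfig(noise = FALSE), tr, cam)
  geom <- measureCellGeometry(sim$mask, cam@pixelSize)
  ord <- order(geom$cell_id)
  expect_equal(geom$length_um[ord], tr$length_um, tolerance = 0.05)
  expect_equal(geom$width_um[ord], tr$width_um, tolerance = 0.08)
})
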