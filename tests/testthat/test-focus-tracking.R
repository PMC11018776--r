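test_that("LoG detector finds a matched-scale blob and is amplitude-monotone", {
  sigma <- 0.6 / 0.066 / (2 * sqrt(2))  # detection scale for 600 nm blobs
  img <- gaussianSpotImage(dim = 41, amp = 500, r0 = 21.0, c0 = 18.0,
                           sigma = sigma, offset = 50)
  spots <- logDetect(img, 0.6, qualityThreshold = 1)
  expect_equal(nrow(spots), 1L)
  expect_lt(abs(spots$row_px - 21), 0.5)
  expect_lt(abs(spots$col_px - 18), 0.5)
  # quality grows linearly with blob amplitude
  q <- vapply(c(100, 200, 400), function(a) {
    logDetect(gaussianSpotImage(41, a, 21, 18, sigma, 50), 0.6, 1)$quality
  }, numeric(1))
  expect_true(all(diff(q) > 0))
  expect_equal(q[3] / q[1], 4, tolerance = 1e-6)
  # blank frame
  expect_equal(nrow(logDetect(matrix(5, 31, 31), 0.6, 1)), 0L)
  expect_error(logDetect(img, 0.1), "blobDiameter")
})

test_that("linking follows the distance and gap rules", {
  drift <- data.frame(frame = 1:8, row_px = 10, col_px = 5 + (1:8))
  tr <- linkSpots(drift)
  expect_equal(length(unique(tr$track_id)), 1L)
  # gap of 2 frames, reappearing 2 px away: closed into one track
  gap <- drift[-c(4, 5), ]
  tr2 <- linkSpots(gap, maxLink = 3, maxGapDist = 3, maxGap = 2)
  expect_equal(length(unique(tr2$track_id)), 1L)
  # gap of 3 frames exceeds maxGap: two tracks
  gap3 <- drift[-(4:6), ]
  tr3 <- linkSpots(gap3, maxLink = 3, maxGapDist = 3, maxGap = 2)
  expect_equal(length(unique(tr3$track_id)), 2L)
  # a 4 px jump with maxLink 3 splits the track
  jump <- data.frame(frame = 1:6, row_px = 10,
                     col_px = c(5, 6, 7, 11, 12, 13))
  tr4 <- linkSpots(jump, maxLink = 3, maxGapDist = 2, maxGap = 0)
  expect_equal(length(unique(tr4$track_id)), 2L)
})

test_that("linking is invariant to spot order within frames", {
  set.seed(31)
  spots <- do.call(rbind, lapply(1:6, function(t) {
    data.frame(frame = t,
               row_px = c(10, 30, 50) + rnorm(3, 0, 0.3),
               col_px = c(10, 30, 50) + rnorm(3, 0, 0.3))
  }))
  a <- linkSpots(spots)
  shuf <- spots[sample(nrow(spots)), ]
  b <- linkSpots(shuf)
  key <- function(d) {
    d <- d[order(d$frame, d$row_px), ]
    split(paste(d$frame, round(d$row_px, 6)), d$track_id)
  }
  expect_setequal(unname(key(a)), unname(key(b)))
})

test_that("the four trajectory filters remove the right tracks", {
  mk <- function(id, frames, cell) data.frame(track_id = id, frame = frames,
                                              row_px = 0, col_px = 0,
                                              cell_id = cell)
  tracks <- rbind(mk(1, 1:10, 1),   # compliant
                  mk(2, 2:10, 2),   # starts late -> (i)
                  mk(3, 1, 3),      # single first-frame detection -> (iii)
                  mk(4, 1:10, 4),   # cell leaves view -> (ii)
                  mk(5, 1:10, 5))   # cell never grew -> (iv)
  lineage <- data.frame(cell_id = 1:5,
                        out_of_view = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                        grew_or_divided = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- applyTrackFilters(tracks, lineage)
  expect_equal(unique(out$track_id), 1)
  removed <- attr(out, "removed")
  expect_equal(removed$reason[match(2:5, removed$track_id)],
               c("not_in_first_frame", "first_frame_false_positive",
                 "cell_out_of_view", "cell_did_not_grow_or_divide"))
  expect_warning(applyTrackFilters(tracks[tracks$track_id %in% c(1, 4), ]),
                 "lineage")
})

test_that("lifespans separate dissolved from censored foci", {
  tracks <- rbind(
    data.frame(track_id = 1, frame = 1:6),   # dissolves: 5 intervals
    data.frame(track_id = 2, frame = 1:40))  # persists to the horizon
  tracks$row_px <- 0; tracks$col_px <- 0
  ls <- focusLifespans(tracks, frameInterval = 0.25, horizonFrame = 40)
  expect_equal(ls$per_track$lifespan_h, c(1.25, 9.75))
  expect_equal(ls$per_track$dissolved, c(TRUE, FALSE))
  expect_equal(ls$percent_dissolved, 50)
  expect_equal(ls$mean_lifespan_h, 1.25)  # censored track excluded
  expect_error(focusLifespans(tracks[0, ], 0.25), "no tracks")
})

test_that("tracked lifespans of simulated dissolving foci match the truth", {
  cam <- CameraModel()
  tr <- makeCellTruth(40, cam, focusFraction = 1, partitionRatio = 6,
                      seed = 32)
  cfg <- SimConfig(nFrames = 30, frameInterval = 900, seed = 33)
  tl <- simulateTimelapse(cfg, "dissolution", tr, cam,
                          focusLifespanMeanH = 1.4)
  spots <- do.call(rbind, lapply(1:30, function(t) {
    img <- backgroundCorrect(tl$movie[, , t], tl$masks[, , t])
    s <- logDetect(img, 0.6, qualityThreshold = 8000)
    if (nrow(s)) {
      s$frame <- t
      s
    } else NULL
  }))
  tracks <- linkSpots(spots, 3, 3, 2)
  filt <- applyTrackFilters(tracks)
  ls <- focusLifespans(filt, 0.25, horizonFrame = 30)
  # truth: focus present on frames 1 .. death-1, so the first-to-last
  # detection lifespan is (death - 2) intervals; foci seen in >= 2 frames
  df <- tl$truth$focus_death_frame
  truthLife <- (pmin(df, 31) - 2) * 0.25
  expectedMean <- mean(truthLife[df >= 3 & df <= 30])
  expect_equal(ls$mean_lifespan_h, expectedMean, tolerance = 1e-9)
  expect_equal(ls$percent_dissolved,
               100 * sum(df >= 3 & df <= 30) / sum(df >= 3), tolerance = 1)
})

test_that("dissolution intensities recover the generator's drop factor", {
  cam <- CameraModel()
  tr <- makeCellTruth(1, cam, focusFraction = 1, partitionRatio = 8,
                      seed = 34)
  tr$focus_death_frame <- 4L
  cfg <- SimConfig(nFrames = 6, frameInterval = 900, noise = FALSE)
  tl <- simulateTimelapse(cfg, "dissolution", tr, cam, intensityDrop = 1)
  out <- dissolutionIntensity(tl$movie, tl$masks, 1, 4)
  expect_equal(unname(out["post"] / out["pre"]), 1, tolerance = 1e-6)
  tl2 <- simulateTimelapse(cfg, "dissolution", tr, cam,
                           intensityDrop = 100 / 120)
  out2 <- dissolutionIntensity(tl2$movie, tl2$masks, 1, 4)
  expect_equal(unname(out2["post"] / out2["pre"]), 100 / 120,
               tolerance = 1e-6)
  expect_error(dissolutionIntensity(tl$movie, tl$masks, 1, 1), "interior")
  expect_error(dissolutionIntensity(tl$movie, tl$masks, 99, 4), "missing")
})

test_that("inheritance fractions sum to one and symmetric division is even", {
  cam <- CameraModel()
  tr <- makeCellTruth(1, cam, marginPx = 12, seed = 35)
  cfg <- SimConfig(nFrames = 4, frameInterval = 900, noise = FALSE)
  tl <- simulateTimelapse(cfg, "division", tr, cam, divisionFrame = 3,
                          asymmetry = 0.5)
  kids <- unique(tl$cells$cell_id[tl$cells$frame == 3])
  ir <- inheritanceRatio(tl$movie[, , 2], tl$masks[, , 2],
                         tl$movie[, , 3], tl$masks[, , 3], 1, kids)
  expect_equal(unname(ir$fractions), c(0.5, 0.5), tolerance = 0.01)
  expect_equal(sum(ir$fractions), 1, tolerance = 0.01)
  expect_error(inheritanceRatio(tl$movie[, , 2], tl$masks[, , 2],
                                tl$movie[, , 3], tl$masks[, , 3], 1,
                                kids[1]), "two daughters")
})
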