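# Shared fixtures and independent oracles, all built in code.

defaultCamera <- function(...) CameraModel(...)

# A small noise-free rendered population with foci.
noiselessFocusSim <- function(n = 3, ratio = 9, seed = 101) {
  cam <- CameraModel()
  tr <- makeCellTruth(n, cam, focusFraction = 1, partitionRatio = ratio,
                      seed = seed)
  sim <- renderCellPopulation(SimConfig(noise = FALSE), tr, cam)
  sim
}

# Exhaustive minimum-cost gated matching for <= 4 x 4 point sets: the
# independent oracle for the Hungarian-assignment linker.  Returns the
# assignment vector (NA = unmatched) minimizing total squared distance,
# where unmatched points cost maxDist^2 each and links beyond maxDist are
# forbidden.
bruteForceMatch <- function(a, b, maxDist) {
  na <- nrow(a); nb <- nrow(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  gate <- maxDist^2
  best <- NULL; bestCost <- Inf
  # enumerate all partial injective maps from a to b
  options <- c(NA_integer_, seq_len(nb))
  grid <- do.call(expand.grid, rep(list(options), na))
  for (k in seq_len(nrow(grid))) {
    m <- as.integer(grid[k, ])
    used <- m[!is.na(m)]
    if (anyDuplicated(used)) next
    cost <- 0
    legal <- TRUE
    for (i in seq_len(na)) {
      if (is.na(m[i])) cost <- cost + gate
      else if (d2[i, m[i]] > gate) { legal <- FALSE; break }
      else cost <- cost + d2[i, m[i]]
    }
    cost <- cost + (nb - length(used)) * gate
    if (legal && cost < bestCost - 1e-12) {
      bestCost <- cost; best <- m
    }
  }
  list(assignment = best, cost = bestCost)
}

# total cost of an assignment vector under the same convention
assignmentCost <- function(m, a, b, maxDist) {
  gate <- maxDist^2
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  cost <- 0
  for (i in seq_along(m))
    cost <- cost + if (is.na(m[i])) gate else d2[i, m[i]]
  cost + (nrow(b) - sum(!is.na(m))) * gate
}

# Render a single isotropic Gaussian spot on a flat offset.
gaussianSpotImage <- function(dim = 23, amp = 100, r0 = 12, c0 = 12,
                              sigma = 2, offset = 0) {
  rows <- matrix(seq_len(dim), dim, dim)
  cols <- matrix(seq_len(dim), dim, dim, byrow = TRUE)
  offset + amp * exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * sigma^2))
}
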