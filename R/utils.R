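# Internal helpers shared across modules.

# Set the RNG deterministically when a seed is given, restoring nothing:
# callers that pass seed = NULL / NA inherit the session RNG stream, which
# keeps one top-level seed in control of a whole pipeline run.
.withSeed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Mirror-pad a matrix by `r` pixels on every side (reflective boundary).
.mirrorPad <- function(x, r) {
  if (r == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  r1 <- min(r, nr); r2 <- min(r, nc)
  top <- x[seq(r1, 1), , drop = FALSE]
  bot <- x[seq(nr, nr - r1 + 1), , drop = FALSE]
  x2 <- rbind(top, x, bot)
  left <- x2[, seq(r2, 1), drop = FALSE]
  right <- x2[, seq(nc, nc - r2 + 1), drop = FALSE]
  cbind(left, x2, right)
}

# 2D convolution with reflective boundary handling via mirror padding.
# `kernel` must have odd dimensions.
.convolve2 <- function(x, kernel) {
  r <- (max(dim(kernel)) - 1L) %/% 2L
  if (r == 0) return(x * kernel[1, 1])
  xp <- .mirrorPad(x, r)
  yp <- EBImage::filter2(xp, kernel, boundary = "circular")
  yp[(r + 1):(r + nrow(x)), (r + 1):(r + ncol(x)), drop = FALSE]
}

# Discrete isotropic Gaussian kernel, normalized to sum 1.
.gaussKernel <- function(sigma, radius = ceiling(4 * sigma)) {
  if (sigma <= 0) return(matrix(1, 1, 1))
  ax <- seq(-radius, radius)
  g <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Scale-normalized negative Laplacian-of-Gaussian kernel: responds
# positively to bright blobs of matched scale.
.logKernel <- function(sigma, radius = ceiling(4 * sigma)) {
  ax <- seq(-radius, radius)
  r2 <- outer(ax^2, ax^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  # sigma^2 * (-laplacian of gaussian); zero-mean so flat regions give 0
  k <- (1 - r2 / (2 * sigma^2)) * g / (pi * sigma^2)
  k - mean(k)
}

# Strict 8-neighbour local maxima of a matrix; returns integer matrix of
# (row, col).  Border pixels are never maxima.
.localMaxima <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  if (nr < 3 || nc < 3) return(cbind(row = integer(), col = integer()))
  core <- x[2:(nr - 1), 2:(nc - 1)]
  ok <- matrix(TRUE, nr - 2, nc - 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- x[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
    ok <- ok & (core > nb)
  }
  idx <- which(ok, arr.ind = TRUE)
  cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
}

# Gated minimum-cost one-to-one matching between two point sets.
# Returns an integer vector m of length nrow(a): m[i] = index into b, or NA.
# Pairs with squared distance > maxDist^2 are never linked.  Implemented as
# a square linear assignment problem with dummy rows/columns whose cost
# slightly exceeds the gate, so unmatched is preferred to an illegal link.
.gatedMatch <- function(a, b, maxDist) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L) return(integer(0))
  if (nb == 0L) return(rep(NA_integer_, na))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  gate <- maxDist^2
  big <- gate * 1e6 + 1
  dummy <- gate * 1.0000001
  n <- na + nb
  cost <- matrix(dummy, n, n)
  cc <- d2
  cc[cc > gate] <- big
  cost[seq_len(na), seq_len(nb)] <- cc
  cost[(na + 1):n, (nb + 1):n] <- 0
  sol <- clue::solve_LSAP(cost)
  m <- rep(NA_integer_, na)
  for (i in seq_len(na)) {
    j <- sol[i]
    if (j <= nb && d2[i, j] <= gate) m[i] <- j
  }
  m
}

# Region properties of one labelled component: area, centroid (row, col),
# eccentricity of the equal-second-moment ellipse (0 = circle), mean of
# `values` over the component.
.regionProps <- function(pix, values = NULL) {
  n <- nrow(pix)
  cr <- mean(pix[, 1]); cc <- mean(pix[, 2])
  # second central moments with the 1/12 pixel-area term so single pixels
  # are circles rather than points
  mrr <- mean((pix[, 1] - cr)^2) + 1 / 12
  mcc <- mean((pix[, 2] - cc)^2) + 1 / 12
  mrc <- mean((pix[, 1] - cr) * (pix[, 2] - cc))
  tr <- mrr + mcc
  det <- mrr * mcc - mrc^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  list(area = n, centroidRow = cr, centroidCol = cc, eccentricity = ecc,
       meanIntensity = if (is.null(values)) NA_real_ else mean(values))
}

# Per-label bounding boxes etc. for an integer label mask: list keyed by
# label of pixel index matrices.
.labelPixels <- function(mask) {
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs > 0]
  out <- lapply(labs, function(l) which(mask == l, arr.ind = TRUE))
  names(out) <- as.character(labs)
  out
}

.isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
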