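#' Discretize intensities into a fixed number of grey levels
#'
#' Fixed-bin-count discretization over the value range of the supplied
#' intensities: with `m = min`, `M = max`, level(v) = `min(B, floor((v - m) *
#' B / (M - m)) + 1)`; a constant input maps entirely to level 1. This is the
#' prerequisite of all texture matrices and of the first-order entropy.
#'
#' @param values nonempty numeric vector of region-of-interest intensities.
#' @param nBins number of grey levels B (>= 2).
#' @return Integer levels in `1..B`, monotone in `values`.
#' @export
discretize <- function(values, nBins) {
  if (!length(values)) stop("empty ROI: nothing to discretize")
  if (nBins < 2) stop("nBins must be at least 2")
  m <- min(values); M <- max(values)
  if (M == m) return(rep(1L, length(values)))
  pmin.int(as.integer(nBins),
           as.integer(floor((values - m) * nBins / (M - m))) + 1L)
}

# Circular shift of a matrix: value at (i, j) of the result is the value at
# (i + dr, j + dc) of the input, with periodic wrapping.
circShift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1 + dr) %% nr) + 1
  ci <- ((seq_len(nc) - 1 + dc) %% nc) + 1
  m[ri, ci, drop = FALSE]
}

#' Single-level undecimated 2D Haar transform
#'
#' Separable filtering with the orthonormal Haar pair (low `[1, 1]/sqrt(2)`,
#' high `[1, -1]/sqrt(2)`) applied along rows and columns with periodic
#' boundary handling and no decimation, so each sub-band keeps the input
#' shape. Filtering pairs each pixel with its successor along the axis.
#' Sub-band names give the row filter first: `LH` is low-pass along rows,
#' high-pass along columns.
#'
#' @param frame numeric matrix, at least 2 x 2.
#' @return A named list of four matrices `LL`, `LH`, `HL`, `HH`.
#' @export
waveletSubbands <- function(frame) {
  if (nrow(frame) < 2 || ncol(frame) < 2) stop("frame must be at least 2x2")
  s2 <- sqrt(2)
  down <- circShift(frame, 1, 0)           # successor along rows
  lowR <- (frame + down) / s2
  highR <- (frame - down) / s2
  sub <- function(m) {
    rightm <- circShift(m, 0, 1)           # successor along columns
    list(L = (m + rightm) / s2, H = (m - rightm) / s2)
  }
  lr <- sub(lowR); hr <- sub(highR)
  list(LL = lr$L, LH = lr$H, HL = hr$L, HH = hr$H)
}

#' Rotation-invariant uniform local binary pattern map
#'
#' For each pixel, samples `points` neighbours on a circle of the given
#' radius (bilinear interpolation at fractional positions, periodic image
#' wrapping), thresholds them against the centre (neighbour >= centre), and
#' encodes the binary pattern rotation-invariantly: patterns with at most two
#' 0/1 transitions around the circle map to their number of set bits (codes
#' `0..P`), all other patterns map to `P + 1`.
#'
#' @param frame numeric matrix.
#' @param radius circle radius in pixels (>= 1).
#' @param points number of sampling points P (>= 4).
#' @return An integer matrix of codes in `0..P+1`, same shape as `frame`.
#' @export
lbpMap <- function(frame, radius = 1, points = 8L) {
  if (radius < 1) stop("radius must be >= 1")
  if (points < 4) stop("points must be >= 4")
  P <- as.integer(points)
  nr <- nrow(frame); nc <- ncol(frame)
  bits <- array(FALSE, c(nr, nc, P))
  for (k in seq_len(P)) {
    ang <- 2 * pi * (k - 1) / P
    dr <- radius * sin(ang); dc <- radius * cos(ang)
    # snap near-integer offsets so the axis-aligned neighbours are exact
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    fr <- floor(dr); fc <- floor(dc)
    wr <- dr - fr; wc <- dc - fc
    nb <- (1 - wr) * (1 - wc) * circShift(frame, fr, fc)
    if (wc > 0) nb <- nb + (1 - wr) * wc * circShift(frame, fr, fc + 1)
    if (wr > 0) nb <- nb + wr * (1 - wc) * circShift(frame, fr + 1, fc)
    if (wr > 0 && wc > 0) nb <- nb + wr * wc * circShift(frame, fr + 1, fc + 1)
    tol <- 1e-9 * (1 + abs(frame))
    bits[, , k] <- nb >= frame - tol
  }
  ones <- apply(bits, c(1, 2), sum)
  trans <- matrix(0L, nr, nc)
  for (k in seq_len(P)) {
    k2 <- (k %% P) + 1L
    trans <- trans + (bits[, , k] != bits[, , k2])
  }
  codes <- ifelse(trans <= 2L, ones, P + 1L)
  storage.mode(codes) <- "integer"
  codes
}
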