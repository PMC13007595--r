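#' First-order intensity statistics
#'
#' Thirteen first-order features of the region-of-interest intensities.
#' Variance uses the population denominator N; Skewness and Kurtosis are the
#' standardized third and fourth central moments (Kurtosis in excess form, so
#' a normal distribution scores 0; both are defined as 0 for a constant ROI);
#' percentiles use linear interpolation between order statistics; Entropy is
#' the Shannon entropy (base 2) of the discretized grey-level histogram.
#'
#' @param values nonempty numeric ROI intensities.
#' @param levels matching integer discretized levels (see [discretize()]).
#' @return A named numeric vector of 13 features.
#' @export
firstOrderFeatures <- function(values, levels) {
  if (!length(values)) stop("empty ROI")
  n <- length(values)
  mu <- mean(values)
  v <- mean((values - mu)^2)
  if (v > 0) {
    skew <- mean((values - mu)^3) / v^1.5
    kurt <- mean((values - mu)^4) / v^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  p <- tabulate(levels) / n
  p <- p[p > 0]
  c(Mean = mu,
    Variance = v,
    Skewness = skew,
    Kurtosis = kurt,
    Minimum = min(values),
    Maximum = max(values),
    Median = median(values),
    `10Percentile` = unname(quantile(values, 0.10, type = 7)),
    `90Percentile` = unname(quantile(values, 0.90, type = 7)),
    RootMeanSquared = sqrt(mean(values^2)),
    Energy = sum(values^2),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    Entropy = -sum(p * log2(p)))
}

#' Grey level co-occurrence matrices
#'
#' For each configured spatial offset, counts ordered pairs of discretized
#' in-mask pixels (both endpoints inside the mask), optionally symmetrizes by
#' adding the transpose, and normalizes to a probability matrix.
#'
#' @param levelsImage integer matrix of grey levels; entries outside the mask
#'   are ignored.
#' @param mask logical/0-1 matrix of the same shape.
#' @param config an [ExtractionConfig-class] (uses `nBins`, `glcmOffsets`,
#'   `glcmSymmetric`).
#' @return A list of B x B probability matrices, one per offset that has at
#'   least one valid pair; errors if no offset has any.
#' @export
glcmMatrix <- function(levelsImage, mask, config) {
  B <- config@nBins
  mask <- mask == 1
  if (!any(mask)) stop("empty mask")
  nr <- nrow(levelsImage); nc <- ncol(levelsImage)
  out <- list()
  for (o in seq_len(nrow(config@glcmOffsets))) {
    dr <- config@glcmOffsets[o, 1]; dc <- config@glcmOffsets[o, 2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    if (!length(r1) || !length(c1)) next
    m1 <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(m1)) next
    i <- levelsImage[r1, c1, drop = FALSE][m1]
    j <- levelsImage[r1 + dr, c1 + dc, drop = FALSE][m1]
    cnt <- matrix(tabulate(i + B * (j - 1L), nbins = B * B), B, B)
    if (config@glcmSymmetric) cnt <- cnt + t(cnt)
    out[[length(out) + 1L]] <- cnt / sum(cnt)
  }
  if (!length(out)) stop("degenerate ROI: no valid pixel pair for any offset")
  out
}

#' Grey level co-occurrence features
#'
#' Computes nine co-occurrence features per offset matrix and reports each
#' averaged over offsets: JointAverage, JointEnergy, JointEntropy, Contrast,
#' Correlation, Idm (inverse difference moment), Idn (inverse difference
#' normalized), Imc1 and Imc2 (informational measures of correlation, from
#' the joint and marginal entropies HXY, HXY1, HXY2, HX, HY). For a
#' degenerate single-level ROI (zero marginal variance) Correlation is
#' reported as 1 and Imc1/Imc2 as 0, keeping all curve values finite.
#'
#' @param matrices list of probability matrices from [glcmMatrix()].
#' @param nBins the number of grey levels B (used by Idn's normalization).
#' @return A named numeric vector of 9 features.
#' @export
glcmFeatures <- function(matrices, nBins) {
  per <- vapply(matrices, function(p) {
    B <- nrow(p)
    i <- matrix(seq_len(B), B, B)
    j <- t(i)
    px <- rowSums(p); py <- colSums(p)
    mux <- sum(seq_len(B) * px); muy <- sum(seq_len(B) * py)
    sx <- sqrt(sum((seq_len(B) - mux)^2 * px))
    sy <- sqrt(sum((seq_len(B) - muy)^2 * py))
    nz <- p > 0
    hxy <- -sum(p[nz] * log2(p[nz]))
    pxy1 <- outer(px, py)
    hxy1 <- -sum(p[nz] * log2(pxy1[nz]))
    nz1 <- pxy1 > 0
    hxy2 <- -sum(pxy1[nz1] * log2(pxy1[nz1]))
    hx <- -sum(px[px > 0] * log2(px[px > 0]))
    hy <- -sum(py[py > 0] * log2(py[py > 0]))
    corr <- if (sx * sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 1
    imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
    imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
    c(JointAverage = sum(i * p),
      JointEnergy = sum(p^2),
      JointEntropy = hxy,
      Contrast = sum((i - j)^2 * p),
      Correlation = corr,
      Idm = sum(p / (1 + (i - j)^2)),
      Idn = sum(p / (1 + abs(i - j) / nBins)),
      Imc1 = imc1,
      Imc2 = imc2)
  }, numeric(9))
  rowMeans(per)
}

# Connected components of equal-level in-mask pixels via the pixel adjacency
# graph (igraph); returns one row per zone with its grey level and size.
zoneList <- function(levelsImage, mask, connectivity = 8L) {
  mask <- mask == 1
  if (!any(mask)) stop("empty mask")
  nr <- nrow(levelsImage); nc <- ncol(levelsImage)
  idx <- which(mask)
  id <- match(seq_len(nr * nc), idx)      # pixel -> vertex id (NA outside)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  ep <- integer(0); eq <- integer(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- as.vector(outer(r1, (c1 - 1L) * nr, "+"))
    b <- as.vector(outer(r1 + dr, (c1 + dc - 1L) * nr, "+"))
    keep <- mask[a] & mask[b] & (levelsImage[a] == levelsImage[b])
    ep <- c(ep, a[keep]); eq <- c(eq, b[keep])
  }
  g <- igraph::make_graph(as.vector(rbind(id[ep], id[eq])), n = length(idx),
                          directed = FALSE)
  comp <- igraph::components(g)
  lev <- levelsImage[idx]
  data.frame(level = as.integer(tapply(lev, comp$membership, function(x) x[1])),
             size = as.integer(comp$csize))
}

#' Grey level size zone matrix
#'
#' Counts connected zones of equal-level in-mask pixels: entry `s[i, j]` is
#' the number of zones of grey level `i` and size `j` pixels.
#'
#' @param levelsImage integer matrix of grey levels.
#' @param mask logical/0-1 matrix of the same shape.
#' @param connectivity 4 or 8 (default) pixel connectivity.
#' @return An integer matrix with one row per grey level `1..max(level)` and
#'   one column per zone size `1..max(size)`.
#' @export
glszmMatrix <- function(levelsImage, mask, connectivity = 8L) {
  z <- zoneList(levelsImage, mask, connectivity)
  nL <- max(z$level); nS <- max(z$size)
  s <- matrix(0L, nL, nS)
  for (k in seq_len(nrow(z))) s[z$level[k], z$size[k]] <-
      s[z$level[k], z$size[k]] + 1L
  s
}

#' Grey level size zone features
#'
#' Six size-zone features from the zone matrix: SmallAreaEmphasis,
#' LargeAreaEmphasis, GrayLevelNonUniformity, SizeZoneNonUniformity,
#' ZonePercentage (zones per ROI pixel) and ZoneEntropy (Shannon entropy,
#' base 2, of the zone distribution).
#'
#' @param s zone matrix from [glszmMatrix()].
#' @param nPixels number of ROI pixels (for ZonePercentage).
#' @return A named numeric vector of 6 features.
#' @export
glszmFeatures <- function(s, nPixels) {
  Nz <- sum(s)
  if (Nz == 0) stop("degenerate ROI: no zones")
  jj <- matrix(seq_len(ncol(s)), nrow(s), ncol(s), byrow = TRUE)
  p <- s / Nz
  nzp <- p[p > 0]
  c(SmallAreaEmphasis = sum(s / jj^2) / Nz,
    LargeAreaEmphasis = sum(s * jj^2) / Nz,
    GrayLevelNonUniformity = sum(rowSums(s)^2) / Nz,
    SizeZoneNonUniformity = sum(colSums(s)^2) / Nz,
    ZonePercentage = Nz / nPixels,
    ZoneEntropy = -sum(nzp * log2(nzp)))
}
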