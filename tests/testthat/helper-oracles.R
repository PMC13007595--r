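# Brute-force reference implementations used as independent oracles.
# All are deliberately naive (scalar loops, literal formulas) and share no
# code with the package.

# GLCM by exhaustive ordered-pair enumeration.
oracleGLCM <- function(levels, mask, offsets, symmetric = TRUE, nBins) {
  out <- list()
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]
    cnt <- matrix(0, nBins, nBins)
    for (r in seq_len(nrow(levels))) for (c in seq_len(ncol(levels))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
      if (mask[r, c] != 1 || mask[r2, c2] != 1) next
      cnt[levels[r, c], levels[r2, c2]] <- cnt[levels[r, c], levels[r2, c2]] + 1
    }
    if (sum(cnt) == 0) next
    if (symmetric) cnt <- cnt + t(cnt)
    out[[length(out) + 1]] <- cnt / sum(cnt)
  }
  out
}

# GLCM features by literal formula sums over one probability matrix.
oracleGLCMFeatures <- function(p, nBins) {
  B <- nrow(p)
  ja <- je <- hxy <- contrast <- idm <- idn <- cross <- 0
  px <- rowSums(p); py <- colSums(p)
  for (i in 1:B) for (j in 1:B) {
    ja <- ja + i * p[i, j]
    je <- je + p[i, j]^2
    if (p[i, j] > 0) hxy <- hxy - p[i, j] * log2(p[i, j])
    contrast <- contrast + (i - j)^2 * p[i, j]
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    idn <- idn + p[i, j] / (1 + abs(i - j) / nBins)
    cross <- cross + i * j * p[i, j]
  }
  mux <- sum((1:B) * px); muy <- sum((1:B) * py)
  sx <- sqrt(sum((1:B - mux)^2 * px)); sy <- sqrt(sum((1:B - muy)^2 * py))
  hxy1 <- hxy2 <- 0
  for (i in 1:B) for (j in 1:B) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  c(JointAverage = ja, JointEnergy = je, JointEntropy = hxy,
    Contrast = contrast,
    Correlation = if (sx * sy > 0) (cross - mux * muy) / (sx * sy) else 1,
    Idm = idm, Idn = idn,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0)
}

# Zone enumeration by explicit stack-based flood fill.
oracleZones <- function(levels, mask, connectivity = 8) {
  nr <- nrow(levels); nc <- ncol(levels)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    nbr <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
  } else nbr <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (mask[r0, c0] != 1 || seen[r0, c0]) next
    lev <- levels[r0, c0]
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; c <- p[2] + nbr[k, 2]
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] != 1 || seen[r, c] || levels[r, c] != lev) next
        seen[r, c] <- TRUE
        stack[[length(stack) + 1]] <- c(r, c)
      }
    }
    zones[[length(zones) + 1]] <- c(level = lev, size = size)
  }
  do.call(rbind, zones)
}

oracleGLSZM <- function(levels, mask, connectivity = 8) {
  z <- oracleZones(levels, mask, connectivity)
  s <- matrix(0, max(z[, "level"]), max(z[, "size"]))
  for (k in seq_len(nrow(z))) s[z[k, "level"], z[k, "size"]] <-
      s[z[k, "level"], z[k, "size"]] + 1
  s
}

oracleGLSZMFeatures <- function(s, nPixels) {
  Nz <- sum(s)
  sae <- lae <- ze <- 0
  for (i in seq_len(nrow(s))) for (j in seq_len(ncol(s))) {
    sae <- sae + s[i, j] / j^2
    lae <- lae + s[i, j] * j^2
    if (s[i, j] > 0) ze <- ze - (s[i, j] / Nz) * log2(s[i, j] / Nz)
  }
  c(SmallAreaEmphasis = sae / Nz, LargeAreaEmphasis = lae / Nz,
    GrayLevelNonUniformity = sum(rowSums(s)^2) / Nz,
    SizeZoneNonUniformity = sum(colSums(s)^2) / Nz,
    ZonePercentage = Nz / nPixels, ZoneEntropy = ze)
}

# LBP by per-pixel enumeration: same sampling definition (periodic wrap,
# bilinear interpolation, neighbour >= centre with tolerance), evaluated
# one pixel and one neighbour at a time.
oracleLBP <- function(frame, radius = 1, P = 8) {
  P <- as.integer(P)
  nr <- nrow(frame); nc <- ncol(frame)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  at <- function(r, c) frame[wrap(r, nr), wrap(c, nc)]
  codes <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    bits <- logical(P)
    for (k in seq_len(P)) {
      ang <- 2 * pi * (k - 1) / P
      dr <- radius * sin(ang); dc <- radius * cos(ang)
      if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
      if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
      fr <- floor(dr); fc <- floor(dc); wr <- dr - fr; wc <- dc - fc
      v <- (1 - wr) * (1 - wc) * at(r + fr, c + fc)
      if (wc > 0) v <- v + (1 - wr) * wc * at(r + fr, c + fc + 1)
      if (wr > 0) v <- v + wr * (1 - wc) * at(r + fr + 1, c + fc)
      if (wr > 0 && wc > 0) v <- v + wr * wc * at(r + fr + 1, c + fc + 1)
      bits[k] <- v >= frame[r, c] - 1e-9 * (1 + abs(frame[r, c]))
    }
    trans <- sum(bits != bits[c(2:P, 1)])
    codes[r, c] <- if (trans <= 2) sum(bits) else P + 1L
  }
  codes
}

# Undecimated Haar sub-bands by direct 2D convolution with the stated
# kernels (pixel paired with its successor along each axis, periodic).
oracleWavelet <- function(frame) {
  nr <- nrow(frame); nc <- ncol(frame)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  conv <- function(kr, kc) {
    out <- matrix(0, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      acc <- 0
      for (a in 0:1) for (b in 0:1)
        acc <- acc + kr[a + 1] * kc[b + 1] *
          frame[wrap(r + a, nr), wrap(c + b, nc)]
      out[r, c] <- acc
    }
    out
  }
  lo <- c(1, 1) / sqrt(2); hi <- c(1, -1) / sqrt(2)
  list(LL = conv(lo, lo), LH = conv(lo, hi),
       HL = conv(hi, lo), HH = conv(hi, hi))
}

# Random small masked level image for oracle-equivalence sweeps.
randomLevelImage <- function(maxSide = 8, maxLevels = 4) {
  nr <- sample(2:maxSide, 1); nc <- sample(2:maxSide, 1)
  levels <- matrix(sample.int(maxLevels, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(rbinom(nr * nc, 1, 0.8), nr, nc)
  if (sum(mask) < 2) mask[sample(nr * nc, 2)] <- 1
  list(levels = levels, mask = mask, nBins = maxLevels)
}
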