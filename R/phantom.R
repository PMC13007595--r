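#' Construct phantom parameters
#'
#' Defaults describe a mid-ventricular short-axis slice at typical cine
#' resolution: a 128 px grid at 1.5 mm spacing, 25 cardiac frames, an
#' end-diastolic endocardial radius of 18 px and epicardial radius of 30 px,
#' and a 30% peak endocardial contraction.
#'
#' @param gridSize pixels per side.
#' @param nFrames number of cardiac frames (12-50).
#' @param center (row, col) centre; defaults to the grid centre.
#' @param rEndoED,rEpiED end-diastolic endo-/epicardial radii in pixels.
#' @param contractionFraction peak fractional endocardial contraction, [0, 1).
#' @param muBackground,muMyocardium,muBloodpool mean class intensities.
#' @param textureAmplitude relative amplitude of the smooth texture field.
#' @param textureSeed integer seed of the subject's texture field.
#' @param pixelSpacing in-plane spacing in mm.
#' @return A validated [PhantomParams-class] object.
#' @export
phantomParams <- function(gridSize = 128L, nFrames = 25L, center = NULL,
                          rEndoED = 18, rEpiED = 30,
                          contractionFraction = 0.3,
                          muBackground = 60, muMyocardium = 200,
                          muBloodpool = 420, textureAmplitude = 0.1,
                          textureSeed = 1234L, pixelSpacing = 1.5) {
  if (is.null(center)) center <- rep((gridSize + 1) / 2, 2)
  new("PhantomParams", gridSize = as.integer(gridSize),
      nFrames = as.integer(nFrames), center = as.numeric(center),
      rEndoED = rEndoED, rEpiED = rEpiED,
      contractionFraction = contractionFraction,
      muBackground = muBackground, muMyocardium = muMyocardium,
      muBloodpool = muBloodpool, textureAmplitude = textureAmplitude,
      textureSeed = as.integer(textureSeed), pixelSpacing = pixelSpacing)
}

# Endo-/epicardial radii at (possibly fractional) frame index t, t = 0..T.
# The endocardium follows a raised-cosine contraction; the epicardium is set
# so the annulus area is conserved analytically (the wall thickens as the
# cavity shrinks, as real myocardium does). t = T closes the cycle.
phantomRadii <- function(params, t) {
  Tn <- params@nFrames
  rEndo <- params@rEndoED -
    params@contractionFraction * params@rEndoED * (1 - cos(2 * pi * t / Tn)) / 2
  rEpi <- sqrt(params@rEpiED^2 - params@rEndoED^2 + rEndo^2)
  list(endo = rEndo, epi = rEpi)
}

#' Generate a contracting-annulus cine phantom
#'
#' Renders one subject's cine sequence: three intensity classes (background,
#' myocardium, blood pool), each modulated by a smooth low-frequency
#' sinusoidal texture field fixed by `textureSeed`. The myocardial texture is
#' parameterized in annulus-relative coordinates (angle and transmural depth),
#' so it deforms with the tissue and the reference feature curves vary
#' smoothly with geometry rather than with per-frame randomness. The mask is
#' the myocardial annulus. Generation is a pure function of `params`.
#'
#' @param params a [PhantomParams-class] object.
#' @return A [CineSequence-class]; its `intensityRange` holds the raw range.
#' @export
generatePhantom <- function(params) {
  validObject(params)
  n <- params@gridSize
  Tn <- params@nFrames
  amp <- params@textureAmplitude

  tx <- withSeed(params@textureSeed, list(
    kTheta = sample(2:4, 1),
    kRad = runif(1, 1, 2),
    kRad2 = runif(1, 0.5, 1.5),
    phase = runif(4, 0, 2 * pi),
    fBg = sample(1:2, 1),
    fBp = sample(1:2, 1),
    phaseBg = runif(2, 0, 2 * pi),
    phaseBp = runif(2, 0, 2 * pi)
  ))

  rowc <- matrix(seq_len(n), n, n) - params@center[1]
  colc <- matrix(seq_len(n), n, n, byrow = TRUE) - params@center[2]
  d <- sqrt(rowc^2 + colc^2)
  theta <- atan2(rowc, colc)
  xn <- (colc + params@center[2]) / n
  yn <- (rowc + params@center[1]) / n

  bgField <- sin(2 * pi * tx$fBg * xn + tx$phaseBg[1]) *
    sin(2 * pi * tx$fBg * yn + tx$phaseBg[2])
  bpField <- sin(2 * pi * tx$fBp * xn + tx$phaseBp[1]) *
    sin(2 * pi * tx$fBp * yn + tx$phaseBp[2])

  frames <- array(0, c(n, n, Tn))
  maskArr <- array(0L, c(n, n, Tn))
  for (t in seq_len(Tn)) {
    r <- phantomRadii(params, t - 1)
    annulus <- d >= r$endo & d < r$epi
    if (sum(annulus) < 16)
      stop("degenerate geometry: empty myocardial annulus at frame ", t)
    img <- params@muBackground * (1 + amp * bgField)
    blood <- d < r$endo
    img[blood] <- params@muBloodpool * (1 + amp * bpField[blood])
    u <- (d - r$endo) / (r$epi - r$endo)
    # angular x transmural modulation plus a purely transmural component;
    # the latter keeps the ROI mean varying with the deforming geometry
    # (through-plane-motion-like brightening), so first-order feature
    # curves are non-degenerate over the cycle
    myoTex <- 0.5 * (sin(tx$kTheta * theta + tx$phase[1]) *
                       cos(pi * tx$kRad * u + tx$phase[2]) +
                     cos(pi * tx$kRad2 * u + tx$phase[3]))
    img[annulus] <- params@muMyocardium * (1 + amp * myoTex[annulus])
    frames[, , t] <- img
    maskArr[, , t] <- annulus
  }
  storage.mode(maskArr) <- "integer"
  new("CineSequence", subjectID = paste0("phantom", params@textureSeed),
      frames = frames, masks = maskArr,
      pixelSpacing = params@pixelSpacing,
      intensityRange = range(frames))
}

#' Rescale a sequence to the unit interval
#'
#' Applies one affine map, defined by the subject's global intensity minimum
#' and maximum over all frames, to every frame. This makes noise standard
#' deviations interpretable as fractions of the intensity range (so values
#' such as 0.010-0.040 are meaningful regardless of the scanner's intensity
#' scale). Masks are unchanged; the original range is recorded.
#'
#' @param seq a [CineSequence-class].
#' @return The rescaled [CineSequence-class] with values in [0, 1].
#' @export
rescaleToUnit <- function(seq) {
  rng <- range(seq@frames)
  if (rng[2] <= rng[1])
    stop("flat image: intensity range is degenerate, cannot rescale")
  new("CineSequence", subjectID = seq@subjectID,
      frames = (seq@frames - rng[1]) / (rng[2] - rng[1]),
      masks = seq@masks, pixelSpacing = seq@pixelSpacing,
      intensityRange = rng)
}

#' Add seeded Gaussian noise to a sequence
#'
#' Every pixel of every frame receives an independent zero-mean Gaussian draw
#' with standard deviation `noiseStd` (in the units of the rescaled
#' intensities). Masks are untouched. The same `(seq, noiseStd, seed)` always
#' yields a bitwise-identical result; `noiseStd = 0` returns the input.
#'
#' @param seq a [CineSequence-class], conventionally rescaled to [0, 1].
#' @param noiseStd noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return A noisy [CineSequence-class].
#' @export
addGaussianNoise <- function(seq, noiseStd, seed) {
  if (noiseStd < 0) stop("noiseStd must be non-negative")
  if (noiseStd == 0) return(seq)
  d <- dim(seq@frames)
  noise <- withSeed(seed, array(rnorm(prod(d), 0, noiseStd), d))
  new("CineSequence", subjectID = seq@subjectID,
      frames = seq@frames + noise, masks = seq@masks,
      pixelSpacing = seq@pixelSpacing, intensityRange = seq@intensityRange)
}

#' Build the full set of noise instances for one subject
#'
#' Produces the reference (no added noise) plus, for each noise level and
#' replicate, one noisy realization whose seed is derived deterministically
#' from `(baseSeed, subject, level index, replicate index)`. With four levels
#' and ten replicates this yields the canonical 41 instances per subject.
#'
#' @param seq the subject's reference [CineSequence-class] (rescaled).
#' @param levels strictly increasing noise standard deviations; the study's
#'   levels are `c(0.010, 0.020, 0.030, 0.040)`.
#' @param replicates replicates per level (>= 1).
#' @param baseSeed integer base seed.
#' @return A list of [NoiseInstance-class], reference first, then levels in
#'   increasing-std order (labels `"L1"`, `"L2"`, ...), replicates in order.
#' @export
makeNoiseInstances <- function(seq, levels = c(0.010, 0.020, 0.030, 0.040),
                               replicates = 10L, baseSeed = 1L) {
  if (!length(levels)) stop("levels must be nonempty")
  if (any(levels < 0)) stop("levels must be non-negative")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  if (!isCount(replicates)) stop("replicates must be a positive count")
  out <- vector("list", 1L + length(levels) * replicates)
  out[[1]] <- new("NoiseInstance", subjectID = seq@subjectID,
                  levelLabel = "reference", noiseStd = 0,
                  replicateIndex = 0L, seed = NA_integer_, sequence = seq)
  k <- 2L
  for (li in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      sd <- instanceSeed(baseSeed, seq@subjectID, li, r)
      out[[k]] <- new("NoiseInstance", subjectID = seq@subjectID,
                      levelLabel = sprintf("L%d", li),
                      noiseStd = levels[li], replicateIndex = as.integer(r),
                      seed = sd,
                      sequence = addGaussianNoise(seq, levels[li], sd))
      k <- k + 1L
    }
  }
  out
}

#' Empirical signal-to-noise ratio
#'
#' Mean in-mask (myocardial) intensity over all frames divided by the noise
#' standard deviation, the usual SNR convention for controlled simulations.
#'
#' @param seq a [CineSequence-class].
#' @param noiseStd noise standard deviation (> 0).
#' @return The SNR as a single number.
#' @export
empiricalSNR <- function(seq, noiseStd) {
  if (noiseStd <= 0) stop("SNR undefined for noiseStd <= 0")
  mean(seq@frames[seq@masks == 1L]) / noiseStd
}

# Per-class phantom physiology used by simulateCohort: contraction fraction
# and wall-thickness multiplier, loosely emulating normal function, reduced
# contraction (infarct-like, dilated-like) and hypertrophic wall thickening.
cohortClassEffects <- function(nClasses) {
  contraction <- c(0.30, 0.18, 0.12, 0.36, 0.24)
  thickness <- c(1.00, 0.95, 0.75, 1.40, 1.05)
  idx <- ((seq_len(nClasses) - 1L) %% 5L) + 1L
  list(contraction = contraction[idx], thickness = thickness[idx])
}

#' Simulate a heterogeneous phantom cohort
#'
#' Draws per-subject geometry from uniform ranges around class-specific
#' physiology (contraction fraction and wall thickness differ by class,
#' emulating the functional differences between diagnostic groups) and varies
#' the frame count over `framesRange` to emulate the temporal-resolution
#' heterogeneity of multi-site cine data. Deterministic given `cohortSeed`.
#'
#' @param nSubjects number of subjects.
#' @param nClasses number of diagnostic classes; subjects are assigned
#'   cyclically so classes stay balanced.
#' @param framesRange integer range of frames per cardiac cycle.
#' @param gridSize phantom grid size in pixels.
#' @param cohortSeed integer seed for the cohort draw.
#' @return A list with one element per subject: `subjectID`, `classLabel`,
#'   `params` ([PhantomParams-class]) and `sequence` (the raw reference
#'   [CineSequence-class]).
#' @export
simulateCohort <- function(nSubjects, nClasses = 5L,
                           framesRange = c(12L, 50L), gridSize = 128L,
                           cohortSeed = 1L) {
  stopifnot(isCount(nSubjects), isCount(nClasses))
  eff <- cohortClassEffects(nClasses)
  draws <- withSeed(cohortSeed, lapply(seq_len(nSubjects), function(i) list(
    rEndo = runif(1, 15, 21),
    thickJitter = runif(1, 0.9, 1.1),
    contrJitter = runif(1, -0.03, 0.03),
    muJitter = runif(3, 0.9, 1.1),
    textureSeed = sample.int(2^30, 1),
    nFrames = sample(seq(framesRange[1], framesRange[2]), 1)
  )))
  lapply(seq_len(nSubjects), function(i) {
    cls <- ((i - 1L) %% nClasses) + 1L
    dr <- draws[[i]]
    thick <- min(12 * eff$thickness[cls] * dr$thickJitter,
                 gridSize / 2 - dr$rEndo - 2)
    params <- phantomParams(
      gridSize = gridSize, nFrames = dr$nFrames,
      rEndoED = dr$rEndo, rEpiED = dr$rEndo + thick,
      contractionFraction = max(0.05, eff$contraction[cls] + dr$contrJitter),
      muBackground = 60 * dr$muJitter[1],
      muMyocardium = 200 * dr$muJitter[2],
      muBloodpool = 420 * dr$muJitter[3],
      textureSeed = dr$textureSeed)
    seqc <- generatePhantom(params)
    seqc@subjectID <- sprintf("S%03d", i)
    list(subjectID = sprintf("S%03d", i),
         classLabel = sprintf("C%d", cls),
         params = params, sequence = seqc)
  })
}

#' Designed feature battery with graded noise sensitivity
#'
#' Validation utility: from the long feature table of a single base feature,
#' constructs synthetic features whose deviation from the subject's reference
#' curve is amplified by known multipliers. After reference-anchored
#' normalization their stability scores scale in proportion, so the true
#' stability ordering is known by construction and ranking recovery can be
#' tested.
#'
#' @param featureTable long feature table (columns `subject_id`,
#'   `level_label`, `replicate_index`, `frame_index`, `feature_id`, `value`)
#'   restricted to one `feature_id`.
#' @param multipliers noise-sensitivity multipliers, default `c(1, 2, 4, 8)`.
#' @return A long feature table with one synthetic feature per multiplier,
#'   named `<base>_x<multiplier>`.
#' @export
syntheticFeatureBattery <- function(featureTable, multipliers = c(1, 2, 4, 8)) {
  stopifnot(length(unique(featureTable$feature_id)) == 1L)
  base <- featureTable$feature_id[1]
  ref <- featureTable[featureTable$level_label == "reference", ]
  refKey <- paste(ref$subject_id, ref$frame_index)
  refVal <- ref$value[match(paste(featureTable$subject_id,
                                  featureTable$frame_index), refKey)]
  if (anyNA(refVal)) stop("reference curve missing for some subject/frame")
  out <- do.call(rbind, lapply(multipliers, function(m) {
    tb <- featureTable
    tb$feature_id <- sprintf("%s_x%g", base, m)
    tb$value <- refVal + m * (featureTable$value - refVal)
    tb
  }))
  rownames(out) <- NULL
  out
}
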