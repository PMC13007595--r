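#' Phantom geometry and appearance parameters
#'
#' Parameters of the synthetic contracting-annulus cine phantom that stands in
#' for a mid-ventricular short-axis slice: a bright blood pool surrounded by a
#' myocardial annulus that contracts and thickens periodically over the
#' cardiac cycle, on a darker background.
#'
#' @slot gridSize integer, pixels per side of the square frame.
#' @slot nFrames integer number of cardiac frames T (12-50).
#' @slot center numeric length 2, (row, col) centre of the annulus in pixels.
#' @slot rEndoED end-diastolic endocardial radius in pixels.
#' @slot rEpiED end-diastolic epicardial radius in pixels.
#' @slot contractionFraction unitless in [0, 1): peak fractional reduction of
#'   the endocardial radius at end-systole.
#' @slot muBackground,muMyocardium,muBloodpool mean class intensities
#'   (arbitrary units).
#' @slot textureAmplitude unitless relative amplitude of the smooth texture
#'   modulation.
#' @slot textureSeed integer seed fixing the texture field of the subject.
#' @slot pixelSpacing in-plane pixel spacing in mm.
#' @export
setClass("PhantomParams", representation(
  gridSize = "integer",
  nFrames = "integer",
  center = "numeric",
  rEndoED = "numeric",
  rEpiED = "numeric",
  contractionFraction = "numeric",
  muBackground = "numeric",
  muMyocardium = "numeric",
  muBloodpool = "numeric",
  textureAmplitude = "numeric",
  textureSeed = "integer",
  pixelSpacing = "numeric"
))

setValidity("PhantomParams", function(object) {
  msg <- character(0)
  if (object@nFrames < 12L) msg <- c(msg, "nFrames must be at least 12")
  if (object@nFrames > 50L) msg <- c(msg, "nFrames must be at most 50")
  if (!(object@rEndoED > 0)) msg <- c(msg, "rEndoED must be positive")
  if (!(object@rEndoED < object@rEpiED))
    msg <- c(msg, "rEndoED must be smaller than rEpiED")
  if (!(object@rEpiED < object@gridSize / 2))
    msg <- c(msg, "rEpiED must be smaller than gridSize/2")
  if (object@contractionFraction < 0 || object@contractionFraction >= 1)
    msg <- c(msg, "contractionFraction must lie in [0, 1)")
  if (any(c(object@muBackground, object@muMyocardium, object@muBloodpool) < 0))
    msg <- c(msg, "class intensities must be non-negative")
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be two finite numbers")
  if (object@pixelSpacing <= 0) msg <- c(msg, "pixelSpacing must be positive")
  if (length(msg)) msg else TRUE
})

#' One subject's cine sequence
#'
#' A 2D+t image stack (frames of one cardiac cycle) with a per-frame binary
#' myocardial region-of-interest mask. Frames and masks are stored as
#' `row x col x frame` arrays; time is the last dimension.
#'
#' @slot subjectID character subject identifier.
#' @slot frames numeric 3D array of intensities.
#' @slot masks integer 3D array of the same dimension, values in {0, 1}.
#' @slot pixelSpacing in-plane pixel spacing in mm.
#' @slot intensityRange numeric length 2: (min, max) of the subject's
#'   reference sequence, recorded when the sequence is rescaled to [0, 1].
#' @export
setClass("CineSequence", representation(
  subjectID = "character",
  frames = "array",
  masks = "array",
  pixelSpacing = "numeric",
  intensityRange = "numeric"
))

setValidity("CineSequence", function(object) {
  msg <- character(0)
  df <- dim(object@frames); dm <- dim(object@masks)
  if (length(df) != 3L || length(dm) != 3L)
    return("frames and masks must be 3D arrays (row, col, frame)")
  if (!all(df == dm)) msg <- c(msg, "frames and masks dimensions differ")
  if (!all(object@masks %in% c(0L, 1L)))
    msg <- c(msg, "masks must contain only 0 and 1")
  fg <- apply(object@masks, 3, sum)
  if (any(fg < 16))
    msg <- c(msg, "every frame mask needs at least 16 foreground pixels")
  if (any(!is.finite(object@frames))) msg <- c(msg, "frames must be finite")
  if (length(object@intensityRange) != 2L)
    msg <- c(msg, "intensityRange must have length 2")
  if (length(msg)) msg else TRUE
})

#' One noise realization of a cine sequence
#'
#' Tags a [CineSequence-class] with its noise level, replicate index and the
#' seed that produced it. The unmodified original carries the level label
#' `"reference"`, noise standard deviation 0 and replicate index 0.
#'
#' @slot subjectID character subject identifier.
#' @slot levelLabel `"reference"` or `"L1"`, `"L2"`, ... in increasing-noise
#'   order.
#' @slot noiseStd Gaussian noise standard deviation as a fraction of the
#'   [0, 1] rescaled intensity range (0 for the reference).
#' @slot replicateIndex integer, 0 for the reference, otherwise >= 1.
#' @slot seed integer seed of this realization (NA for the reference).
#' @slot sequence the noisy [CineSequence-class].
#' @export
setClass("NoiseInstance", representation(
  subjectID = "character",
  levelLabel = "character",
  noiseStd = "numeric",
  replicateIndex = "integer",
  seed = "integer",
  sequence = "CineSequence"
))

setValidity("NoiseInstance", function(object) {
  msg <- character(0)
  ref <- identical(object@levelLabel, "reference")
  if (ref && (object@noiseStd != 0 || object@replicateIndex != 0L))
    msg <- c(msg, "reference instance must have noiseStd 0 and replicate 0")
  if (!ref && object@replicateIndex < 1L)
    msg <- c(msg, "non-reference replicateIndex must be >= 1")
  if (object@noiseStd < 0) msg <- c(msg, "noiseStd must be non-negative")
  if (!identical(object@subjectID, object@sequence@subjectID))
    msg <- c(msg, "subjectID disagrees with the wrapped sequence")
  if (length(msg)) msg else TRUE
})

#' Radiomic feature extraction configuration
#'
#' Controls intensity discretization, the image filters applied before
#' extraction and the feature families computed in the region of interest.
#'
#' @slot nBins integer number of discretization bins B (>= 2).
#' @slot glcmOffsets integer matrix, one `(drow, dcol)` offset per row.
#' @slot glcmSymmetric logical, symmetrize co-occurrence matrices.
#' @slot zoneConnectivity 4 or 8, pixel connectivity for size zones.
#' @slot lbpRadius neighbourhood radius of the local binary pattern, pixels.
#' @slot lbpPoints number of circular LBP sampling points P (>= 4).
#' @slot filters subset of `c("original", "wavelet", "lbp2d")`.
#' @slot families subset of `c("firstorder", "glcm", "glszm")`.
#' @export
setClass("ExtractionConfig", representation(
  nBins = "integer",
  glcmOffsets = "matrix",
  glcmSymmetric = "logical",
  zoneConnectivity = "integer",
  lbpRadius = "numeric",
  lbpPoints = "integer",
  filters = "character",
  families = "character"
))

setValidity("ExtractionConfig", function(object) {
  msg <- character(0)
  if (object@nBins < 2L) msg <- c(msg, "nBins must be at least 2")
  off <- object@glcmOffsets
  if (ncol(off) != 2L || nrow(off) < 1L)
    msg <- c(msg, "glcmOffsets must be a k x 2 matrix")
  if (any(off[, 1] == 0 & off[, 2] == 0))
    msg <- c(msg, "glcmOffsets must be nonzero")
  if (nrow(off) > 1) {
    key <- paste(off[, 1], off[, 2]); opp <- paste(-off[, 1], -off[, 2])
    if (any(duplicated(key)) || any(opp %in% key))
      msg <- c(msg, "glcmOffsets must be pairwise distinct and non-opposite")
  }
  if (!object@zoneConnectivity %in% c(4L, 8L))
    msg <- c(msg, "zoneConnectivity must be 4 or 8")
  if (object@lbpRadius < 1) msg <- c(msg, "lbpRadius must be >= 1")
  if (object@lbpPoints < 4L) msg <- c(msg, "lbpPoints must be >= 4")
  if (!all(object@filters %in% c("original", "wavelet", "lbp2d")))
    msg <- c(msg, "unknown filter name")
  if (!all(object@families %in% c("firstorder", "glcm", "glszm")))
    msg <- c(msg, "unknown family name")
  if (!length(object@filters)) msg <- c(msg, "at least one filter required")
  if (!length(object@families)) msg <- c(msg, "at least one family required")
  if (length(msg)) msg else TRUE
})
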