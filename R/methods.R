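#' @describeIn CineSequence-class subject identifier.
setMethod("subjectID", "CineSequence", function(x) x@subjectID)

#' @describeIn CineSequence-class intensity array (row x col x frame).
setMethod("frames", "CineSequence", function(x) x@frames)

#' @describeIn CineSequence-class binary mask array (row x col x frame).
setMethod("masks", "CineSequence", function(x) x@masks)

#' @describeIn CineSequence-class number of frames T.
setMethod("nFrames", "CineSequence", function(x) dim(x@frames)[3])

#' @describeIn CineSequence-class in-plane pixel spacing (mm).
setMethod("pixelSpacing", "CineSequence", function(x) x@pixelSpacing)

#' @describeIn CineSequence-class (min, max) of the reference sequence.
setMethod("intensityRange", "CineSequence", function(x) x@intensityRange)

setMethod("show", "CineSequence", function(object) {
  d <- dim(object@frames)
  cat("CineSequence '", object@subjectID, "': ", d[1], "x", d[2],
      " pixels, ", d[3], " frames, spacing ", object@pixelSpacing,
      " mm\n", sep = "")
  cat("  intensity range [", format(object@intensityRange[1]), ", ",
      format(object@intensityRange[2]), "], ROI ",
      sum(object@masks[, , 1]), " px in frame 1\n", sep = "")
})

#' @describeIn NoiseInstance-class subject identifier.
setMethod("subjectID", "NoiseInstance", function(x) x@subjectID)

#' @describeIn NoiseInstance-class noise level label.
setMethod("levelLabel", "NoiseInstance", function(x) x@levelLabel)

#' @describeIn NoiseInstance-class Gaussian noise standard deviation.
setMethod("noiseStd", "NoiseInstance", function(x) x@noiseStd)

#' @describeIn NoiseInstance-class replicate index (0 for the reference).
setMethod("replicateIndex", "NoiseInstance", function(x) x@replicateIndex)

#' @describeIn NoiseInstance-class the wrapped noisy sequence.
setMethod("cineSequence", "NoiseInstance", function(x) x@sequence)

#' @describeIn NoiseInstance-class number of frames of the wrapped sequence.
setMethod("nFrames", "NoiseInstance", function(x) nFrames(x@sequence))

setMethod("show", "NoiseInstance", function(object) {
  cat("NoiseInstance '", object@subjectID, "' level ", object@levelLabel,
      " (std ", format(object@noiseStd), ", replicate ",
      object@replicateIndex, ")\n", sep = "")
})

setMethod("show", "PhantomParams", function(object) {
  cat("PhantomParams: ", object@gridSize, "x", object@gridSize, " px, ",
      object@nFrames, " frames, endo/epi ", object@rEndoED, "/",
      object@rEpiED, " px, contraction ", object@contractionFraction, "\n",
      sep = "")
})

setMethod("show", "ExtractionConfig", function(object) {
  cat("ExtractionConfig: B=", object@nBins, ", filters {",
      paste(object@filters, collapse = ", "), "}, families {",
      paste(object@families, collapse = ", "), "}\n", sep = "")
})
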