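#' @rdname CineSequence-class
#' @param object,x a package object.
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname CineSequence-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname CineSequence-class
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname CineSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname CineSequence-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname CineSequence-class
#' @export
setGeneric("intensityRange", function(x) standardGeneric("intensityRange"))

#' @rdname NoiseInstance-class
#' @export
setGeneric("levelLabel", function(x) standardGeneric("levelLabel"))

#' @rdname NoiseInstance-class
#' @export
setGeneric("noiseStd", function(x) standardGeneric("noiseStd"))

#' @rdname NoiseInstance-class
#' @export
setGeneric("replicateIndex", function(x) standardGeneric("replicateIndex"))

#' @rdname NoiseInstance-class
#' @export
setGeneric("cineSequence", function(x) standardGeneric("cineSequence"))
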