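#' Construct an extraction configuration
#'
#' Defaults: 32 grey levels, the four standard 2D co-occurrence offsets
#' (0 deg, 90 deg, 45 deg, 135 deg) with symmetrization, 8-connected size
#' zones, an 8-point radius-1 local binary pattern, all three filters and all
#' three feature families.
#'
#' @param nBins number of discretization bins B.
#' @param glcmOffsets integer matrix of `(drow, dcol)` offsets.
#' @param glcmSymmetric symmetrize co-occurrence matrices.
#' @param zoneConnectivity 4 or 8.
#' @param lbpRadius,lbpPoints local binary pattern geometry.
#' @param filters subset of `c("original", "wavelet", "lbp2d")`.
#' @param families subset of `c("firstorder", "glcm", "glszm")`.
#' @return A validated [ExtractionConfig-class].
#' @export
extractionConfig <- function(nBins = 32L,
                             glcmOffsets = rbind(c(0L, 1L), c(1L, 0L),
                                                 c(1L, 1L), c(1L, -1L)),
                             glcmSymmetric = TRUE,
                             zoneConnectivity = 8L,
                             lbpRadius = 1, lbpPoints = 8L,
                             filters = c("original", "wavelet", "lbp2d"),
                             families = c("firstorder", "glcm", "glszm")) {
  storage.mode(glcmOffsets) <- "integer"
  new("ExtractionConfig", nBins = as.integer(nBins),
      glcmOffsets = glcmOffsets, glcmSymmetric = glcmSymmetric,
      zoneConnectivity = as.integer(zoneConnectivity),
      lbpRadius = lbpRadius, lbpPoints = as.integer(lbpPoints),
      filters = filters, families = families)
}

# Filter images derived from one frame, named as they appear in feature ids.
filterImages <- function(frame, config) {
  imgs <- list()
  if ("original" %in% config@filters) imgs$original <- frame
  if ("wavelet" %in% config@filters) {
    wb <- waveletSubbands(frame)
    names(wb) <- paste0("wavelet-", names(wb))
    imgs <- c(imgs, wb)
  }
  if ("lbp2d" %in% config@filters)
    imgs$lbp2d <- lbpMap(frame, config@lbpRadius, config@lbpPoints)
  imgs
}

# Features of one filter image restricted to the mask.
familyFeatures <- function(img, mask, config) {
  vals <- img[mask == 1]
  lev <- discretize(vals, config@nBins)
  levImg <- matrix(NA_integer_, nrow(img), ncol(img))
  levImg[mask == 1] <- lev
  out <- numeric(0)
  if ("firstorder" %in% config@families) {
    f <- firstOrderFeatures(vals, lev)
    names(f) <- paste0("firstorder_", names(f))
    out <- c(out, f)
  }
  if ("glcm" %in% config@families) {
    f <- glcmFeatures(glcmMatrix(levImg, mask, config), config@nBins)
    names(f) <- paste0("glcm_", names(f))
    out <- c(out, f)
  }
  if ("glszm" %in% config@families) {
    f <- glszmFeatures(glszmMatrix(levImg, mask, config@zoneConnectivity),
                       length(vals))
    names(f) <- paste0("glszm_", names(f))
    out <- c(out, f)
  }
  out
}

#' Extract the radiomic feature vector of one frame
#'
#' Applies every enabled filter to the frame, discretizes the in-mask values
#' of each filter image, computes every enabled family and concatenates the
#' results under `<filter>_<family>_<Feature>` names. The feature id set is
#' a function of the configuration only, so it is identical across frames
#' and noise instances.
#'
#' @param frame numeric matrix.
#' @param mask 0-1 matrix of the same shape with a nonempty foreground.
#' @param config an [ExtractionConfig-class].
#' @return A named numeric vector (all values finite).
#' @export
extractFrame <- function(frame, mask, config) {
  if (!any(mask == 1)) stop("empty mask")
  imgs <- filterImages(frame, config)
  out <- unlist(lapply(names(imgs), function(nm) {
    f <- tryCatch(familyFeatures(imgs[[nm]], mask, config),
                  error = function(e) stop("filter '", nm, "': ",
                                           conditionMessage(e), call. = FALSE))
    names(f) <- paste0(nm, "_", names(f))
    f
  }))
  if (any(!is.finite(out)))
    stop("non-finite feature value: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Extract the long feature table of a set of noise instances
#'
#' Runs [extractFrame()] on every frame of every instance and stacks the
#' results into the long per-instance feature table used by the curve
#' assembly stage.
#'
#' @param instances list of [NoiseInstance-class] (e.g. from
#'   [makeNoiseInstances()]).
#' @param config an [ExtractionConfig-class].
#' @return A data.frame with columns `subject_id`, `level_label`,
#'   `replicate_index`, `frame_index` (1-based), `feature_id`, `value`.
#' @export
extractFeatures <- function(instances, config) {
  rows <- lapply(instances, function(inst) {
    sq <- cineSequence(inst)
    Tn <- nFrames(sq)
    per <- lapply(seq_len(Tn), function(t)
      extractFrame(frames(sq)[, , t], masks(sq)[, , t], config))
    ids <- names(per[[1]])
    data.frame(subject_id = subjectID(inst),
               level_label = levelLabel(inst),
               replicate_index = replicateIndex(inst),
               frame_index = rep(seq_len(Tn), each = length(ids)),
               feature_id = rep(ids, Tn),
               value = unlist(per, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
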