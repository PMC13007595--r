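#' Write a cine sequence as NIfTI image + mask
#'
#' Stores the 2D+t stack with time as the last dimension and the in-plane
#' pixel spacing in the header; the mask is written with identical geometry.
#'
#' @param seq a [CineSequence-class].
#' @param imagePath,maskPath output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, `c(imagePath, maskPath)`.
#' @export
writeCineNifti <- function(seq, imagePath, maskPath) {
  dir.create(dirname(imagePath), recursive = TRUE, showWarnings = FALSE)
  sp <- seq@pixelSpacing
  img <- RNifti::asNifti(seq@frames)
  msk <- RNifti::asNifti(seq@masks)
  RNifti::pixdim(img) <- c(sp, sp, 1)
  RNifti::pixdim(msk) <- c(sp, sp, 1)
  RNifti::writeNifti(img, imagePath)
  RNifti::writeNifti(msk, maskPath)
  invisible(c(imagePath, maskPath))
}

#' Read a cine sequence from NIfTI image + mask
#'
#' Validates that image and mask agree in shape and spacing and that the
#' mask is binary, then rebuilds the [CineSequence-class] (intensity range
#' recomputed from the data read).
#'
#' @param imagePath,maskPath paths written by [writeCineNifti()].
#' @param subjectID subject identifier to attach; defaults to the name of
#'   the containing directory.
#' @return A [CineSequence-class].
#' @export
readCineNifti <- function(imagePath, maskPath, subjectID = NULL) {
  img <- RNifti::readNifti(imagePath)
  msk <- RNifti::readNifti(maskPath)
  di <- dim(img); dm <- dim(msk)
  if (length(di) != 3 || !identical(di, dm))
    stop("geometry error: image dim ", paste(di, collapse = "x"),
         " vs mask dim ", paste(dm, collapse = "x"))
  spI <- RNifti::pixdim(img)[1:2]; spM <- RNifti::pixdim(msk)[1:2]
  if (any(abs(spI - spM) > 1e-6))
    stop("geometry error: image and mask pixel spacing differ")
  ma <- array(as.numeric(msk), dm)
  if (!all(ma %in% c(0, 1))) stop("mask error: mask is not binary")
  storage.mode(ma) <- "integer"
  fa <- array(as.numeric(img), di)
  if (is.null(subjectID)) subjectID <- basename(dirname(imagePath))
  new("CineSequence", subjectID = subjectID, frames = fa, masks = ma,
      pixelSpacing = spI[1], intensityRange = range(fa))
}

# Paths of one instance inside the NIfTI tree: <subject>/<level>_<rep>.nii.gz
# (reference.nii.gz for the original), mask alongside as *_mask.nii.gz.
instancePaths <- function(dir, subjectID, levelLabel, replicateIndex) {
  stem <- if (levelLabel == "reference") "reference"
          else sprintf("%s_%02d", levelLabel, replicateIndex)
  c(image = file.path(dir, subjectID, paste0(stem, ".nii.gz")),
    mask = file.path(dir, subjectID, paste0(stem, "_mask.nii.gz")))
}

#' Write a set of noise instances and their manifest
#'
#' Writes every instance as NIfTI image + mask under
#' `<dir>/<subject>/<level>_<replicate>.nii.gz` (the reference as
#' `reference.nii.gz`) and returns the cohort manifest rows.
#'
#' @param instances list of [NoiseInstance-class].
#' @param dir output directory.
#' @return A data.frame with columns `subject_id`, `n_frames`,
#'   `level_label`, `noise_std`, `replicate_index`, `seed`, `image_path`,
#'   `mask_path` (paths relative to `dir`).
#' @export
writeNoiseInstances <- function(instances, dir) {
  rows <- lapply(instances, function(inst) {
    p <- instancePaths(dir, subjectID(inst), levelLabel(inst),
                       replicateIndex(inst))
    writeCineNifti(cineSequence(inst), p["image"], p["mask"])
    data.frame(subject_id = subjectID(inst),
               n_frames = nFrames(inst),
               level_label = levelLabel(inst),
               noise_std = noiseStd(inst),
               replicate_index = replicateIndex(inst),
               seed = inst@seed,
               image_path = sub(paste0("^", dir, "/?"), "", p["image"]),
               mask_path = sub(paste0("^", dir, "/?"), "", p["mask"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read noise instances back from a manifest
#'
#' @param manifest data.frame as returned by [writeNoiseInstances()].
#' @param dir directory the manifest paths are relative to.
#' @return A list of [NoiseInstance-class].
#' @export
readNoiseInstances <- function(manifest, dir) {
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    sq <- readCineNifti(file.path(dir, r$image_path),
                        file.path(dir, r$mask_path),
                        subjectID = r$subject_id)
    new("NoiseInstance", subjectID = r$subject_id,
        levelLabel = r$level_label, noiseStd = r$noise_std,
        replicateIndex = as.integer(r$replicate_index),
        seed = if (is.na(r$seed)) NA_integer_ else as.integer(r$seed),
        sequence = sq)
  })
}
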