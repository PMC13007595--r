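# Canonical ordering of noise level labels: reference first, then by the
# numeric suffix of "L<k>" labels, then anything else lexicographically.
levelRank <- function(labels) {
  u <- unique(labels)
  r <- rep(3L, length(u))
  r[u == "reference"] <- 1L
  isL <- grepl("^L[0-9]+$", u)
  r[isL] <- 2L
  num <- rep(0, length(u))
  num[isL] <- as.numeric(sub("^L", "", u[isL]))
  key <- integer(length(u))
  key[order(r, num, u)] <- seq_along(u)
  key[match(labels, u)]
}

#' Assemble feature curves from the long feature table
#'
#' Combines the per-frame feature values of each (subject, feature, noise
#' instance) into one ordered curve. The table must be complete: every
#' instance must carry every feature at every frame of its subject.
#'
#' @param featureTable long table from [extractFeatures()].
#' @return A data.frame with one row per curve: `subject_id`, `feature_id`,
#'   `level_label`, `replicate_index` and a list column `values` holding the
#'   length-T curve in frame order.
#' @export
buildCurves <- function(featureTable) {
  ft <- featureTable
  ord <- order(ft$subject_id, ft$feature_id, levelRank(ft$level_label),
               ft$replicate_index, ft$frame_index)
  ft <- ft[ord, ]
  key <- paste(ft$subject_id, ft$feature_id, ft$level_label,
               ft$replicate_index, sep = "\r")
  first <- !duplicated(key)
  gid <- cumsum(first)
  nT <- tapply(ft$frame_index, ft$subject_id, max)
  head <- ft[first, c("subject_id", "feature_id", "level_label",
                      "replicate_index")]
  lens <- tabulate(gid)
  expLen <- as.vector(nT[head$subject_id])
  bad <- which(lens != expLen)
  # frame indices must be exactly 1..T within every group
  okFrames <- ft$frame_index == stats::ave(ft$frame_index, gid,
                                           FUN = seq_along)
  if (length(bad) || !all(okFrames)) {
    if (!length(bad)) bad <- gid[which(!okFrames)[1]]
    b <- head[bad[1], ]
    stop("incomplete feature table: instance (", b$subject_id, ", ",
         b$level_label, ", replicate ", b$replicate_index,
         ") is missing frames of feature ", b$feature_id)
  }
  # every instance of a subject must carry the subject's full feature set
  instKey <- paste(head$subject_id, head$level_label, head$replicate_index,
                   sep = "\r")
  nFeatPerInst <- table(instKey)
  nFeatPerSubj <- tapply(head$feature_id, head$subject_id,
                         function(x) length(unique(x)))
  subjOfInst <- head$subject_id[match(names(nFeatPerInst), instKey)]
  short <- which(as.vector(nFeatPerInst) != nFeatPerSubj[subjOfInst])
  if (length(short)) {
    ik <- names(nFeatPerInst)[short[1]]
    have <- head$feature_id[instKey == ik]
    all <- unique(head$feature_id[head$subject_id == subjOfInst[short[1]]])
    stop("incomplete feature table: instance (", gsub("\r", ", ", ik),
         ") is missing feature ", setdiff(all, have)[1])
  }
  head$values <- unname(split(ft$value, gid))
  rownames(head) <- NULL
  head
}

#' Reference-anchored curve normalization
#'
#' For every (subject, feature), computes the mean and standard deviation
#' (population denominator T) of the least-noisy curve - the reference
#' instance - and maps every curve of that subject and feature, reference
#' and noisy alike, through `v -> (v - mu_ref) / sigma_ref`. The reference
#' curve thus has mean 0 and standard deviation 1, and all noise instances
#' are expressed on that scale. Features whose reference curve shows no
#' variation over the cardiac cycle (`sigma_ref == 0`) cannot be normalized
#' and are excluded for that subject.
#'
#' @param curves curve set from [buildCurves()].
#' @return A list with `curves` (normalized curve set, excluded features
#'   dropped) and `params` (data.frame `subject_id`, `feature_id`, `mu_ref`,
#'   `sigma_ref`, `excluded`).
#' @export
normalizeCurves <- function(curves) {
  key <- paste(curves$subject_id, curves$feature_id, sep = "\r")
  refRows <- which(curves$level_label == "reference")
  refKey <- key[refRows]
  if (anyNA(match(unique(key), refKey))) {
    miss <- unique(key)[is.na(match(unique(key), refKey))][1]
    stop("missing reference curve for subject/feature ",
         gsub("\r", " / ", miss))
  }
  mu <- vapply(curves$values[refRows], mean, numeric(1))
  sig <- vapply(curves$values[refRows], function(v)
    sqrt(mean((v - mean(v))^2)), numeric(1))
  params <- data.frame(subject_id = curves$subject_id[refRows],
                       feature_id = curves$feature_id[refRows],
                       mu_ref = mu, sigma_ref = sig,
                       excluded = sig == 0, stringsAsFactors = FALSE)
  m <- match(key, refKey)
  keep <- !params$excluded[m]
  out <- curves[keep, ]
  out$values <- Map(function(v, mu, sg) (v - mu) / sg,
                    out$values, mu[m][keep], sig[m][keep])
  rownames(out) <- NULL
  list(curves = out, params = params)
}
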