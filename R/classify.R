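#' Uniformly subsample a curve to k frames
#'
#' Picks `k` frame indices spread uniformly over `0..T-1` via
#' `i_j = round(j * (T - 1) / (k - 1))` for `j = 0..k-1` (round half up),
#' always including both endpoints, and returns the curve values at those
#' frames. Brings curves of different lengths onto a common 12-frame grid
#' for the per-feature classifiers.
#'
#' @param values numeric curve of length T >= k.
#' @param k target number of frames (default 12).
#' @return A numeric vector of length `k`.
#' @export
subsampleCurve <- function(values, k = 12L) {
  Tn <- length(values)
  if (k < 2) stop("k must be at least 2")
  if (Tn < k) stop("insufficient frames: T = ", Tn, " < k = ", k)
  j <- seq_len(k) - 1
  idx <- floor(j * (Tn - 1) / (k - 1) + 0.5)   # round half up
  if (any(diff(idx) <= 0)) stop("subsample indices not strictly increasing")
  values[idx + 1]
}

#' Class-balanced train/validation/test split
#'
#' Seeded random partition of subjects into train, validation and test sets
#' with exact per-class counts (the study design: 12/4/4 per class for five
#' classes, i.e. 60/20/20 overall).
#'
#' @param labels named character vector: subject id -> class label.
#' @param counts integer vector `c(train, validation, test)` per class.
#' @param seed integer seed.
#' @return A data.frame with columns `subject_id`, `class_label`,
#'   `partition`.
#' @export
splitSubjects <- function(labels, counts = c(12L, 4L, 4L), seed = 1L) {
  stopifnot(length(counts) == 3, all(counts >= 1))
  parts <- rep(c("train", "validation", "test"), counts)
  out <- lapply(sort(unique(labels)), function(cl) {
    ids <- names(labels)[labels == cl]
    if (length(ids) < sum(counts))
      stop("stratification error: class ", cl, " has ", length(ids),
           " subjects, needs ", sum(counts))
    picked <- withSeed(stableHash("split", seed, cl),
                       sample(ids, sum(counts)))
    data.frame(subject_id = picked, class_label = cl, partition = parts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Build the row matrix (instances x k frames) and labels for a set of
# subjects, from the normalized curves of one feature.
curveRows <- function(curves, split, partition, referenceOnly, k) {
  subj <- split$subject_id[split$partition == partition]
  cls <- stats::setNames(split$class_label, split$subject_id)
  sel <- curves[curves$subject_id %in% subj, ]
  if (referenceOnly) sel <- sel[sel$level_label == "reference", ]
  if (!nrow(sel)) stop("no curves for partition ", partition)
  x <- do.call(rbind, lapply(sel$values, subsampleCurve, k = k))
  colnames(x) <- paste0("f", seq_len(k))
  list(x = as.data.frame(x), y = factor(cls[sel$subject_id]),
       subjects = sel$subject_id)
}

#' Evaluate one feature's decision tree
#'
#' The study-design validation of the stability-accuracy link: one
#' classification tree per feature, trained on the 12-frame subsampled
#' normalized curves of all noise instances of the training subjects,
#' validated on all noise instances of the validation subjects, and tested
#' on the reference (original) curves of the test subjects only. Accuracy is
#' the fraction of correctly classified rows; a feature is informative when
#' its validation accuracy reaches 1/3. Tree hyperparameters are the rpart
#' defaults unless overridden via `control`.
#'
#' @param featureId the feature to evaluate.
#' @param curves normalized curve set ([normalizeCurves()]`$curves`).
#' @param split split assignment from [splitSubjects()].
#' @param k frames after subsampling (default 12).
#' @param control an [rpart::rpart.control()] list.
#' @param seed integer seed (set before fitting).
#' @return A data.frame row: `feature_id`, `validation_accuracy`,
#'   `test_accuracy`, `informative`.
#' @export
evaluateFeatureTree <- function(featureId, curves, split, k = 12L,
                                control = rpart::rpart.control(), seed = 1L) {
  cur <- curves[curves$feature_id == featureId, ]
  if (!nrow(cur)) stop("no curves for feature ", featureId)
  tr <- curveRows(cur, split, "train", FALSE, k)
  va <- curveRows(cur, split, "validation", FALSE, k)
  te <- curveRows(cur, split, "test", TRUE, k)
  # leakage guards: the three subject sets must be disjoint
  stopifnot(!any(tr$subjects %in% c(va$subjects, te$subjects)),
            !any(va$subjects %in% te$subjects))
  if (nlevels(droplevels(tr$y)) < 2)
    stop("degenerate training data: single class")
  fit <- withSeed(stableHash("tree", seed, featureId),
                  rpart::rpart(y ~ ., data = cbind(tr$x, y = tr$y),
                               method = "class", control = control))
  acc <- function(rows) {
    pred <- predict(fit, rows$x, type = "class")
    mean(as.character(pred) == as.character(rows$y))
  }
  va_acc <- acc(va)
  data.frame(feature_id = featureId,
             validation_accuracy = va_acc,
             test_accuracy = acc(te),
             informative = va_acc >= 1 / 3,
             stringsAsFactors = FALSE)
}

#' Evaluate decision trees for every feature
#'
#' Runs [evaluateFeatureTree()] over all features present in the curve set.
#'
#' @inheritParams evaluateFeatureTree
#' @return A data.frame, one row per feature.
#' @export
evaluateFeatureTrees <- function(curves, split, k = 12L,
                                 control = rpart::rpart.control(),
                                 seed = 1L) {
  ids <- sort(unique(curves$feature_id))
  out <- do.call(rbind, lapply(ids, evaluateFeatureTree, curves = curves,
                               split = split, k = k, control = control,
                               seed = seed))
  rownames(out) <- NULL
  out
}

#' Correlation between stability rank and classification accuracy
#'
#' Spearman correlation between the consensus stability rank and the
#' test-set accuracy, restricted to informative features (validation
#' accuracy >= 1/3). A negative coefficient means more stable features (low
#' rank) reach higher accuracy. Also reports the median test accuracy of the
#' most and least stable informative features (`topN` each end).
#'
#' @param consensus consensus table from [consensusRanking()].
#' @param results tree results from [evaluateFeatureTrees()].
#' @param topN group size for the top/bottom accuracy summary (default 15).
#' @return A list: `rho`, `n_informative`, `median_accuracy_top`,
#'   `median_accuracy_bottom`. `rho` is NA with fewer than 3 informative
#'   features.
#' @export
stabilityAccuracyCorrelation <- function(consensus, results, topN = 15L) {
  inf <- results[results$informative, ]
  m <- match(inf$feature_id, consensus$feature_id)
  ranked <- !is.na(m) & !is.na(consensus$consensus_rank[m])
  inf <- inf[ranked, ]
  rk <- consensus$consensus_rank[m[ranked]]
  if (nrow(inf) < 3)
    return(list(rho = NA_real_, n_informative = nrow(inf),
                median_accuracy_top = NA_real_,
                median_accuracy_bottom = NA_real_))
  ord <- order(rk)
  nEnd <- min(topN, floor(nrow(inf) / 2))
  list(rho = spearmanRho(rk, inf$test_accuracy),
       n_informative = nrow(inf),
       median_accuracy_top = median(inf$test_accuracy[ord[seq_len(nEnd)]]),
       median_accuracy_bottom =
         median(inf$test_accuracy[rev(ord)[seq_len(nEnd)]]))
}
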