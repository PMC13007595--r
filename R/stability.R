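#' Mean absolute error between two feature curves
#'
#' Frame-wise mean absolute difference `(1/T) * sum |f_t - g_t|`, the
#' distance underlying all stability scores. Symmetric and 0 iff the curves
#' are identical.
#'
#' @param f,g numeric curves of equal length.
#' @return A single non-negative number.
#' @export
curveMAE <- function(f, g) {
  if (length(f) != length(g))
    stop("curve length mismatch: ", length(f), " vs ", length(g))
  mean(abs(f - g))
}

#' Mean pairwise MAE over all noise instances
#'
#' The subject-level stability score of a feature: the mean of [curveMAE()]
#' over all unordered pairs of the subject's noise instances (the reference
#' counts as an instance, so 41 instances give a mean over 820 pairs). Lower
#' is more stable; 0 is perfect stability.
#'
#' @param curveMatrix numeric matrix, one instance curve per row.
#' @return A list with `mpMAE` and `n_pairs`.
#' @export
meanPairwiseMAE <- function(curveMatrix) {
  n <- nrow(curveMatrix)
  if (is.null(n) || n < 2) stop("need at least 2 instances")
  d <- dist(curveMatrix, method = "manhattan") / ncol(curveMatrix)
  list(mpMAE = mean(d), n_pairs = n * (n - 1) / 2)
}

#' Mean pairwise MAE restricted to equal noise levels
#'
#' Pools the pairwise MAE over all unordered pairs of instances sharing a
#' noise level label (the single reference instance contributes no pair).
#' Features sensitive to the amount of noise but stable across realizations
#' of the same level score low here while scoring high overall.
#'
#' @param curveMatrix numeric matrix, one instance curve per row.
#' @param levels character vector of level labels, one per row.
#' @return A list with `within_level_mpMAE` (NA when no level has two or
#'   more instances) and `n_within_pairs`.
#' @export
withinLevelMAE <- function(curveMatrix, levels) {
  stopifnot(nrow(curveMatrix) == length(levels))
  dm <- as.matrix(dist(curveMatrix, method = "manhattan")) /
    ncol(curveMatrix)
  tot <- 0; np <- 0L
  for (lv in unique(levels)) {
    idx <- which(levels == lv)
    if (length(idx) < 2) next
    sub <- dm[idx, idx]
    tot <- tot + sum(sub[upper.tri(sub)])
    np <- np + length(idx) * (length(idx) - 1L) / 2L
  }
  list(within_level_mpMAE = if (np > 0) tot / np else NA_real_,
       n_within_pairs = np)
}

#' Rank features by stability within one subject
#'
#' Ascending fractional ranks on the stability score: rank 1 is the most
#' stable feature; ties receive the mean of their positional ranks.
#'
#' @param scores named numeric vector of per-feature scores (no NAs).
#' @return Named fractional ranks.
#' @export
rankFeatures <- function(scores) {
  if (!length(scores)) stop("empty ranking: all features excluded")
  if (length(scores) < 2) stop("need at least 2 features to rank")
  rank(scores, ties.method = "average")
}

#' Per-subject stability table
#'
#' Computes, for every (subject, feature), the overall and within-level mean
#' pairwise MAE and the subject's fractional stability ranks (overall and
#' within-level). Features excluded during normalization are reported with
#' NA scores and `excluded = TRUE`.
#'
#' @param normalized result of [normalizeCurves()] (or just its `curves`
#'   component).
#' @return A data.frame with columns `subject_id`, `feature_id`, `mpMAE`,
#'   `within_level_mpMAE`, `n_pairs`, `n_within_pairs`, `rank`,
#'   `within_rank`, `excluded`.
#' @export
stabilityTable <- function(normalized) {
  params <- NULL
  curves <- normalized
  if (is.list(normalized) && !is.data.frame(normalized) &&
      all(c("curves", "params") %in% names(normalized))) {
    curves <- normalized$curves
    params <- normalized$params
  }
  key <- paste(curves$subject_id, curves$feature_id, sep = "\r")
  groups <- split(seq_len(nrow(curves)), key)
  recs <- lapply(groups, function(idx) {
    m <- do.call(rbind, curves$values[idx])
    ov <- meanPairwiseMAE(m)
    wl <- withinLevelMAE(m, curves$level_label[idx])
    data.frame(subject_id = curves$subject_id[idx[1]],
               feature_id = curves$feature_id[idx[1]],
               mpMAE = ov$mpMAE,
               within_level_mpMAE = wl$within_level_mpMAE,
               n_pairs = ov$n_pairs, n_within_pairs = wl$n_within_pairs,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  rownames(tab) <- NULL
  tab$rank <- NA_real_
  tab$within_rank <- NA_real_
  for (s in unique(tab$subject_id)) {
    i <- which(tab$subject_id == s)
    tab$rank[i] <- rankFeatures(stats::setNames(tab$mpMAE[i],
                                                tab$feature_id[i]))
    wi <- i[!is.na(tab$within_level_mpMAE[i])]
    if (length(wi) >= 2)
      tab$within_rank[wi] <- rank(tab$within_level_mpMAE[wi],
                                  ties.method = "average")
  }
  tab$excluded <- FALSE
  if (!is.null(params) && any(params$excluded)) {
    ex <- params[params$excluded, c("subject_id", "feature_id")]
    ex$mpMAE <- NA_real_; ex$within_level_mpMAE <- NA_real_
    ex$n_pairs <- NA_integer_; ex$n_within_pairs <- NA_integer_
    ex$rank <- NA_real_; ex$within_rank <- NA_real_
    ex$excluded <- TRUE
    tab <- rbind(tab, ex)
    rownames(tab) <- NULL
  }
  tab[order(tab$subject_id, tab$feature_id), , drop = FALSE]
}

#' Spearman rank correlation of two score vectors
#'
#' Pearson correlation of fractional ranks. Returns NA (an undefined marker,
#' not an error) when fewer than 3 complete pairs are available or either
#' side has zero rank variance.
#'
#' @param x,y paired numeric vectors.
#' @return A correlation in `[-1, 1]`, or NA.
#' @export
spearmanRho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Between-subject consistency of stability rankings
#'
#' Pairwise Spearman correlation of the per-subject stability scores over
#' the features ranked (non-excluded) in both subjects of each pair.
#'
#' @param stability stability table from [stabilityTable()].
#' @return A list with `matrix` (symmetric, unit diagonal, subjects as
#'   dimnames) and `median_rho` (median off-diagonal coefficient, NA cells
#'   removed).
#' @export
correlationMatrix <- function(stability) {
  subjects <- sort(unique(stability$subject_id))
  if (length(subjects) < 2) stop("need at least 2 subjects")
  st <- stability[!stability$excluded, ]
  wide <- split(stats::setNames(st$mpMAE, st$feature_id), st$subject_id)
  m <- diag(1, length(subjects))
  dimnames(m) <- list(subjects, subjects)
  for (a in seq_along(subjects)) for (b in seq_len(a - 1L)) {
    xa <- wide[[subjects[a]]]; xb <- wide[[subjects[b]]]
    shared <- intersect(names(xa), names(xb))
    rho <- spearmanRho(xa[shared], xb[shared])
    m[a, b] <- rho; m[b, a] <- rho
  }
  off <- m[lower.tri(m)]
  list(matrix = m, median_rho = median(off, na.rm = TRUE))
}

# Order features by (median rank, median score, feature id) and return the
# consensus positions 1..K.
consensusOrder <- function(medRank, medScore, ids) {
  ord <- order(medRank, medScore, ids)
  pos <- integer(length(ord))
  pos[ord] <- seq_along(ord)
  pos
}

#' Median-rank consensus across subjects
#'
#' Features non-excluded in every subject are ordered by the median of their
#' per-subject stability ranks; ties are broken by median mpMAE, then by
#' feature id. A parallel consensus is computed on the within-level scores.
#' Features excluded in at least one subject are listed after the consensus
#' with NA consensus ranks and their `n_subjects_present`.
#'
#' @param stability stability table from [stabilityTable()].
#' @return A data.frame with columns `feature_id`, `consensus_rank`,
#'   `median_rank`, `median_mpMAE`, `within_level_consensus_rank`,
#'   `n_subjects_present`, ordered by consensus rank.
#' @export
consensusRanking <- function(stability) {
  nSubj <- length(unique(stability$subject_id))
  ok <- stability[!stability$excluded, ]
  present <- tapply(ok$subject_id, ok$feature_id,
                    function(x) length(unique(x)))
  full <- names(present)[present == nSubj]
  if (!length(full)) stop("empty consensus: no feature present in all subjects")
  sub <- ok[ok$feature_id %in% full, ]
  medRank <- tapply(sub$rank, sub$feature_id, median)
  medMae <- tapply(sub$mpMAE, sub$feature_id, median)
  medWRank <- tapply(sub$within_rank, sub$feature_id,
                     function(x) median(x, na.rm = TRUE))
  medWMae <- tapply(sub$within_level_mpMAE, sub$feature_id,
                    function(x) median(x, na.rm = TRUE))
  ids <- names(medRank)
  out <- data.frame(feature_id = ids,
                    consensus_rank = consensusOrder(medRank, medMae, ids),
                    median_rank = as.vector(medRank),
                    median_mpMAE = as.vector(medMae),
                    within_level_consensus_rank =
                      if (all(is.na(medWRank))) NA_integer_
                      else consensusOrder(medWRank, medWMae, ids),
                    n_subjects_present = nSubj,
                    stringsAsFactors = FALSE)
  partial <- setdiff(names(present), full)
  allFeat <- unique(stability$feature_id)
  missing <- setdiff(allFeat, names(present))
  extra <- c(partial, missing)
  if (length(extra)) {
    out <- rbind(out, data.frame(
      feature_id = extra, consensus_rank = NA_integer_,
      median_rank = NA_real_, median_mpMAE = NA_real_,
      within_level_consensus_rank = NA_integer_,
      n_subjects_present = as.integer(c(present[partial],
                                        rep(0L, length(missing)))),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[order(is.na(out$consensus_rank), out$consensus_rank, out$feature_id), ,
      drop = FALSE]
}
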