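test_that("curve MAE has its closed forms", {
  f <- c(0, 1, 2)
  expect_equal(curveMAE(f, f), 0)
  expect_equal(curveMAE(f, f + 0.5), 0.5)
  expect_equal(curveMAE(c(0, 1, 2), c(1, 1, 1)), 2 / 3)
  expect_equal(curveMAE(f, f + 0.5), curveMAE(f + 0.5, f))  # symmetry
  expect_error(curveMAE(1:3, 1:4), "length mismatch")
})

test_that("mean pairwise MAE enumerates unordered instance pairs", {
  A <- c(0, 1, 0, 1)
  m <- rbind(A, A, A)
  expect_equal(meanPairwiseMAE(m)$mpMAE, 0)
  m2 <- rbind(A, A, A + 1)
  r <- meanPairwiseMAE(m2)
  expect_equal(r$mpMAE, 2 / 3)           # pair MAEs {0, 1, 1}
  expect_equal(r$n_pairs, 3)
  # 41 instances -> C(41, 2) = 820 pairs
  m41 <- matrix(rnorm(41 * 5), 41, 5)
  expect_equal(meanPairwiseMAE(m41)$n_pairs, 820)
  expect_error(meanPairwiseMAE(m41[1, , drop = FALSE]), "at least 2")
})

test_that("within-level MAE pools same-level pairs only", {
  A <- c(0, 0, 0); B <- c(1, 1, 1)
  m <- rbind(A, A, B, B + 1)
  r <- withinLevelMAE(m, c("L1", "L1", "L2", "L2"))
  expect_equal(r$within_level_mpMAE, 0.5)  # pair MAEs {0, 1}
  expect_equal(r$n_within_pairs, 2)
  # identical within level but shifted across levels: within 0, overall > 0
  m2 <- rbind(A, A, B, B)
  r2 <- withinLevelMAE(m2, c("L1", "L1", "L2", "L2"))
  expect_equal(r2$within_level_mpMAE, 0)
  expect_gt(meanPairwiseMAE(m2)$mpMAE, 0)
  # the lone reference contributes no pair
  r3 <- withinLevelMAE(rbind(A, A, B), c("reference", "L1", "L1"))
  expect_equal(r3$n_within_pairs, 1)
  # reference-only subject: undefined marker, not an error
  r4 <- withinLevelMAE(rbind(A), "reference")
  expect_true(is.na(r4$within_level_mpMAE))
  expect_equal(r4$n_within_pairs, 0L)
  # 4 levels x 10 replicates pool 4 * 45 = 180 pairs
  m41 <- matrix(0, 41, 3)
  lv <- c("reference", rep(paste0("L", 1:4), each = 10))
  expect_equal(withinLevelMAE(m41, lv)$n_within_pairs, 180)
})

test_that("feature ranking uses ascending fractional ranks", {
  expect_equal(rankFeatures(c(a = 0.1, b = 0.3, c = 0.5)),
               c(a = 1, b = 2, c = 3))
  expect_equal(rankFeatures(c(a = 0.1, c = 0.1, b = 0.3)),
               c(a = 1.5, c = 1.5, b = 3))
  expect_error(rankFeatures(numeric(0)), "excluded")
})

test_that("spearman correlation handles ties and degenerate input", {
  expect_equal(spearmanRho(1:5, 1:5), 1)
  expect_equal(spearmanRho(1:5, 5:1), -1)
  # closed form 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 2, n = 4
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(spearmanRho(1:2, 2:1)))          # < 3 pairs
  expect_true(is.na(spearmanRho(c(1, 1, 1), 1:3)))   # zero rank variance
  # monotone transform invariance
  x <- c(0.3, 0.1, 0.9, 0.5); y <- c(2, 1, 8, 3)
  expect_equal(spearmanRho(exp(x), y), spearmanRho(x, y))
})

test_that("the stability table integrates scores, ranks and exclusions", {
  mk <- function(subj) longTable(subj, list(
    reference = list(stable = c(0, 1, 0, 1), wobbly = c(0, 1, 0, 1)),
    L1.1 = list(stable = c(0, 1, 0, 1) + 0.01,
                wobbly = c(0, 1, 0, 1) + 0.5),
    L1.2 = list(stable = c(0, 1, 0, 1) - 0.01,
                wobbly = c(0, 1, 0, 1) - 0.5)))
  tb <- rbind(mk("s1"), mk("s2"))
  st <- stabilityTable(normalizeCurves(buildCurves(tb)))
  expect_equal(nrow(st), 4)
  for (s in c("s1", "s2")) {
    sub <- st[st$subject_id == s, ]
    expect_lt(sub$mpMAE[sub$feature_id == "stable"],
              sub$mpMAE[sub$feature_id == "wobbly"])
    expect_equal(sort(sub$rank), c(1, 2))
    expect_equal(sub$rank[sub$feature_id == "stable"], 1)
  }
  expect_true(all(st$n_pairs == 3))
  expect_true(all(st$n_within_pairs == 1))
})

test_that("zero-noise replicates give exactly zero mpMAE", {
  s <- rescaleToUnit(generatePhantom(smallPhantomParams()))
  inst <- makeNoiseInstances(s, levels = 0, replicates = 2L, baseSeed = 1L)
  cfg <- extractionConfig(filters = "original", families = "firstorder")
  st <- stabilityTable(normalizeCurves(buildCurves(extractFeatures(inst,
                                                                   cfg))))
  expect_true(all(st$mpMAE[!st$excluded] == 0))
})

test_that("correlation matrices are symmetric with unit diagonal", {
  mk <- function(subj, noise) {
    base <- c(0.1, 0.2, 0.3, 0.4, 0.5)
    vals <- base + noise
    data.frame(subject_id = subj, feature_id = paste0("f", 1:5),
               mpMAE = vals, rank = rank(vals), excluded = FALSE,
               stringsAsFactors = FALSE)
  }
  set.seed(3)
  st <- rbind(mk("a", rnorm(5, 0, 0.01)), mk("b", rnorm(5, 0, 0.01)),
              mk("c", rnorm(5, 0, 0.01)))
  cm <- correlationMatrix(st)
  expect_equal(cm$matrix, t(cm$matrix))
  expect_equal(diag(cm$matrix), c(a = 1, b = 1, c = 1))
  expect_true(all(abs(cm$matrix) <= 1))
  # relabeling invariance: permuting subjects permutes rows/cols
  st2 <- st; st2$subject_id <- chartr("abc", "cab", st2$subject_id)
  cm2 <- correlationMatrix(st2)
  expect_equal(cm2$matrix["a", "b"], cm$matrix["a", "b"])
  # shared latent profile: median rho rises as subject noise shrinks
  med <- vapply(c(0.2, 0.05, 0.005), function(amp) {
    set.seed(9)
    st3 <- do.call(rbind, lapply(letters[1:4], function(s) {
      base <- seq(0.1, 1, length.out = 12)
      v <- base + rnorm(12, 0, amp)
      data.frame(subject_id = s, feature_id = paste0("f", 1:12),
                 mpMAE = v, rank = rank(v), excluded = FALSE,
                 stringsAsFactors = FALSE)
    }))
    correlationMatrix(st3)$median_rho
  }, 0)
  expect_true(all(diff(med) > 0))
  expect_gt(med[3], 0.95)
})

test_that("consensus ranking follows median rank with stated tie-breaks", {
  mkst <- function(subj, maes) data.frame(
    subject_id = subj, feature_id = names(maes), mpMAE = unname(maes),
    within_level_mpMAE = unname(maes) / 2, rank = rank(unname(maes)),
    within_rank = rank(unname(maes)), excluded = FALSE,
    stringsAsFactors = FALSE)
  # identical orderings across subjects reproduce the common order
  st <- rbind(mkst("s1", c(a = 0.1, b = 0.2, c = 0.3)),
              mkst("s2", c(a = 0.2, b = 0.4, c = 0.9)),
              mkst("s3", c(a = 0.15, b = 0.3, c = 0.31)))
  cons <- consensusRanking(st)
  expect_equal(cons$feature_id, c("a", "b", "c"))
  expect_equal(cons$consensus_rank, 1:3)

  # median robustness: ranks {1, 3, 100} -> median 3
  expect_equal(median(c(1, 3, 100)), 3)

  # tie on median rank broken by median mpMAE
  st2 <- rbind(mkst("s1", c(x = 0.4, y = 0.2)),
               mkst("s2", c(x = 0.2, y = 0.4)))
  cons2 <- consensusRanking(st2)   # both have median rank 1.5
  expect_equal(cons2$consensus_rank[cons2$feature_id == "x"],
               cons2$consensus_rank[cons2$feature_id == "y"] - 1L,
               ignore_attr = TRUE)

  # a feature excluded in one subject leaves the consensus
  st3 <- rbind(mkst("s1", c(a = 0.1, b = 0.2, c = 0.3)),
               mkst("s2", c(a = 0.2, b = 0.4, c = 0.9)))
  st3$excluded[st3$subject_id == "s2" & st3$feature_id == "c"] <- TRUE
  st3$rank[st3$subject_id == "s2"] <- c(1, 2, NA)
  cons3 <- consensusRanking(st3)
  expect_true(is.na(cons3$consensus_rank[cons3$feature_id == "c"]))
  expect_equal(cons3$n_subjects_present[cons3$feature_id == "c"], 1L)

  # invariance to subject order and to a monotone transform of one
  # subject's scores
  stPerm <- st[order(st$feature_id, decreasing = TRUE), ]
  expect_equal(consensusRanking(stPerm)$consensus_rank[
    match(cons$feature_id, consensusRanking(stPerm)$feature_id)],
    cons$consensus_rank)
  stMono <- st
  i <- stMono$subject_id == "s2"
  stMono$mpMAE[i] <- exp(stMono$mpMAE[i])
  stMono$rank[i] <- rank(stMono$mpMAE[i])
  expect_equal(consensusRanking(stMono)$feature_id, cons$feature_id)
})

test_that("a designed feature battery is ranked in design order", {
  s <- rescaleToUnit(generatePhantom(smallPhantomParams()))
  inst <- makeNoiseInstances(s, 0.02, 3L, 21L)
  cfg <- extractionConfig(filters = "original", families = "firstorder")
  ft <- extractFeatures(inst, cfg)
  base <- ft[ft$feature_id == "original_firstorder_Mean", ]
  bat <- syntheticFeatureBattery(base, c(1, 2, 4, 8))
  st <- stabilityTable(normalizeCurves(buildCurves(bat)))
  ord <- st$feature_id[order(st$rank)]
  expect_equal(ord, paste0("original_firstorder_Mean_x", c(1, 2, 4, 8)))
  # mpMAE scales exactly with the designed multiplier
  m <- st$mpMAE[match(paste0("original_firstorder_Mean_x", c(1, 2, 4, 8)),
                      st$feature_id)]
  expect_equal(m / m[1], c(1, 2, 4, 8), tolerance = 1e-9)
})
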