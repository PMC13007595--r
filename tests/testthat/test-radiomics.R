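cfg4 <- extractionConfig(nBins = 4L)

test_that("discretization follows the fixed-bin-count formula", {
  expect_equal(discretize(c(5, 5, 5), 4), c(1L, 1L, 1L))
  expect_equal(discretize(c(0, 10), 2), c(1L, 2L))
  expect_equal(discretize(c(1, 1, 2, 10), 2), c(1L, 1L, 1L, 2L))
  # monotone in v, covers 1..<=B
  v <- runif(50)
  lv <- discretize(v, 8)
  expect_true(all(diff(lv[order(v)]) >= 0))
  expect_true(all(lv >= 1 & lv <= 8))
  expect_error(discretize(numeric(0), 4), "empty")
})

test_that("haar sub-bands match a direct convolution oracle", {
  # constant image: LL gains sqrt(2) per axis, high-pass bands vanish
  cst <- matrix(3, 5, 7)
  wb <- waveletSubbands(cst)
  expect_equal(wb$LL, matrix(6, 5, 7))
  expect_equal(wb$LH, matrix(0, 5, 7))
  expect_equal(wb$HL, matrix(0, 5, 7))
  expect_equal(wb$HH, matrix(0, 5, 7))
  # a ramp along one axis kills HH (high-pass of the constant axis is 0)
  ramp <- matrix(rep(1:6, each = 4), 4, 6)
  expect_equal(waveletSubbands(ramp)$HH, matrix(0, 4, 6))
  # random images against the brute-force convolution oracle
  set.seed(42)
  for (i in 1:10) {
    x <- matrix(rnorm(64), 8, 8)
    got <- waveletSubbands(x)
    want <- oracleWavelet(x)
    for (b in names(want))
      expect_lt(max(abs(got[[b]] - want[[b]])), 1e-10)
  }
  expect_error(waveletSubbands(matrix(1, 1, 5)), "2x2")
})

test_that("LBP codes match a per-pixel enumeration oracle", {
  # flat field: uniform all-ones pattern -> code P
  expect_true(all(lbpMap(matrix(5, 6, 6), 1, 8) == 8L))
  # single bright pixel is a strict local maximum -> code 0
  img <- matrix(0, 7, 7); img[4, 4] <- 10
  expect_equal(lbpMap(img, 1, 8)[4, 4], 0L)
  set.seed(7)
  for (i in 1:10) {
    x <- matrix(rnorm(64), 8, 8)
    expect_identical(lbpMap(x, 1, 8), oracleLBP(x, 1, 8))
  }
  # codes bounded by P + 1
  x <- matrix(rnorm(100), 10, 10)
  expect_true(all(lbpMap(x, 1.5, 12) <= 13L))
})

test_that("first-order features have their closed forms", {
  f <- firstOrderFeatures(c(1, 2, 3), discretize(c(1, 2, 3), 4))
  expect_equal(unname(f["Mean"]), 2)
  expect_equal(unname(f["Variance"]), 2 / 3)     # population denominator
  expect_equal(unname(f["Median"]), 2)
  expect_equal(unname(f["Energy"]), 14)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(14 / 3))

  cst <- firstOrderFeatures(rep(4, 10), rep(1L, 10))
  expect_equal(unname(cst["Variance"]), 0)
  expect_equal(unname(cst["Entropy"]), 0)
  expect_equal(unname(cst["MeanAbsoluteDeviation"]), 0)
  expect_equal(unname(cst["Skewness"]), 0)

  # moment estimators: skewness/kurtosis of a large normal sample sit
  # within 3 standard errors of 0
  set.seed(1)
  v <- rnorm(1e4, 5, 2)
  g <- firstOrderFeatures(v, discretize(v, 32))
  expect_lt(abs(g["Skewness"]), 3 * sqrt(6 / 1e4))
  expect_lt(abs(g["Kurtosis"]), 3 * sqrt(24 / 1e4))
  # percentiles: linear interpolation between order statistics
  expect_equal(unname(g["10Percentile"]), unname(quantile(v, 0.1)))
})

test_that("GLCM matrices and features match brute-force oracles", {
  # the 2x2 worked example: p(1,2) = p(2,1) = 0.5 under offset (0,1)
  lv <- rbind(c(1L, 2L), c(1L, 2L))
  msk <- matrix(1L, 2, 2)
  cfg1 <- extractionConfig(nBins = 4L, glcmOffsets = rbind(c(0L, 1L)))
  m <- glcmMatrix(lv, msk, cfg1)
  expect_length(m, 1)
  expect_equal(m[[1]][1, 2], 0.5)
  expect_equal(m[[1]][2, 1], 0.5)
  expect_equal(sum(m[[1]]), 1)
  f <- glcmFeatures(m, 4L)
  expect_equal(unname(f["Contrast"]), 1)
  expect_equal(unname(f["JointAverage"]), 1.5)

  # constant ROI: point mass at (1, 1)
  mc <- glcmMatrix(matrix(1L, 3, 3), matrix(1L, 3, 3), cfg4)
  expect_true(all(vapply(mc, function(p) p[1, 1], 0) == 1))
  fc <- glcmFeatures(mc, 4L)
  expect_equal(unname(fc["Contrast"]), 0)
  expect_equal(unname(fc["Idm"]), 1)
  expect_equal(unname(fc["JointEntropy"]), 0)
  expect_equal(unname(fc["Correlation"]), 1)    # degenerate convention

  # random masked images against the pair-enumeration oracle
  set.seed(11)
  for (i in 1:20) {
    ri <- randomLevelImage()
    cfg <- extractionConfig(nBins = ri$nBins)
    got <- tryCatch(glcmMatrix(ri$levels, ri$mask, cfg),
                    error = function(e) NULL)
    want <- oracleGLCM(ri$levels, ri$mask, cfg@glcmOffsets, TRUE, ri$nBins)
    if (is.null(got)) { expect_length(want, 0); next }
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(glcmFeatures(got, ri$nBins),
                 rowMeans(vapply(want, oracleGLCMFeatures, numeric(9),
                                 nBins = ri$nBins)),
                 tolerance = 1e-10)
    for (p in got) expect_equal(p, t(p))        # symmetry
  }
})

test_that("GLSZM matrices and features match a flood-fill oracle", {
  lv <- rbind(c(1L, 1L), c(2L, 3L))
  s <- glszmMatrix(lv, matrix(1L, 2, 2))
  expect_equal(s[1, 2], 1L)   # one zone of level 1, size 2
  expect_equal(s[2, 1], 1L)
  expect_equal(s[3, 1], 1L)
  expect_equal(sum(s), 3L)

  # constant ROI: a single zone covering the mask
  sc <- glszmMatrix(matrix(1L, 4, 4), matrix(1L, 4, 4))
  expect_equal(sum(sc), 1L)
  expect_equal(sc[1, 16], 1L)
  fz <- glszmFeatures(sc, 16)
  expect_equal(unname(fz["ZoneEntropy"]), 0)
  expect_equal(unname(fz["ZonePercentage"]), 1 / 16)

  # worked small-area emphasis: zones {(1,2),(2,1),(3,1)} -> 0.75
  expect_equal(unname(glszmFeatures(s, 4)["SmallAreaEmphasis"]), 0.75)

  set.seed(13)
  for (i in 1:20) {
    ri <- randomLevelImage()
    got <- glszmMatrix(ri$levels, ri$mask, 8L)
    want <- oracleGLSZM(ri$levels, ri$mask, 8)
    expect_equal(unname(got) * 1.0, unname(want) * 1.0)
    expect_equal(glszmFeatures(got, sum(ri$mask)),
                 oracleGLSZMFeatures(want, sum(ri$mask)),
                 tolerance = 1e-10)
    # 4-connectivity variant
    expect_equal(unname(glszmMatrix(ri$levels, ri$mask, 4L)) * 1.0,
                 unname(oracleGLSZM(ri$levels, ri$mask, 4)) * 1.0)
  }
})

test_that("frame extraction composes filters and families", {
  p <- smallPhantomParams()
  s <- rescaleToUnit(generatePhantom(p))
  fr <- frames(s)[, , 1]; mk <- masks(s)[, , 1]

  # constant ROI under original/firstorder
  cfgOF <- extractionConfig(filters = "original", families = "firstorder")
  v <- extractFrame(matrix(7, 16, 16), matrix(1L, 16, 16), cfgOF)
  expect_equal(unname(v["original_firstorder_Variance"]), 0)

  # default configuration: (1 + 4 + 1) filters x (13 + 9 + 6) features
  full <- extractFrame(fr, mk, extractionConfig())
  expect_length(full, 168L)
  expect_true(all(is.finite(full)))
  expect_identical(full, extractFrame(fr, mk, extractionConfig()))

  # intensity-shift invariance: discretized texture features unchanged,
  # Mean shifts by the constant
  sh <- extractFrame(fr + 5, mk, extractionConfig())
  texture <- grep("glcm|glszm|Entropy", names(full), value = TRUE)
  expect_equal(sh[texture], full[texture], tolerance = 1e-9)
  expect_equal(unname(sh["original_firstorder_Mean"] -
                        full["original_firstorder_Mean"]), 5,
               tolerance = 1e-9)
  expect_error(extractFrame(fr, matrix(0L, 64, 64), extractionConfig()),
               "empty mask")
})

test_that("feature tables are long, complete and deterministic", {
  s <- rescaleToUnit(generatePhantom(smallPhantomParams()))
  inst <- makeNoiseInstances(s, 0.02, 2L, 5L)
  cfg <- extractionConfig(filters = "original", families = "firstorder")
  ft <- extractFeatures(inst, cfg)
  expect_equal(nrow(ft), 3 * 12 * 13)   # instances x frames x features
  expect_setequal(unique(ft$level_label), c("reference", "L1"))
  expect_identical(ft, extractFeatures(inst, cfg))
})

test_that("many LBP feature curves are cycle-constant and excluded", {
  # the LBP code image varies little over the cycle, so a substantial
  # share of LBP curves has zero reference variance and is excluded,
  # while original-filter first-order curves never are
  s <- rescaleToUnit(generatePhantom(smallPhantomParams()))
  cfg <- extractionConfig(filters = c("original", "lbp2d"),
                          families = "firstorder")
  inst <- makeNoiseInstances(s, 0.01, 1L, 3L)
  norm <- normalizeCurves(buildCurves(extractFeatures(inst, cfg)))
  ex <- norm$params
  lbp <- ex[grepl("^lbp2d", ex$feature_id), ]
  orig <- ex[grepl("^original", ex$feature_id), ]
  expect_gt(sum(lbp$excluded), 0)
  expect_equal(sum(orig$excluded), 0)
})
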