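# cineRadStab

Noise-stability analysis of dynamic radiomic feature curves in cine cardiac
imaging.

## The problem

Radiomics quantifies image texture through large batteries of intensity and
texture descriptors. In cine cardiac MR, a feature can be computed on every
frame of the cardiac cycle, turning it into a *feature curve* — the
trajectory of, say, GLCM contrast of the left-ventricular myocardium across
the cycle. Before such curves can feed prognostic models, one must know
which of them survive image noise and which fall apart. `cineRadStab`
implements a complete, reproducible pipeline for answering that question,
with a synthetic contracting-annulus phantom standing in for patient data so
every stage runs on a laptop with no downloads.

## The method

For each subject, the pipeline builds a set of **noise instances**: the
original (reference) sequence plus, for each noise level
σ ∈ {0.010, 0.020, 0.030, 0.040} (fractions of the [0, 1] rescaled intensity
range), several seeded replicates with i.i.d. zero-mean Gaussian noise —
with 4 levels × 10 replicates, 41 instances per subject. Radiomic features
(first-order, GLCM, GLSZM families on original, Haar-wavelet and LBP
filtered images) are extracted per frame and assembled into curves
f = (f₁, …, f_T).

All curves of a subject and feature are normalized by the *reference*
curve's mean and standard deviation, so the reference has mean 0 and SD 1.
Features whose reference curve shows no cycle variation (σ_ref = 0) are
excluded. Stability of a feature for a subject is the **mean pairwise MAE**

  mpMAE = mean over instance pairs (i, j) of (1/T) Σₜ |fₜ⁽ⁱ⁾ − fₜ⁽ʲ⁾|,

lower = more stable (0 is perfect). A second score restricts the pairs to
instances of the same noise level, isolating sensitivity to the *amount* of
noise from sensitivity to its realization. Features are ranked per subject
(fractional ranks), ranking consistency across subjects is measured by
pairwise Spearman correlation, and a consensus ranking orders features by
their median rank. Finally, one decision tree per feature (12-frame
subsampled curves, class-balanced train/validation/test split, test on
original images only) probes whether stability translates into
classification accuracy.

## Worked example

```r
library(cineRadStab)

params <- phantomParams()                      # 128 px, 25 frames
seqc   <- rescaleToUnit(generatePhantom(params))
seqc
#> CineSequence 'phantom1234': 128x128 pixels, 25 frames, spacing 1.5 mm
#>   intensity range [54.00069, 460.2924], ROI 1808 px in frame 1

inst <- makeNoiseInstances(seqc, levels = c(0.01, 0.02, 0.03, 0.04),
                           replicates = 10, baseSeed = 1)
length(inst)                                   # 41 noise instances
#> [1] 41

cfg <- extractionConfig(filters = "original", families = "firstorder")
st  <- stabilityTable(normalizeCurves(buildCurves(extractFeatures(inst, cfg))))
head(st[order(st$rank), c("feature_id", "mpMAE", "within_level_mpMAE", "rank")], 5)
#>                           feature_id    mpMAE within_level_mpMAE rank
#>           original_firstorder_Energy 1.026404          0.5982042    1
#>           original_firstorder_Median 2.285812          2.1845338    2
#>         original_firstorder_Skewness 3.033041          2.9712082    3
#>             original_firstorder_Mean 3.229526          3.1505444    4
#>  original_firstorder_RootMeanSquared 5.280246          3.0769934    5
```

Energy is this subject's most stable first-order feature: its curve moves
by about 1 normalized unit between noise instances on average. The
`within_level_mpMAE` column shows how much of that movement persists among
instances with the *same* noise level — a feature with a large gap between
the two columns (compare `Variance`, whose expectation shifts by σ² at each
level) reacts to the amount of noise rather than to its realization.

The full pipeline — cohort simulation, noise, extraction, curves,
stability, consensus, per-feature trees — runs from one configuration:

```r
cfg <- pipelineConfig(nSubjects = 5)
runPipeline(cfg, "pipeline-out")
```

and writes `stability.csv`, `consensus.csv`, `correlation.csv`,
`classification.csv` plus JSON summaries under `pipeline-out/`, with stage
caching (a changed noise seed re-runs noise and downstream stages but
reuses the simulated geometry). A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

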