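#' Assemble a pipeline configuration
#'
#' One structured configuration drives the whole analysis. The noise
#' defaults are the canonical study conditions: four Gaussian noise levels
#' with standard deviations 0.010-0.040 (fractions of the [0, 1] rescaled
#' range) and ten replicates each, i.e. 41 noise instances per subject
#' including the original. Cohort defaults are desk-scale: five phantom
#' subjects with heterogeneous geometry and frame counts.
#'
#' @param nSubjects,nClasses,framesRange,gridSize,cohortSeed cohort
#'   specification (see [simulateCohort()]).
#' @param levels,replicates,baseSeed noise specification (see
#'   [makeNoiseInstances()]).
#' @param extraction an [ExtractionConfig-class].
#' @param splitCounts per-class `c(train, validation, test)` counts for the
#'   classification stage, or NULL to derive feasible counts automatically.
#' @param classifySeed,classifyFrames classification seed and subsampled
#'   frame count.
#' @return A validated pipeline configuration (a named list).
#' @export
pipelineConfig <- function(nSubjects = 5L, nClasses = 5L,
                           framesRange = c(12L, 50L), gridSize = 128L,
                           cohortSeed = 1L,
                           levels = c(0.010, 0.020, 0.030, 0.040),
                           replicates = 10L, baseSeed = 1L,
                           extraction = extractionConfig(),
                           splitCounts = NULL, classifySeed = 1L,
                           classifyFrames = 12L) {
  stopifnot(isCount(nSubjects), isCount(nClasses),
            length(framesRange) == 2, isCount(replicates))
  validObject(extraction)
  list(cohort = list(nSubjects = as.integer(nSubjects),
                     nClasses = as.integer(nClasses),
                     framesRange = as.integer(framesRange),
                     gridSize = as.integer(gridSize),
                     cohortSeed = as.integer(cohortSeed)),
       noise = list(levels = levels, replicates = as.integer(replicates),
                    baseSeed = as.integer(baseSeed)),
       extraction = extraction,
       classify = list(splitCounts = splitCounts,
                       seed = as.integer(classifySeed),
                       k = as.integer(classifyFrames)))
}

configDigest <- function(x) {
  if (is(x, "ExtractionConfig"))
    x <- lapply(methods::slotNames(x), function(s) slot(x, s))
  stableHash(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE))
}

readManifest <- function(outdir) {
  p <- file.path(outdir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else list(stages = list())
}

writeManifest <- function(outdir, manifest) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# A stage is current when its recorded hash matches and all outputs exist.
stageCurrent <- function(manifest, name, hash, outdir) {
  st <- manifest$stages[[name]]
  !is.null(st) && identical(st$hash, hash) &&
    all(file.exists(file.path(outdir, unlist(st$outputs))))
}

#' Run the full stability pipeline
#'
#' Executes simulate, noise, extract, curves, stability and classify in
#' order, writing every stage's tables under `outdir`. Stage outputs are
#' cached: a stage re-runs only when its configuration (or an upstream
#' stage's) changed, so e.g. changing the noise seed reuses the simulated
#' phantom geometry. All randomness flows from the seeds in the
#' configuration, making two runs from one configuration byte-identical.
#'
#' @param config configuration from [pipelineConfig()].
#' @param outdir output directory (created if needed).
#' @param verbose print per-stage progress lines.
#' @return Invisibly, a list with per-stage `ran` flags, output paths and
#'   the stage hashes.
#' @export
runPipeline <- function(config, outdir, verbose = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- readManifest(outdir)
  note <- function(...) if (verbose) message("[", format(Sys.time(),
                                                         "%H:%M:%S"),
                                             "] ", ...)
  ran <- list()
  hashes <- list()

  runStage <- function(name, hash, outputs, fun) {
    hashes[[name]] <<- hash
    if (stageCurrent(manifest, name, hash, outdir)) {
      note("stage ", name, ": up to date, skipped")
      ran[[name]] <<- FALSE
    } else {
      note("stage ", name, ": running (hash ", hash, ")")
      fun()
      manifest$stages[[name]] <<- list(hash = hash, outputs = outputs)
      writeManifest(outdir, manifest)
      ran[[name]] <<- TRUE
    }
    file.path(outdir, outputs)
  }

  ## 1. simulate: reference phantoms -----------------------------------
  h1 <- configDigest(list(stage = "simulate", config$cohort))
  cohortCsv <- "cohort.csv"
  simOut <- runStage("simulate", h1, cohortCsv, function() {
    cohort <- do.call(simulateCohort, config$cohort)
    rows <- lapply(cohort, function(s) {
      p <- instancePaths(file.path(outdir, "nifti"), s$subjectID,
                         "reference", 0L)
      writeCineNifti(s$sequence, p["image"], p["mask"])
      data.frame(subject_id = s$subjectID, class_label = s$classLabel,
                 n_frames = nFrames(s$sequence), stringsAsFactors = FALSE)
    })
    write.csv(do.call(rbind, rows), file.path(outdir, cohortCsv),
              row.names = FALSE)
  })

  ## 2. noise instances --------------------------------------------------
  h2 <- configDigest(list(stage = "noise", h1, config$noise))
  instCsv <- "instances.csv"
  runStage("noise", h2, instCsv, function() {
    cohort <- read.csv(file.path(outdir, cohortCsv),
                       stringsAsFactors = FALSE)
    rows <- lapply(cohort$subject_id, function(sid) {
      p <- instancePaths(file.path(outdir, "nifti"), sid, "reference", 0L)
      ref <- rescaleToUnit(readCineNifti(p["image"], p["mask"], sid))
      inst <- makeNoiseInstances(ref, config$noise$levels,
                                 config$noise$replicates,
                                 config$noise$baseSeed)
      writeNoiseInstances(inst, file.path(outdir, "nifti"))
    })
    man <- do.call(rbind, rows)
    man$image_path <- file.path("nifti", man$image_path)
    man$mask_path <- file.path("nifti", man$mask_path)
    write.csv(man, file.path(outdir, instCsv), row.names = FALSE)
  })

  ## 3. feature extraction ----------------------------------------------
  h3 <- configDigest(list(stage = "extract", h2, config$extraction))
  featCsv <- "features.csv"
  runStage("extract", h3, featCsv, function() {
    man <- read.csv(file.path(outdir, instCsv), stringsAsFactors = FALSE)
    tabs <- lapply(split(man, man$subject_id), function(m) {
      inst <- readNoiseInstances(m, outdir)
      extractFeatures(inst, config$extraction)
    })
    write.csv(do.call(rbind, tabs), file.path(outdir, featCsv),
              row.names = FALSE)
  })

  ## 4. curve assembly + normalization ----------------------------------
  h4 <- configDigest(list(stage = "curves", h3))
  curvesCsv <- "normalized_curves.csv"
  exclCsv <- "exclusions.csv"
  runStage("curves", h4, c(curvesCsv, exclCsv), function() {
    ft <- read.csv(file.path(outdir, featCsv), stringsAsFactors = FALSE)
    norm <- normalizeCurves(buildCurves(ft))
    long <- curvesToLong(norm$curves)
    long$normalized <- TRUE
    write.csv(long, file.path(outdir, curvesCsv), row.names = FALSE)
    write.csv(norm$params[, c("subject_id", "feature_id", "sigma_ref",
                              "excluded")],
              file.path(outdir, exclCsv), row.names = FALSE)
  })

  ## 5. stability, consensus, consistency -------------------------------
  h5 <- configDigest(list(stage = "stability", h4))
  stabCsv <- "stability.csv"; consCsv <- "consensus.csv"
  corrCsv <- "correlation.csv"; stabJson <- "stability_summary.json"
  runStage("stability", h5, c(stabCsv, consCsv, corrCsv, stabJson),
           function() {
    long <- read.csv(file.path(outdir, curvesCsv), stringsAsFactors = FALSE)
    excl <- read.csv(file.path(outdir, exclCsv), stringsAsFactors = FALSE)
    curves <- buildCurves(long[, c("subject_id", "level_label",
                                   "replicate_index", "frame_index",
                                   "feature_id", "value")])
    stab <- stabilityTable(list(curves = curves, params = excl))
    write.csv(stab, file.path(outdir, stabCsv), row.names = FALSE)
    write.csv(consensusRanking(stab), file.path(outdir, consCsv),
              row.names = FALSE)
    nSubj <- length(unique(stab$subject_id))
    if (nSubj >= 2) {
      cm <- correlationMatrix(stab)
      write.csv(cbind(subject_id = rownames(cm$matrix),
                      as.data.frame(cm$matrix)),
                file.path(outdir, corrCsv), row.names = FALSE)
      medRho <- cm$median_rho
    } else {
      write.csv(data.frame(subject_id = character(0)),
                file.path(outdir, corrCsv), row.names = FALSE)
      medRho <- NA_real_
    }
    jsonlite::write_json(list(median_spearman_rho = medRho,
                              n_subjects = nSubj),
                         file.path(outdir, stabJson), auto_unbox = TRUE,
                         digits = NA, na = "null")
  })

  ## 6. per-feature decision trees --------------------------------------
  h6 <- configDigest(list(stage = "classify", h5, config$classify))
  clsCsv <- "classification.csv"; clsJson <- "classification_summary.json"
  runStage("classify", h6, c(clsCsv, clsJson), function() {
    cohort <- read.csv(file.path(outdir, cohortCsv),
                       stringsAsFactors = FALSE)
    labels <- stats::setNames(cohort$class_label, cohort$subject_id)
    counts <- config$classify$splitCounts
    if (is.null(counts)) counts <- autoSplitCounts(labels)
    long <- read.csv(file.path(outdir, curvesCsv), stringsAsFactors = FALSE)
    feasible <- !is.null(counts) &&
      min(table(labels)) >= sum(counts) && length(unique(labels)) >= 2 &&
      min(tapply(long$frame_index, long$subject_id, max)) >=
        config$classify$k
    if (!feasible) {
      note("stage classify: cohort cannot support the split, ",
           "writing empty results")
      write.csv(data.frame(feature_id = character(0),
                           validation_accuracy = numeric(0),
                           test_accuracy = numeric(0),
                           informative = logical(0)),
                file.path(outdir, clsCsv), row.names = FALSE)
      jsonlite::write_json(list(rho = NULL, n_informative = 0L),
                           file.path(outdir, clsJson), auto_unbox = TRUE,
                           digits = NA, null = "null")
      return(invisible(NULL))
    }
    curves <- buildCurves(long[, c("subject_id", "level_label",
                                   "replicate_index", "frame_index",
                                   "feature_id", "value")])
    split <- splitSubjects(labels, counts, config$classify$seed)
    res <- evaluateFeatureTrees(curves, split, k = config$classify$k,
                                seed = config$classify$seed)
    stab <- read.csv(file.path(outdir, stabCsv), stringsAsFactors = FALSE)
    cons <- read.csv(file.path(outdir, consCsv), stringsAsFactors = FALSE)
    res$consensus_rank <- cons$consensus_rank[match(res$feature_id,
                                                    cons$feature_id)]
    write.csv(res, file.path(outdir, clsCsv), row.names = FALSE)
    sac <- stabilityAccuracyCorrelation(cons, res)
    jsonlite::write_json(sac, file.path(outdir, clsJson),
                         auto_unbox = TRUE, digits = NA, na = "null")
  })

  invisible(list(ran = ran, hashes = hashes, outdir = outdir))
}

# Largest per-class (train, val, test) counts in 3:1:1 proportion that the
# cohort supports, or NULL when some class has fewer than 5 subjects.
autoSplitCounts <- function(labels) {
  m <- min(table(labels))
  if (m < 5) return(NULL)
  tr <- max(1L, floor(m * 3 / 5))
  va <- max(1L, floor(m / 5))
  te <- m - tr - va
  if (te < 1) return(NULL)
  c(tr, va, te)
}

#' Flatten a curve set back to the long table format
#'
#' @param curves curve set from [buildCurves()] (or normalized curves).
#' @return A long data.frame with one row per (curve, frame).
#' @export
curvesToLong <- function(curves) {
  lens <- lengths(curves$values)
  data.frame(subject_id = rep(curves$subject_id, lens),
             level_label = rep(curves$level_label, lens),
             replicate_index = rep(curves$replicate_index, lens),
             frame_index = unlist(lapply(lens, seq_len)),
             feature_id = rep(curves$feature_id, lens),
             value = unlist(curves$values),
             stringsAsFactors = FALSE)
}
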