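# Shared small fixtures, built in code.

smallPhantomParams <- function(...) {
  phantomParams(gridSize = 64L, nFrames = 12L, rEndoED = 10, rEpiED = 18, ...)
}

# Long feature table from explicit per-instance curves.
# curves: named list instance_key -> named list feature_id -> numeric curve;
# instance keys "reference" or "L<k>.<rep>".
longTable <- function(subject, curves) {
  rows <- list()
  for (ik in names(curves)) {
    if (ik == "reference") { lvl <- "reference"; rep <- 0L }
    else {
      parts <- strsplit(ik, ".", fixed = TRUE)[[1]]
      lvl <- parts[1]; rep <- as.integer(parts[2])
    }
    for (fid in names(curves[[ik]])) {
      v <- curves[[ik]][[fid]]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject, level_label = lvl, replicate_index = rep,
        frame_index = seq_along(v), feature_id = fid, value = v,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Normalized curve set for classification tests: one feature, nPerClass
# subjects per class, `reps` noisy instances per subject plus the reference.
# gen(classIndex, subjectIndex, isReference) returns a length-T curve.
classCurveSet <- function(gen, nPerClass = 20, nClasses = 5, T = 12,
                          reps = 2, featureId = "feat") {
  rows <- list(); labels <- character(0)
  for (cl in seq_len(nClasses)) for (s in seq_len(nPerClass)) {
    sid <- sprintf("C%d_S%02d", cl, s)
    labels[sid] <- paste0("class", cl)
    inst <- c(list(c("reference", 0)),
              lapply(seq_len(reps), function(r) c("L1", r)))
    for (i in inst) {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sid, feature_id = featureId, level_label = i[1],
        replicate_index = as.integer(i[2]), stringsAsFactors = FALSE)
      rows[[length(rows)]]$values <- list(gen(cl, s, i[1] == "reference"))
    }
  }
  list(curves = do.call(rbind, rows), labels = labels)
}
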