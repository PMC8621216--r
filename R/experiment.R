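#' Default experiment configuration
#'
#' Nested list of all pipeline settings; any subset can be overridden
#' through `...` (named sub-lists are merged, not replaced).
#'
#' @param ... named overrides, e.g.
#'   `phantom = list(nPatients = 12), folds = list(k = 2)`.
#' @return Named list with sections `phantom`, `folds`, `train`,
#'   `sweep`, `seed`, `outDir`.
#' @export
experimentConfig <- function(...) {
  cfg <- list(
    phantom = list(nPatients = 40L, clipsPerPatient = c(2L, 4L),
                   bPatientFraction = 0.38, heterogeneousFraction = 0.44,
                   frameTrainFraction = 0.6, nFramesRange = c(30L, 60L),
                   imageHeight = 128L, imageWidth = 128L),
    folds = list(k = 10L, validationFraction = 0.1),
    train = list(epochs = 10L, batchSize = 16L, learningRate = 1e-3,
                 dropout = 0.5, earlyStoppingPatience = 3L,
                 classWeighting = TRUE, augment = TRUE,
                 framesPerClip = 4L, valFramesPerClip = 2L,
                 maxTestFramesPerClip = 4L),
    sweep = list(tValues = seq(0.5, 0.9, by = 0.1), tauValues = 1:40),
    seed = 0L,
    outDir = NULL
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  cfg
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose keys mirror [experimentConfig()].
#' @return Merged configuration list.
#' @export
readExperimentConfig <- function(path) {
  do.call(experimentConfig, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# pick up to `per` frame indices per clip, evenly spaced
.spacedIdx <- function(n, per) {
  if (n <= per) seq_len(n) else unique(round(seq(1, n, length.out = per)))
}

# Assemble a frame array + labels from the clips of given patients.
# With balance = TRUE the per-clip frame count of the minority class is
# scaled up (capped by clip length) so both classes contribute
# comparable frame numbers despite unequal clip counts.
.gatherFrames <- function(clips, manifest, patients, framesPerClip,
                          balance = FALSE) {
  sel <- manifest[manifest$patient_id %in% patients, , drop = FALSE]
  if (!nrow(sel)) return(list(x = NULL, y = character()))
  nPerClass <- table(sel$clip_label)
  xs <- list(); ys <- character()
  for (i in seq_len(nrow(sel))) {
    clip <- clips[[sel$clip_id[i]]]
    fpc <- framesPerClip
    if (balance)
      fpc <- round(framesPerClip * max(nPerClass) /
                   nPerClass[[sel$clip_label[i]]])
    idx <- .spacedIdx(nFrames(clip), min(fpc, nFrames(clip)))
    xs[[length(xs) + 1L]] <- clip@frames[, , idx, drop = FALSE]
    ys <- c(ys, clip@frameLabels[idx])
  }
  list(x = array(unlist(xs), c(dim(xs[[1]])[1:2], length(ys))), y = ys)
}

#' Run the end-to-end experiment
#'
#' Desk-scale version of the full workflow: generate a synthetic
#' cohort; route clips between the frame-training and clip-inference
#' pools; build a patient-grouped K-fold plan; per fold, train the
#' frame classifier on the training patients' frame-pool clips and
#' evaluate frame-level metrics on the test patients' homogeneous
#' clips; pool the clip-inference predictions of every fold's test
#' patients and sweep the (t, tau) grid; report the selected operating
#' point. Fully reproducible under `config$seed` (training is
#' deterministic given the seed).
#'
#' @param config list from [experimentConfig()] or
#'   [readExperimentConfig()].
#' @param verbose print stage progress.
#' @return List with elements `manifest`, `foldPlan`, `pools`,
#'   `models` (per fold), `frameReports` (per fold), `frameAggregate`,
#'   `clipPredictions`, `sweep`, `operatingPoint`, and `paths` when
#'   `config$outDir` is set.
#' @export
runExperiment <- function(config = experimentConfig(), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  seed <- config$seed

  say("stage cohort: generating ", config$phantom$nPatients, " patients")
  cohort <- .stage("cohort", {
    ph <- config$phantom
    generateCohort(nPatients = ph$nPatients,
                   clipsPerPatient = ph$clipsPerPatient,
                   bPatientFraction = ph$bPatientFraction,
                   heterogeneousFraction = ph$heterogeneousFraction,
                   frameTrainFraction = ph$frameTrainFraction,
                   nFramesRange = ph$nFramesRange,
                   cfg = phantomConfig(imageHeight = ph$imageHeight,
                                       imageWidth = ph$imageWidth),
                   seed = seed)
  })
  manifest <- cohort$manifest

  pools <- .stage("routing", routePools(manifest))
  plan <- .stage("splits",
                 makeFolds(manifest, k = config$folds$k,
                           validationFraction =
                             config$folds$validationFraction,
                           seed = seed + 1L))

  tc <- config$train
  augment <- if (isTRUE(tc$augment)) {
    if (is.null(tc$augmentRanges)) augmentationRanges()
    else do.call(augmentationRanges, tc$augmentRanges)
  } else NULL
  inputShape <- c(config$phantom$imageHeight, config$phantom$imageWidth)

  models <- list(); frameReports <- list(); clipPred <- list()
  rocCurves <- list()
  for (f in seq_len(plan@k)) {
    sets <- foldSets(plan, f)
    say("stage fold ", f, ": training")
    model <- .stage(paste0("train fold ", f), {
      tr <- .gatherFrames(cohort$clips, pools$framePool, sets$train,
                          tc$framesPerClip, balance = TRUE)
      # validation may draw on any clip of the validation patients
      # (per-frame ground truth is known); without both classes,
      # early stopping is disabled rather than misled
      va <- .gatherFrames(cohort$clips, manifest, sets$validation,
                          tc$valFramesPerClip %||% 2L)
      if (length(unique(va$y)) < 2L) va <- list(x = NULL, y = NULL)
      if (is.null(tr$x)) stop("no frame-pool clips for training patients")
      m <- buildFrameClassifier(inputShape, dropout = tc$dropout,
                                seed = seed + 100L + f)
      trainFrameClassifier(m, tr$x, tr$y, va$x, va$y,
                           config = trainConfig(
                             epochs = tc$epochs, batchSize = tc$batchSize,
                             learningRate = tc$learningRate,
                             earlyStoppingPatience =
                               tc$earlyStoppingPatience,
                             classWeighting = tc$classWeighting,
                             seed = seed + 200L + f),
                           augment = augment)
    })
    models[[f]] <- model

    frameReports[[f]] <- .stage(paste0("frame metrics fold ", f), {
      homo <- manifest[manifest$homogeneity == "homogeneous" &
                       manifest$patient_id %in% sets$test, , drop = FALSE]
      te <- .gatherFrames(cohort$clips, homo, sets$test,
                          tc$maxTestFramesPerClip)
      if (is.null(te$x) || length(unique(te$y)) < 2L) {
        # fall back to every test clip (per-frame ground truth is known)
        te <- .gatherFrames(cohort$clips, manifest, sets$test,
                            tc$maxTestFramesPerClip)
      }
      if (is.null(te$x) || length(unique(te$y)) < 2L)
        stop("test patients lack both classes at the frame level")
      p <- .cnn_forward(.liveNet(model), te$x)
      roc <- rocAuc(p[, 2], te$y)
      rocCurves[[f]] <- cbind(fold = f, roc$curve)
      cm <- confusionCounts(ifelse(p[, 2] > p[, 1], "B", "A"), te$y)
      metricReport(cm, auc = roc$auc)
    })

    say("stage fold ", f, ": clip inference")
    clipPred[[f]] <- .stage(paste0("clip inference fold ", f), {
      sel <- pools$clipPool[pools$clipPool$patient_id %in% sets$test, ,
                            drop = FALSE]
      preds <- lapply(sel$clip_id, function(cid) {
        pr <- predictFrames(model, cohort$clips[[cid]])
        pr$fold <- f
        pr
      })
      do.call(rbind, preds)
    })
  }

  frameAgg <- .stage("aggregation", aggregateFolds(frameReports))
  allPred <- do.call(rbind, clipPred)

  say("stage sweep: ", length(config$sweep$tValues), " x ",
      length(config$sweep$tauValues), " grid")
  sweepRes <- .stage("sweep", {
    ids <- unique(allPred$clipId)
    probs <- lapply(ids, function(cid) {
      sub <- allPred[allPred$clipId == cid, ]
      sub$pB[order(sub$frameIndex)]
    })
    labels <- manifest$clip_label[match(ids, manifest$clip_id)]
    tauMax <- min(max(config$sweep$tauValues),
                  min(manifest$n_frames[match(ids, manifest$clip_id)]))
    thresholdSweep(probs, labels, config$sweep$tValues,
                   config$sweep$tauValues[config$sweep$tauValues <=
                                          tauMax])
  })
  op <- selectOperatingPoint(sweepRes)

  result <- list(manifest = manifest, foldPlan = plan, pools = pools,
                 models = models, frameReports = frameReports,
                 frameAggregate = frameAgg, clipPredictions = allPred,
                 rocCurves = do.call(rbind, rocCurves),
                 sweep = sweepRes, operatingPoint = op,
                 config = config)

  if (!is.null(config$outDir)) {
    result$paths <- .stage("outputs", .writeExperiment(result,
                                                       config$outDir))
  }
  result
}

# write the result bundle plus a machine-readable run manifest
.writeExperiment <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    manifest = file.path(outDir, "manifest.csv"),
    foldPlan = file.path(outDir, "fold_plan.json"),
    frameMetrics = file.path(outDir, "frame_metrics.csv"),
    rocCurves = file.path(outDir, "frame_roc.csv"),
    predictions = file.path(outDir, "clip_predictions.csv"),
    sweep = file.path(outDir, "sweep.csv"),
    operatingPoint = file.path(outDir, "operating_point.json"),
    runManifest = file.path(outDir, "run_manifest.json")
  )
  writeManifest(result$manifest, paths$manifest)
  writeFoldPlan(result$foldPlan, paths$foldPlan)
  perFold <- do.call(rbind, result$frameReports)
  perFold$fold <- seq_len(nrow(perFold))
  write.csv(perFold, paths$frameMetrics, row.names = FALSE)
  write.csv(result$rocCurves, paths$rocCurves, row.names = FALSE)
  write.csv(result$clipPredictions, paths$predictions, row.names = FALSE)
  write.csv(result$sweep@grid, paths$sweep, row.names = FALSE)
  op <- result$operatingPoint
  jsonlite::write_json(
    list(t = op@t, tau = op@tau,
         sensitivity = attr(op, "sensitivity"),
         specificity = attr(op, "specificity")),
    paths$operatingPoint, auto_unbox = TRUE, digits = NA)
  cfgFile <- tempfile(fileext = ".json")
  jsonlite::write_json(result$config, cfgFile, auto_unbox = TRUE,
                       force = TRUE)
  # content-address every artifact so downstream stages can verify
  # their inputs have not silently changed
  artifacts <- setdiff(names(paths), "runManifest")
  hashes <- lapply(artifacts, function(nm)
    list(file = basename(paths[[nm]]),
         md5 = unname(tools::md5sum(paths[[nm]]))))
  names(hashes) <- artifacts
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(cfgFile)),
         seed = result$config$seed,
         artifacts = hashes),
    paths$runManifest, auto_unbox = TRUE)
  unlink(cfgFile)
  paths
}
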