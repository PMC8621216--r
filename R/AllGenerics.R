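#' @name lusBline-accessors
#' @title Accessors for lusBline classes
#'
#' @description Accessor generics for the package's S4 containers:
#' pixel data, labels, identifiers and derived quantities are read
#' through these rather than by direct slot access.
#'
#' @param object an S4 object from this package.
#' @return The corresponding slot value; see the individual methods.
NULL

#' @rdname lusBline-accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname lusBline-accessors
#' @export
setGeneric("frameLabels", function(object) standardGeneric("frameLabels"))

#' @rdname lusBline-accessors
#' @export
setGeneric("clipId", function(object) standardGeneric("clipId"))

#' @rdname lusBline-accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))

#' @rdname lusBline-accessors
#' @export
setGeneric("clipLabel", function(object) standardGeneric("clipLabel"))

#' @rdname lusBline-accessors
#' @export
setGeneric("severity", function(object) standardGeneric("severity"))

#' @rdname lusBline-accessors
#' @export
setGeneric("homogeneity", function(object) standardGeneric("homogeneity"))

#' @rdname lusBline-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname lusBline-accessors
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' @rdname lusBline-accessors
#' @export
setGeneric("sweepGrid", function(object) standardGeneric("sweepGrid"))

#' @rdname lusBline-accessors
#' @export
setMethod("frames", "LUSClip", function(object) object@frames)

#' @rdname lusBline-accessors
#' @export
setMethod("frameLabels", "LUSClip", function(object) object@frameLabels)

#' @rdname lusBline-accessors
#' @export
setMethod("clipId", "LUSClip", function(object) object@clipId)

#' @rdname lusBline-accessors
#' @export
setMethod("patientId", "LUSClip", function(object) object@patientId)

#' @rdname lusBline-accessors
#' @export
setMethod("clipLabel", "LUSClip", function(object) object@clipLabel)

#' @rdname lusBline-accessors
#' @export
setMethod("severity", "LUSClip", function(object) object@severity)

#' @rdname lusBline-accessors
#' @export
setMethod("homogeneity", "LUSClip", function(object) object@homogeneity)

#' @rdname lusBline-accessors
#' @export
setMethod("nFrames", "LUSClip", function(object) dim(object@frames)[3])

#' @rdname lusBline-accessors
#' @export
setMethod("sweepGrid", "SweepResult", function(object) object@grid)

setMethod("show", "PhantomConfig", function(object) {
  cat("PhantomConfig:", object@imageHeight, "x", object@imageWidth,
      "sector", object@sectorAngle, "deg\n")
  cat("  pleural depth", object@pleuralDepthFraction, "| A-lines",
      object@nALines, "| B rays", object@bLineCount,
      "(width", object@bLineWidth, "px)\n")
  cat("  speckle sigma", object@speckleSigma, "| brightness jitter",
      object@brightnessJitter, "\n")
})

setMethod("show", "LUSFrame", function(object) {
  cat("LUSFrame", paste(dim(object@pixels), collapse = " x "),
      "| label", object@frameLabel)
  if (length(object@rayAngles))
    cat(" |", length(object@rayAngles), "B rays")
  cat("\n")
})

setMethod("show", "LUSClip", function(object) {
  d <- dim(object@frames)
  cat("LUSClip", object@clipId, "(patient", paste0(object@patientId, ")"),
      "\n")
  cat(" ", d[3], "frames of", d[1], "x", d[2], "|", object@clipLabel,
      "/", object@severity, "/", object@homogeneity, "\n")
  cat("  B frames:", sum(object@frameLabels == "B"), "of", d[3], "\n")
})

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan:", object@k, "patient-grouped folds over",
      length(object@assignment), "patients\n")
  sizes <- vapply(object@folds, function(s)
    c(length(s$train), length(s$validation), length(s$test)), numeric(3))
  cat("  patients per fold (train/val/test): ",
      paste(apply(sizes, 2, paste, collapse = "/"), collapse = ", "), "\n")
})

setMethod("show", "FrameClassifier", function(object) {
  cat("FrameClassifier: truncated-VGG,",
      paste(object@blockConvs, collapse = "+"), "convs of",
      paste(object@blockFilters, collapse = "/"), "filters\n")
  cat("  input", paste(object@inputShape, collapse = " x "),
      "| dropout", object@dropout,
      "|", format(nParameters(object), big.mark = ","), "parameters\n")
  cat("  trained:", object@trained,
      if (nrow(object@history)) sprintf("(%d epochs)", max(object@history$epoch))
      else "", "\n")
})

setMethod("show", "ClipDecision", function(object) {
  cat("ClipDecision", object@clipId, ":",
      if (object@yHat == 1L) "B" else "A",
      sprintf("(t = %.2f, tau = %d)", object@t, object@tau), "\n")
  if (length(object@window))
    cat("  triggering window: frames", object@window[1], "-",
        object@window[2], "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(truth = c("B", "A"), predicted = c("B", "A")))
  cat("ConfusionMatrix (positive class: B)\n")
  print(m)
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult:", length(object@tValues), "t values x",
      length(object@tauValues), "tau values on", object@nB, "B /",
      object@nA, "A clips\n")
  best <- object@grid[which.max(object@grid$sensitivity +
                                object@grid$specificity), ]
  cat(sprintf("  best sens+spec: t = %.2f, tau = %d (sens %.3f, spec %.3f)\n",
              best$t, best$tau, best$sensitivity, best$specificity))
})

setMethod("show", "ThresholdSetting", function(object) {
  cat(sprintf("ThresholdSetting: t = %.2f, tau = %d\n", object@t, object@tau))
})

setMethod("show", "Heatmap", function(object) {
  cat("Heatmap", paste(dim(object@importance), collapse = " x "),
      "| target class", object@targetClass,
      "| max", signif(max(object@importance), 3), "\n")
})
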