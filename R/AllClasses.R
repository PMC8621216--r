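#' Phantom generator configuration
#'
#' Geometry and noise settings for the synthetic sector-scan lung
#' ultrasound phantom. Distances are in pixels, angles in degrees,
#' intensities on \[0, 1\].
#'
#' @slot imageHeight,imageWidth frame dimensions in pixels.
#' @slot sectorAngle full opening angle of the scan sector, degrees.
#' @slot pleuralDepthFraction depth of the pleural line as a fraction of
#'   image height; must lie in (0.05, 0.5) so that at least one A-line
#'   reverberation fits below it.
#' @slot nALines number of horizontal A-line reverberations drawn in
#'   A-labelled frames, at integer multiples of the pleural depth.
#' @slot bLineCount number of vertical B-line rays in B-labelled frames.
#' @slot bLineWidth width of each B-line ray, in pixels at the pleural line.
#' @slot speckleSigma log-scale standard deviation of the multiplicative
#'   speckle noise.
#' @slot brightnessJitter per-frame global brightness jitter fraction.
#'
#' @seealso [phantomConfig()], [generateFrame()], [generateClip()]
#' @export
setClass("PhantomConfig",
  representation(
    imageHeight = "integer", imageWidth = "integer",
    sectorAngle = "numeric", pleuralDepthFraction = "numeric",
    nALines = "integer", bLineCount = "integer", bLineWidth = "numeric",
    speckleSigma = "numeric", brightnessJitter = "numeric"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@imageHeight < 16L || object@imageWidth < 16L)
    msg <- c(msg, "image dimensions must be at least 16 pixels")
  if (object@pleuralDepthFraction <= 0.05 || object@pleuralDepthFraction >= 0.5)
    msg <- c(msg, "pleuralDepthFraction must lie in (0.05, 0.5)")
  if (object@sectorAngle <= 10 || object@sectorAngle >= 150)
    msg <- c(msg, "sectorAngle must lie in (10, 150) degrees")
  if (object@nALines < 0L) msg <- c(msg, "nALines must be >= 0")
  if (object@bLineCount < 0L) msg <- c(msg, "bLineCount must be >= 0")
  if (object@bLineWidth < 1) msg <- c(msg, "bLineWidth must be >= 1 pixel")
  if (object@speckleSigma < 0 || object@brightnessJitter < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A single lung ultrasound frame
#'
#' One masked grayscale frame with, for synthetic frames, its ground
#' truth label and the ray geometry used to draw it (which supports
#' Grad-CAM localization checks via [rayPixelMask()]).
#'
#' @slot pixels grayscale intensity matrix on \[0, 1\]; pixels outside
#'   the scan sector are exactly 0.
#' @slot frameLabel `"A"` or `"B"`.
#' @slot rayAngles angular positions (radians from the vertical probe
#'   axis) of the B-line rays; length 0 for A frames or real data.
#' @slot rayWidthAngle angular full width of one ray at the pleural line.
#' @slot sector geometry list (`apexRow`, `apexCol`, `angleRad`, `rmin`,
#'   `rmax`, `rhoP`) describing the sector in pixel coordinates.
#' @export
setClass("LUSFrame",
  representation(
    pixels = "matrix", frameLabel = "character",
    rayAngles = "numeric", rayWidthAngle = "numeric", sector = "list"
  )
)

setValidity("LUSFrame", function(object) {
  msg <- character()
  if (!object@frameLabel %in% c("A", "B"))
    msg <- c(msg, "frameLabel must be 'A' or 'B'")
  rng <- range(object@pixels)
  if (rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "pixel intensities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' An ordered lung ultrasound clip
#'
#' A clip is an ordered stack of frames sharing one sector geometry,
#' together with its clip-level labels. The clip label is `"B"` iff at
#' least one frame is a B frame; a clip is homogeneous iff all frame
#' labels agree; severity is `"none"` iff the clip is an A clip.
#'
#' @slot frames numeric array `height x width x nFrames` on \[0, 1\].
#' @slot frameLabels per-frame ground-truth labels, `"A"`/`"B"`.
#' @slot clipId,patientId opaque identifiers.
#' @slot clipLabel `"A"` or `"B"`.
#' @slot severity `"none"`, `"mild"`, `"moderate"` or `"severe"`.
#' @slot homogeneity `"homogeneous"` or `"heterogeneous"`.
#' @slot rayAngles shared ray angles of the clip's B frames (may be
#'   length 0), radians from the vertical axis.
#' @slot rayWidthAngle angular width of one ray.
#' @slot sector sector geometry list, identical for all frames.
#' @export
setClass("LUSClip",
  representation(
    frames = "array", frameLabels = "character",
    clipId = "character", patientId = "character",
    clipLabel = "character", severity = "character",
    homogeneity = "character",
    rayAngles = "numeric", rayWidthAngle = "numeric", sector = "list"
  )
)

setValidity("LUSClip", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    return("frames must be a height x width x nFrames array")
  if (length(object@frameLabels) != d[3])
    msg <- c(msg, "frameLabels length must equal the number of frames")
  if (!all(object@frameLabels %in% c("A", "B")))
    msg <- c(msg, "frameLabels must be 'A' or 'B'")
  hasB <- any(object@frameLabels == "B")
  if ((object@clipLabel == "B") != hasB)
    msg <- c(msg, "clipLabel must be 'B' iff at least one frame label is 'B'")
  homo <- length(unique(object@frameLabels)) == 1L
  if ((object@homogeneity == "homogeneous") != homo)
    msg <- c(msg, "homogeneity flag contradicts the frame labels")
  if ((object@severity == "none") != (object@clipLabel == "A"))
    msg <- c(msg, "severity must be 'none' iff the clip label is 'A'")
  rng <- range(object@frames)
  if (rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "pixel intensities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ultrasound beam mask
#'
#' A simple polygon delimiting the ultrasound sector in pixel
#' coordinates (columns = x, rows = y, origin top-left). Everything
#' outside the polygon is screen furniture and is zeroed by
#' [applyMask()].
#'
#' @slot polygon numeric matrix with columns `x`, `y` (ordered vertices).
#' @slot width,height dimensions of the image the mask applies to.
#' @export
setClass("BeamMask",
  representation(polygon = "matrix", width = "integer", height = "integer")
)

setValidity("BeamMask", function(object) {
  msg <- character()
  p <- object@polygon
  if (ncol(p) != 2L || nrow(p) < 3L)
    msg <- c(msg, "polygon must be an n x 2 matrix with n >= 3")
  if (anyNA(p)) msg <- c(msg, "polygon vertices must be finite")
  if (!.polygonIsSimple(p))
    msg <- c(msg, "polygon must be simple (non-self-intersecting)")
  area <- .polygonArea(p)
  if (area <= 0.2 * object@width * object@height)
    msg <- c(msg, "mask polygon must cover more than 20% of the image")
  if (length(msg)) msg else TRUE
})

#' Stochastic augmentation ranges
#'
#' Ranges for training-time augmentation. Parameters are drawn uniformly
#' on `[-range, +range]` (shear one-sided on `[0, shearMax]`, flips
#' Bernoulli(0.5)); brightness is a multiplicative factor drawn on
#' `[1 - brightnessMax, 1 + brightnessMax]`.
#'
#' @slot rotationMax maximum rotation, degrees (default 45).
#' @slot shiftMax maximum translation as a fraction of each dimension
#'   (default 0.10, both axes).
#' @slot zoomMax maximum magnification in/out fraction (default 0.10).
#' @slot shearMax maximum counterclockwise shear, degrees (default 10).
#' @slot horizontalFlip whether horizontal reflection is enabled.
#' @slot brightnessMax maximum brightness change fraction (default 0.30).
#' @export
setClass("AugmentationRanges",
  representation(
    rotationMax = "numeric", shiftMax = "numeric", zoomMax = "numeric",
    shearMax = "numeric", horizontalFlip = "logical",
    brightnessMax = "numeric"
  )
)

setValidity("AugmentationRanges", function(object) {
  v <- c(object@rotationMax, object@shiftMax, object@zoomMax,
         object@shearMax, object@brightnessMax)
  if (any(v < 0)) "augmentation ranges must be >= 0" else TRUE
})

#' Patient-grouped K-fold plan
#'
#' Assignment of every patient to exactly one fold, plus per-fold
#' train/validation/test patient sets. Within every fold all clips of a
#' patient fall in a single set, preventing patient-level leakage.
#'
#' @slot k number of folds.
#' @slot assignment named integer vector, patient id -> fold index.
#' @slot folds list of `k` lists with elements `train`, `validation`,
#'   `test` (character vectors of patient ids).
#' @slot validationFraction fraction of non-test patients held out for
#'   validation.
#' @slot seed seed used to build the plan (NA if none).
#' @export
setClass("FoldPlan",
  representation(
    k = "integer", assignment = "integer", folds = "list",
    validationFraction = "numeric", seed = "numeric"
  )
)

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (length(object@folds) != object@k)
    msg <- c(msg, "folds list length must equal k")
  pts <- names(object@assignment)
  for (f in seq_along(object@folds)) {
    s <- object@folds[[f]]
    all3 <- c(s$train, s$validation, s$test)
    if (anyDuplicated(all3))
      msg <- c(msg, sprintf("fold %d: a patient appears in two sets", f))
    if (!setequal(all3, pts))
      msg <- c(msg, sprintf("fold %d: sets do not partition the patients", f))
  }
  if (length(msg)) msg else TRUE
})

#' Training configuration for the frame classifier
#'
#' @slot epochs maximum number of training epochs.
#' @slot batchSize minibatch size.
#' @slot learningRate Adam step size.
#' @slot earlyStoppingPatience epochs without validation-loss improvement
#'   before stopping (ignored without validation data).
#' @slot classWeighting if TRUE, losses are weighted by inverse class
#'   frequency to counter A/B imbalance.
#' @slot seed RNG seed controlling shuffling, augmentation and dropout.
#' @export
setClass("TrainConfig",
  representation(
    epochs = "integer", batchSize = "integer", learningRate = "numeric",
    earlyStoppingPatience = "integer", classWeighting = "logical",
    seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@earlyStoppingPatience < 1L)
    msg <- c(msg, "earlyStoppingPatience must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Truncated-VGG frame classifier
#'
#' A compact convolutional network: the first three VGG16 blocks
#' ((2, 2, 3) convolution layers of (64, 128, 256) 3x3 filters), with
#' 2x2 max-pooling after blocks 1 and 2 only (the third block's pool is
#' removed), followed by global average pooling, dropout and a 2-node
#' softmax head. The forward pass maps one grayscale frame to the
#' probability pair \eqn{[p_A, p_B]}.
#'
#' Weights are stored in the object (portable across sessions); the
#' live compute backend is cached in an environment and rebuilt on
#' demand.
#'
#' @slot inputShape integer height/width of the model input (each
#'   divisible by 4, the total pooling factor).
#' @slot blockFilters filters per convolutional block.
#' @slot blockConvs convolution layers per block.
#' @slot nClasses number of output classes (2: A, B).
#' @slot dropout dropout rate applied after global average pooling.
#' @slot weights list of per-layer weights (`W`, `b`); convolutional `W`
#'   is `(9 * inChannels) x outChannels`, dense `W` is `channels x classes`.
#' @slot seed seed used for weight initialization and dropout.
#' @slot history per-epoch training/validation loss data.frame.
#' @slot trained logical.
#' @slot cache environment holding the live backend pointer.
#' @export
setClass("FrameClassifier",
  representation(
    inputShape = "integer", blockFilters = "integer", blockConvs = "integer",
    nClasses = "integer", dropout = "numeric", weights = "list",
    seed = "integer", history = "data.frame", trained = "logical",
    cache = "environment"
  )
)

setValidity("FrameClassifier", function(object) {
  msg <- character()
  if (length(object@inputShape) != 2L || any(object@inputShape %% 4L != 0L))
    msg <- c(msg, "inputShape must be two dimensions, each divisible by 4")
  if (length(object@blockFilters) != length(object@blockConvs))
    msg <- c(msg, "blockFilters and blockConvs must have equal length")
  if (length(msg)) msg else TRUE
})

#' Threshold setting for clip-level inference
#'
#' @slot t classification threshold: minimum \eqn{p_B} for a frame to
#'   count as a B frame; in \[0.5, 1).
#' @slot tau contiguity threshold: minimum number of consecutive B
#'   frames required to call the clip B-positive; a positive integer.
#' @export
setClass("ThresholdSetting",
  representation(t = "numeric", tau = "integer")
)

setValidity("ThresholdSetting", function(object) {
  msg <- character()
  if (object@t < 0.5 || object@t >= 1)
    msg <- c(msg, "t must lie in [0.5, 1)")
  if (object@tau < 1L) msg <- c(msg, "tau must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Clip-level decision
#'
#' The binary A/B call for one clip under a \eqn{(t, \tau)} setting.
#' `yHat` is 1 (B) iff a triggering window exists: `window` then holds
#' the (start, end) frame indices of the earliest run of exactly `tau`
#' consecutive frames with \eqn{p_B \ge t}; otherwise it has length 0.
#'
#' @slot clipId clip identifier (may be `NA`).
#' @slot yHat integer 0 (A) or 1 (B).
#' @slot window integer (start, end) of the triggering window, or
#'   length 0 when `yHat` is 0.
#' @slot t,tau the threshold setting used.
#' @export
setClass("ClipDecision",
  representation(
    clipId = "character", yHat = "integer", window = "integer",
    t = "numeric", tau = "integer"
  )
)

setValidity("ClipDecision", function(object) {
  msg <- character()
  if ((object@yHat == 1L) != (length(object@window) == 2L))
    msg <- c(msg, "a triggering window must be present iff yHat is 1")
  if (length(object@window) == 2L &&
      diff(object@window) + 1L != object@tau)
    msg <- c(msg, "triggering window length must equal tau")
  if (length(msg)) msg else TRUE
})

#' Confusion matrix with B as the positive class
#'
#' @slot tp,fp,tn,fn non-negative counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer")
)

setValidity("ConfusionMatrix", function(object) {
  if (any(c(object@tp, object@fp, object@tn, object@fn) < 0L))
    "counts must be >= 0" else TRUE
})

#' Sensitivity/specificity surfaces over a threshold grid
#'
#' Result of [thresholdSweep()]: one row per \eqn{(t, \tau)} pair with
#' the clip-level confusion counts, sensitivity (true-positive rate on
#' ground-truth-B clips) and specificity (true-negative rate on
#' ground-truth-A clips).
#'
#' @slot grid data.frame with columns `t`, `tau`, `tp`, `fn`, `tn`,
#'   `fp`, `sensitivity`, `specificity`.
#' @slot tValues,tauValues the grid axes.
#' @slot nB,nA number of ground-truth B and A clips evaluated.
#' @export
setClass("SweepResult",
  representation(grid = "data.frame", tValues = "numeric",
                 tauValues = "integer", nB = "integer", nA = "integer")
)

setValidity("SweepResult", function(object) {
  msg <- character()
  need <- c("t", "tau", "tp", "fn", "tn", "fp", "sensitivity", "specificity")
  if (!all(need %in% names(object@grid)))
    msg <- c(msg, "grid is missing required columns")
  if (nrow(object@grid) != length(object@tValues) * length(object@tauValues))
    msg <- c(msg, "grid is incomplete over the requested threshold values")
  s <- c(object@grid$sensitivity, object@grid$specificity)
  if (any(s < 0 | s > 1, na.rm = TRUE))
    msg <- c(msg, "sensitivity and specificity must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Grad-CAM heatmap
#'
#' Non-negative spatial importance map for one frame and one target
#' class, upsampled to the input size and max-normalized to 1 whenever
#' any activation is positive.
#'
#' @slot importance numeric matrix, same size as the input frame.
#' @slot targetClass `"A"` or `"B"`.
#' @export
setClass("Heatmap",
  representation(importance = "matrix", targetClass = "character")
)

setValidity("Heatmap", function(object) {
  msg <- character()
  if (any(object@importance < 0)) msg <- c(msg, "importance must be >= 0")
  if (!object@targetClass %in% c("A", "B"))
    msg <- c(msg, "targetClass must be 'A' or 'B'")
  if (length(msg)) msg else TRUE
})
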