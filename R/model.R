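#' Training configuration
#'
#' @param epochs maximum epochs (default 10).
#' @param batchSize minibatch size (default 16).
#' @param learningRate Adam step size (default 1e-4).
#' @param earlyStoppingPatience epochs of non-improving validation loss
#'   tolerated before stopping (default 3).
#' @param classWeighting inverse-frequency loss weighting (default TRUE).
#' @param seed RNG seed for shuffling, augmentation and dropout.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 10L, batchSize = 16L,
                        learningRate = 1e-4, earlyStoppingPatience = 3L,
                        classWeighting = TRUE, seed = 0L) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      earlyStoppingPatience = as.integer(earlyStoppingPatience),
      classWeighting = classWeighting, seed = as.integer(seed))
}

#' Build the truncated-VGG frame classifier
#'
#' Constructs the network of [FrameClassifier-class]: three
#' convolutional blocks of (2, 2, 3) layers with (64, 128, 256) 3x3
#' single-stride filters and spatial-preserving padding, 2x2 max-pooling
#' after blocks 1 and 2 only (so the spatial downsampling factor is
#' exactly 4), then global average pooling, dropout and a 2-node softmax
#' head. Weights are He-initialized from `seed`; optionally a weight
#' list saved from another model (e.g. pretrained) can be supplied.
#'
#' @param inputShape integer `c(height, width)`, each divisible by 4.
#' @param blockFilters,blockConvs architecture plan (defaults above).
#' @param dropout dropout rate after global average pooling.
#' @param seed seed for weight initialization and dropout noise.
#' @param weights optional weight list (as stored in the `weights` slot)
#'   used instead of random initialization.
#' @return An untrained [FrameClassifier-class].
#' @examples
#' m <- buildFrameClassifier(c(32L, 32L))
#' nParameters(m)
#' @export
buildFrameClassifier <- function(inputShape = c(128L, 128L),
                                 blockFilters = c(64L, 128L, 256L),
                                 blockConvs = c(2L, 2L, 3L),
                                 dropout = 0.5, seed = 0L,
                                 weights = NULL) {
  inputShape <- as.integer(inputShape)
  if (length(inputShape) != 2L || any(inputShape %% 4L != 0L))
    stop("inputShape must be c(height, width) with both divisible by 4 ",
         "(two 2x2 pooling stages)")
  model <- new("FrameClassifier", inputShape = inputShape,
               blockFilters = as.integer(blockFilters),
               blockConvs = as.integer(blockConvs), nClasses = 2L,
               dropout = dropout, weights = list(),
               seed = as.integer(seed),
               history = data.frame(), trained = FALSE,
               cache = new.env(parent = emptyenv()))
  ptr <- .newNet(model)
  if (!is.null(weights)) .cnn_set_weights(ptr, weights)
  model@weights <- .cnn_get_weights(ptr)
  model@cache$ptr <- ptr
  model
}

.newNet <- function(model) {
  .cnn_create(model@inputShape[1], model@inputShape[2], 1L,
              model@blockFilters, model@blockConvs, model@nClasses,
              model@dropout, model@seed)
}

# live backend handle; rebuilt from the stored weights when the cached
# external pointer is absent or stale (e.g. after deserialization)
.liveNet <- function(model) {
  ptr <- model@cache$ptr
  if (is.null(ptr) || !.cnn_is_valid(ptr)) {
    ptr <- .newNet(model)
    if (length(model@weights)) .cnn_set_weights(ptr, model@weights)
    model@cache$ptr <- ptr
  }
  ptr
}

#' @rdname lusBline-accessors
#' @export
setMethod("nParameters", "FrameClassifier", function(object) {
  inC <- 1L
  n <- 0
  for (b in seq_along(object@blockFilters)) {
    outC <- object@blockFilters[b]
    for (k in seq_len(object@blockConvs[b])) {
      n <- n + 9 * inC * outC + outC
      inC <- outC
    }
  }
  n + inC * object@nClasses + object@nClasses
})

# coerce assorted inputs to an H x W x N frame array at the model size,
# resizing bilinearly when needed
.asFrameArray <- function(x, inputShape) {
  if (is(x, "LUSClip")) x <- x@frames
  if (is(x, "LUSFrame")) x <- x@pixels
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  if (d[3] == 0L) stop("empty clip: no frames to process")
  if (d[1] != inputShape[1] || d[2] != inputShape[2]) {
    out <- array(0, c(inputShape, d[3]))
    for (i in seq_len(d[3])) {
      img <- EBImage::resize(EBImage::Image(t(x[, , i])),
                             w = inputShape[2], h = inputShape[1])
      out[, , i] <- t(EBImage::imageData(img))
    }
    x <- pmin(pmax(out, 0), 1)
  }
  x
}

.labelsToInt <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("A", "B"))) stop("labels must be 'A' or 'B'")
    return(as.integer(y == "B"))
  }
  as.integer(y)
}

#' Train the frame classifier
#'
#' Minibatch Adam training with binary cross-entropy, optional
#' inverse-frequency class weighting, stochastic augmentation applied to
#' training batches only, and early stopping on validation loss (the
#' best-validation weights are restored). Deterministic for a fixed
#' `config@seed`: shuffling, augmentation draws and dropout masks all
#' derive from it.
#'
#' @param model a [FrameClassifier-class].
#' @param x training frames, `H x W x N` array (masked grayscale, values
#'   in \[0, 1\]).
#' @param y training labels, `"A"`/`"B"` (or 0/1 with 1 = B).
#' @param xVal,yVal optional validation frames/labels.
#' @param config a [TrainConfig-class].
#' @param augment an [AugmentationRanges-class], or `NULL` to disable
#'   augmentation.
#' @return The trained model, with `history` holding per-epoch losses.
#' @export
trainFrameClassifier <- function(model, x, y, xVal = NULL, yVal = NULL,
                                 config = trainConfig(),
                                 augment = augmentationRanges()) {
  stopifnot(is(model, "FrameClassifier"), is(config, "TrainConfig"))
  validObject(config)
  x <- .asFrameArray(x, model@inputShape)
  y <- .labelsToInt(y)
  stopifnot(dim(x)[3] == length(y))
  if (length(unique(y)) < 2L)
    stop("training pool must contain both classes (A and B)")
  w <- if (config@classWeighting) {
    nc <- tabulate(y + 1L, 2L)
    length(y) / (2 * nc)
  } else c(1, 1)
  if (config@epochs == 0L) return(model)

  # a fresh backend makes the dropout stream a pure function of the seed
  ptr <- .newNet(model)
  if (length(model@weights)) .cnn_set_weights(ptr, model@weights)
  model@cache$ptr <- ptr

  hasVal <- !is.null(xVal)
  if (hasVal) {
    xVal <- .asFrameArray(xVal, model@inputShape)
    yVal <- .labelsToInt(yVal)
  }
  evalLoss <- function() {
    p <- .cnn_forward(ptr, xVal)
    pTruth <- p[cbind(seq_along(yVal), yVal + 1L)]
    list(loss = mean(-w[yVal + 1L] * log(pmax(pTruth, 1e-12))),
         acc = mean((p[, 2] >= 0.5) == (yVal == 1L)))
  }

  n <- length(y)
  best <- list(loss = Inf, weights = NULL, wait = 0L)
  hist <- data.frame()
  .withSeed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config@batchSize)
      trainLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config@batchSize - 1L, n)]
        xb <- x[, , idx, drop = FALSE]
        if (!is.null(augment))
          for (j in seq_along(idx))
            xb[, , j] <- augmentFrame(xb[, , j], augment)
        trainLoss <- trainLoss +
          .cnn_train_batch(ptr, xb, y[idx], w, config@learningRate) *
          length(idx)
      }
      trainLoss <- trainLoss / n
      row <- data.frame(epoch = epoch, trainLoss = trainLoss,
                        valLoss = NA_real_, valAcc = NA_real_)
      if (hasVal) {
        v <- evalLoss()
        row$valLoss <- v$loss; row$valAcc <- v$acc
        if (v$loss < best$loss - 1e-6) {
          best$loss <- v$loss
          best$weights <- .cnn_get_weights(ptr)
          best$wait <- 0L
        } else {
          best$wait <- best$wait + 1L
        }
      }
      hist <- rbind(hist, row)
      if (hasVal && best$wait >= config@earlyStoppingPatience) break
    }
  })
  if (hasVal && !is.null(best$weights)) {
    model@weights <- best$weights
    .cnn_set_weights(ptr, best$weights)
  } else {
    model@weights <- .cnn_get_weights(ptr)
  }
  model@history <- hist
  model@trained <- TRUE
  model
}

#' Frame-wise prediction
#'
#' Applies the classifier independently to every frame of a clip (or
#' array of frames); predictions are a pure, order-preserving function
#' of the pixels with no temporal coupling. Frames are resized to the
#' model input shape when needed.
#'
#' @param model a [FrameClassifier-class].
#' @param clip a [LUSClip-class], `H x W x N` array, matrix or
#'   [LUSFrame-class].
#' @return A data.frame with one row per frame: `clipId`, `frameIndex`,
#'   `pA`, `pB`, `predictedClass` (argmax).
#' @export
predictFrames <- function(model, clip) {
  stopifnot(is(model, "FrameClassifier"))
  cid <- if (is(clip, "LUSClip")) clip@clipId else NA_character_
  x <- .asFrameArray(clip, model@inputShape)
  p <- .cnn_forward(.liveNet(model), x)
  data.frame(clipId = cid, frameIndex = seq_len(nrow(p)),
             pA = p[, 1], pB = p[, 2],
             predictedClass = ifelse(p[, 2] > p[, 1], "B", "A"),
             stringsAsFactors = FALSE)
}
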