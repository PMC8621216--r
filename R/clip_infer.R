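#' Threshold setting constructor
#'
#' @param t classification threshold in \[0.5, 1).
#' @param tau contiguity threshold, positive integer.
#' @return A [ThresholdSetting-class].
#' @export
thresholdSetting <- function(t = 0.7, tau = 3L) {
  new("ThresholdSetting", t = t, tau = as.integer(tau))
}

.checkProbs <- function(pB) {
  if (length(pB) == 0L) stop("empty probability sequence: a clip must ",
                             "have at least one frame")
  if (anyNA(pB) || any(pB < 0 | pB > 1))
    stop("frame probabilities must lie in [0, 1]")
}

# run lengths of frames with pB >= t; returns start indices and lengths
.bRuns <- function(pB, t) {
  r <- rle(pB >= t)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(starts = starts[keep], lengths = r$lengths[keep])
}

#' Clip classification by the contiguity rule
#'
#' A clip is called B-positive iff at least one window of exactly `tau`
#' consecutive frames has B-line probability at or above `t` in every
#' frame (inclusive comparison):
#' \deqn{\hat y = 1\!\left[\bigvee_{i=1}^{n-\tau+1}
#'       \bigwedge_{j=i}^{i+\tau-1} (p_{Bj} \ge t)\right]}
#' For `n < tau` the admissible window range is empty and the decision
#' is A. The earliest-starting triggering window is reported.
#'
#' @param pB ordered per-frame B-line probabilities (acquisition order).
#' @param setting a [ThresholdSetting-class], or `NULL` to use `t`, `tau`.
#' @param t,tau threshold values used when `setting` is `NULL`.
#' @param clipId optional identifier carried into the result.
#' @return A [ClipDecision-class].
#' @examples
#' classifyClip(c(0.9, 0.6, 0.9, 0.9), t = 0.7, tau = 2)  # window 3-4
#' classifyClip(c(0.9, 0.6, 0.9), t = 0.7, tau = 2)       # no run: A
#' @export
classifyClip <- function(pB, setting = NULL, t = 0.7, tau = 3L,
                         clipId = NA_character_) {
  if (!is.null(setting)) { t <- setting@t; tau <- setting@tau }
  tau <- as.integer(tau)
  validObject(new("ThresholdSetting", t = t, tau = tau))
  .checkProbs(pB)
  runs <- .bRuns(pB, t)
  hit <- which(runs$lengths >= tau)
  if (length(hit)) {
    s <- runs$starts[hit[1]]
    new("ClipDecision", clipId = as.character(clipId), yHat = 1L,
        window = c(s, s + tau - 1L), t = t, tau = tau)
  } else {
    new("ClipDecision", clipId = as.character(clipId), yHat = 0L,
        window = integer(), t = t, tau = tau)
  }
}

#' Clip classification by probability averaging
#'
#' The baseline rule appropriate for homogeneous clips: the clip is
#' called B-positive iff the mean frame B-line probability is at or
#' above `threshold`. On heterogeneous clips, where short B-frame runs
#' sit in a long A background, the mean is dragged below threshold and
#' the clip is falsely called negative — the failure mode the
#' contiguity rule of [classifyClip()] addresses.
#'
#' @param pB ordered per-frame B-line probabilities.
#' @param threshold decision threshold on the mean (default 0.5,
#'   inclusive).
#' @param clipId optional identifier.
#' @return A [ClipDecision-class] (with `t` set to `threshold` and
#'   `tau` to 1; no triggering window semantics).
#' @examples
#' classifyClipAveraging(c(rep(0.9, 10), rep(0.1, 40)))  # mean 0.26: A
#' @export
classifyClipAveraging <- function(pB, threshold = 0.5,
                                  clipId = NA_character_) {
  .checkProbs(pB)
  y <- as.integer(mean(pB) >= threshold)
  new("ClipDecision", clipId = as.character(clipId), yHat = y,
      window = if (y == 1L) c(1L, 1L) else integer(),
      t = threshold, tau = 1L)
}

#' Sweep the (t, tau) threshold grid
#'
#' Evaluates the contiguity rule of [classifyClip()] at every
#' combination of classification threshold and contiguity threshold on
#' a set of clips with ground truth, recording clip-level sensitivity
#' (true-positive rate over B clips) and specificity (true-negative
#' rate over A clips) for each grid point.
#'
#' @param clipProbs list of per-clip probability vectors (each ordered
#'   by acquisition).
#' @param labels ground-truth clip labels, `"A"`/`"B"`, aligned with
#'   `clipProbs`.
#' @param tValues classification threshold grid (default 0.5 to 0.9 by
#'   0.1).
#' @param tauValues contiguity threshold grid (default 1 to 40).
#' @return A [SweepResult-class].
#' @examples
#' probs <- list(rep(0.95, 10), c(rep(0.1, 8), 0.95, 0.95), rep(0.2, 10))
#' sweepRes <- thresholdSweep(probs, c("B", "B", "A"), tauValues = 1:4)
#' head(sweepGrid(sweepRes))
#' @export
thresholdSweep <- function(clipProbs, labels,
                           tValues = seq(0.5, 0.9, by = 0.1),
                           tauValues = 1:40) {
  stopifnot(length(clipProbs) == length(labels))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("sweep needs both A and B clips in the evaluation set")
  tauValues <- as.integer(tauValues)
  lapply(clipProbs, .checkProbs)
  isB <- labels == "B"
  nB <- sum(isB); nA <- sum(!isB)
  grid <- expand.grid(tau = tauValues, t = tValues)[, c("t", "tau")]
  # the decision at (t, tau) is maxrun(t) >= tau, so one pass over runs
  # per t serves the whole tau axis
  sens <- spec <- tp <- fn <- tn <- fp <- numeric(nrow(grid))
  row <- 1L
  for (t in tValues) {
    maxRun <- vapply(clipProbs, function(p) {
      r <- .bRuns(p, t)
      if (length(r$lengths)) max(r$lengths) else 0L
    }, integer(1))
    for (tau in tauValues) {
      yHat <- maxRun >= tau
      tp[row] <- sum(yHat & isB); fn[row] <- sum(!yHat & isB)
      fp[row] <- sum(yHat & !isB); tn[row] <- sum(!yHat & !isB)
      sens[row] <- tp[row] / nB; spec[row] <- tn[row] / nA
      row <- row + 1L
    }
  }
  grid$tp <- as.integer(tp); grid$fn <- as.integer(fn)
  grid$tn <- as.integer(tn); grid$fp <- as.integer(fp)
  grid$sensitivity <- sens; grid$specificity <- spec
  new("SweepResult", grid = grid, tValues = tValues,
      tauValues = tauValues, nB = as.integer(nB), nA = as.integer(nA))
}

#' Select the operating point of a sweep
#'
#' Returns the grid point maximizing `criterion` (by default combined
#' sensitivity + specificity). Ties are broken in favour of the smaller
#' contiguity threshold, then the smaller classification threshold.
#'
#' @param sweep a [SweepResult-class].
#' @param criterion function of `(sensitivity, specificity)` returning
#'   the value to maximize.
#' @return A [ThresholdSetting-class]; the achieved sensitivity and
#'   specificity are attached as attributes `sensitivity` and
#'   `specificity`.
#' @export
selectOperatingPoint <- function(sweep,
                                 criterion = function(sens, spec)
                                   sens + spec) {
  stopifnot(is(sweep, "SweepResult"))
  g <- sweep@grid
  val <- criterion(g$sensitivity, g$specificity)
  ord <- order(-val, g$tau, g$t)
  bestRow <- g[ord[1], ]
  out <- thresholdSetting(bestRow$t, bestRow$tau)
  attr(out, "sensitivity") <- bestRow$sensitivity
  attr(out, "specificity") <- bestRow$specificity
  out
}

#' Classify a prediction table clip by clip
#'
#' Convenience wrapper applying [classifyClip()] to a frame-level
#' prediction table (as produced by [predictFrames()], rows ordered by
#' `frameIndex` within `clipId`).
#'
#' @param predictions data.frame with columns `clipId`, `frameIndex`,
#'   `pB`.
#' @param setting a [ThresholdSetting-class].
#' @return data.frame with columns `clipId`, `yHat`, `windowStart`,
#'   `windowEnd`.
#' @export
classifyClips <- function(predictions, setting = thresholdSetting()) {
  stopifnot(all(c("clipId", "frameIndex", "pB") %in% names(predictions)))
  ids <- unique(predictions$clipId)
  rows <- lapply(ids, function(cid) {
    sub <- predictions[predictions$clipId == cid, ]
    sub <- sub[order(sub$frameIndex), ]
    d <- classifyClip(sub$pB, setting, clipId = cid)
    data.frame(clipId = cid, yHat = d@yHat,
               windowStart = if (length(d@window)) d@window[1] else NA,
               windowEnd = if (length(d@window)) d@window[2] else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot sensitivity/specificity curves of a sweep
#'
#' Draws, for each classification threshold, sensitivity (solid) and
#' specificity (dashed) as functions of the contiguity threshold —
#' the usual way of exploring how the two hyperparameters trade off.
#'
#' @param sweep a [SweepResult-class].
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, the sweep grid.
#' @export
plotSweep <- function(sweep, ...) {
  g <- sweep@grid
  ts <- sweep@tValues
  cols <- seq_along(ts)
  sensM <- sapply(ts, function(t) g$sensitivity[g$t == t])
  specM <- sapply(ts, function(t) g$specificity[g$t == t])
  graphics::matplot(sweep@tauValues, sensM, type = "l", lty = 1,
                    col = cols, ylim = c(0, 1),
                    xlab = "contiguity threshold (tau)",
                    ylab = "sensitivity (solid) / specificity (dashed)",
                    ...)
  graphics::matlines(sweep@tauValues, specM, lty = 2, col = cols)
  graphics::legend("bottomright", legend = sprintf("t = %.1f", ts),
                   col = cols, lty = 1, cex = 0.8)
  invisible(g)
}
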