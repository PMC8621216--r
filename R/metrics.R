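#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney U statistic normalized by
#' `nPos * nNeg`: the probability that a random positive instance
#' scores above a random negative one, ties contributing 1/2. It is
#' therefore invariant under strictly monotone transforms of the
#' scores. Curve points are the (FPR, TPR) pairs obtained by sweeping
#' the decision threshold through the observed scores.
#'
#' @param scores numeric scores (here: per-frame or per-clip `pB`).
#' @param labels ground truth, `"A"`/`"B"` (or 0/1 with 1 = positive).
#' @param positive label of the positive class (default `"B"`).
#' @return List with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`, monotone non-decreasing).
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c("A", "A", "B", "B"))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels, positive = "B") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("ROC/AUC needs both classes present in the labels")
  r <- rank(scores)                      # midranks: ties count 1/2
  auc <- (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / nP, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / nN, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

#' Confusion matrix with B-line as the positive class
#'
#' @param predicted predicted labels, `"A"`/`"B"` (or 0/1 decisions).
#' @param truth ground-truth labels, aligned with `predicted`.
#' @param positive positive class label (default `"B"`).
#' @return A [ConfusionMatrix-class].
#' @examples
#' confusionCounts(c("B", "A", "B"), c("B", "B", "B"))
#' @export
confusionCounts <- function(predicted, truth, positive = "B") {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (is.numeric(predicted))
    predicted <- ifelse(predicted == 1, positive, setdiff(c("A", "B"),
                                                          positive))
  p <- predicted == positive
  t <- truth == positive
  new("ConfusionMatrix",
      tp = as.integer(sum(p & t)), fp = as.integer(sum(p & !t)),
      tn = as.integer(sum(!p & !t)), fn = as.integer(sum(!p & t)))
}

#' Summary metrics from a confusion matrix
#'
#' Accuracy, precision, recall/sensitivity, F1 and specificity, with
#' B-line as the positive class; specificity is computed on the A class
#' only. Metrics with empty denominators are `NA`.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param auc optional AUC to include in the report.
#' @return One-row data.frame with columns `accuracy`, `auc`,
#'   `precision`, `recall_sensitivity`, `f1`, `specificity`.
#' @examples
#' cm <- new("ConfusionMatrix", tp = 9L, fn = 1L, tn = 23L, fp = 2L)
#' metricReport(cm)   # sensitivity 0.9, specificity 0.92
#' @export
metricReport <- function(cm, auc = NA_real_) {
  stopifnot(is(cm, "ConfusionMatrix"))
  total <- cm@tp + cm@fp + cm@tn + cm@fn
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- div(cm@tp, cm@tp + cm@fp)
  rec <- div(cm@tp, cm@tp + cm@fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  data.frame(accuracy = div(cm@tp + cm@tn, total), auc = auc,
             precision = prec, recall_sensitivity = rec, f1 = f1,
             specificity = div(cm@tn, cm@tn + cm@fp))
}

#' Aggregate per-fold metric reports
#'
#' Mean and sample (n-1) standard deviation of each metric across the
#' folds of a cross-validation experiment.
#'
#' @param reports list of one-row data.frames from [metricReport()]
#'   (one per fold), or a data.frame with one row per fold.
#' @return data.frame with rows `mean` and `sd`.
#' @examples
#' r <- list(data.frame(auc = 0.9), data.frame(auc = 1.0))
#' aggregateFolds(r)   # mean 0.95, sd ~0.0707
#' @export
aggregateFolds <- function(reports) {
  if (is.data.frame(reports)) reports <- split(reports,
                                               seq_len(nrow(reports)))
  if (length(reports) == 0L) stop("no fold reports to aggregate")
  if (length(reports) < 2L)
    stop("fold aggregation needs at least 2 folds")
  df <- do.call(rbind, reports)
  out <- rbind(vapply(df, mean, numeric(1), na.rm = TRUE),
               vapply(df, sd, numeric(1), na.rm = TRUE))
  out <- as.data.frame(out)
  rownames(out) <- c("mean", "sd")
  out
}

#' Render a confusion matrix to PNG
#'
#' Draws the 2x2 count matrix as a shaded block image (rows: truth B,
#' A; columns: predicted B, A; darker = larger count), written without
#' a graphics device so it works headless.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param file PNG output path.
#' @param cell pixel size of one cell.
#' @return Invisibly, the image array.
#' @export
renderConfusionMatrix <- function(cm, file, cell = 64L) {
  counts <- matrix(c(cm@tp, cm@fn, cm@fp, cm@tn), 2, 2)
  shade <- 1 - counts / max(1, max(counts))     # dark = many
  img <- kronecker(shade, matrix(1, cell, cell))
  # thin grid lines
  img[c(cell, cell + 1), ] <- 0
  img[, c(cell, cell + 1)] <- 0
  png::writePNG(img, file)
  invisible(img)
}

#' Format an aggregated metric table
#'
#' Renders the output of [aggregateFolds()] in the conventional
#' `mean (SD sd)` layout.
#'
#' @param agg data.frame from [aggregateFolds()].
#' @param digits significant digits.
#' @return Named character vector.
#' @export
formatMetricTable <- function(agg, digits = 3) {
  vapply(names(agg), function(nm)
    sprintf("%.*f (SD %.*f)", digits, agg["mean", nm], digits,
            agg["sd", nm]),
    character(1))
}
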