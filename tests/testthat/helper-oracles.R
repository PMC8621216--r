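# Independent oracles used against the package implementations.

# literal all-windows scan of the contiguity rule: enumerate every
# window of length tau and test whether all its probabilities are >= t
bruteForceClipDecision <- function(pB, t, tau) {
  n <- length(pB)
  if (n < tau) return(0L)
  ind <- as.numeric(pB >= t)
  windows <- embed(ind, tau)          # one row per window
  as.integer(any(rowSums(windows) == tau))
}

# AUC by explicit pair counting (ties count 1/2)
bruteForceAuc <- function(scores, labels, positive = "B") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Hand-written frame classifier for the phantom: a column crossed by a
# B-line ray stays bright over most of the depth below the pleural
# line, whereas A-frame columns are bright only at thin reverberation
# bands. Completely independent of the CNN.
oracleFrameLabel <- function(frame) {
  s <- frame@sector
  px <- frame@pixels
  H <- nrow(px); W <- ncol(px)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  rho <- sqrt((rows - s$apexRow)^2 + (cols - s$apexCol)^2)
  theta <- atan2(cols - s$apexCol, rows - s$apexRow)
  inSector <- abs(theta) <= s$angleRad / 2 & rho >= s$rmin & rho <= s$rmax
  region <- inSector & rho > s$rhoP + 6
  frac <- vapply(seq_len(W), function(j) {
    v <- px[region[, j], j]
    if (length(v) < 12) return(0)
    mean(v > 0.42)
  }, numeric(1))
  if (max(frac) > 0.5) "B" else "A"
}

# severity taxonomy recomputed from ray geometry, independent of the
# generator's internals
oracleSeverity <- function(count, coverage) {
  if (count == 0) "none"
  else if (count < 3) "mild"
  else if (coverage < 0.5) "moderate"
  else "severe"
}

# manifest with the generator's column layout but no pixel data; enough
# for split/routing logic
fakeManifest <- function(nPatients, clipsPerPatient = 3L,
                         bFraction = 0.38, hetFraction = 0.44,
                         frameTrainFraction = 0.6, seed = 1) {
  withr::local_seed(seed)
  nB <- round(bFraction * nPatients)
  cls <- sample(rep(c("B", "A"), c(nB, nPatients - nB)))
  rows <- list()
  for (p in seq_len(nPatients)) {
    for (ci in seq_len(clipsPerPatient)) {
      pid <- sprintf("P%03d", p)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, clip_id = sprintf("%s_C%02d", pid, ci),
        path = NA_character_, clip_label = cls[p],
        severity = if (cls[p] == "A") "none" else "moderate",
        homogeneity = "homogeneous", n_frames = 40L, batch = 1L,
        stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  bIdx <- which(man$clip_label == "B")
  het <- sample(bIdx, round(hetFraction * length(bIdx)))
  man$homogeneity[het] <- "heterogeneous"
  man$batch[het] <- 2L
  homoIdx <- which(man$homogeneity == "homogeneous")
  late <- sample(homoIdx, round((1 - frameTrainFraction) * length(homoIdx)))
  man$batch[late] <- 2L
  man
}

# small 3-block classifier for fast unit tests
tinyClassifier <- function(inputShape = c(16L, 16L), seed = 1L,
                           dropout = 0.0) {
  buildFrameClassifier(inputShape, blockFilters = c(4L, 6L, 8L),
                       blockConvs = c(1L, 1L, 1L), dropout = dropout,
                       seed = seed)
}
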