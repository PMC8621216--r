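#' Patient-grouped, class-stratified K-fold plan
#'
#' Patients (never clips) are partitioned into `k` folds, stratified by
#' each patient's majority clip class so both classes appear in every
#' test fold. For fold `f`, the test set is fold `f`'s patients; a
#' fraction of the remaining patients (stratified, at least one per
#' class) is held out for validation and the rest train. All clips of a
#' patient therefore fall in exactly one of train/validation/test in
#' every fold.
#'
#' @param manifest a cohort manifest with columns `patient_id` and
#'   `clip_label` (see [generateCohort()]).
#' @param k number of folds (default 10).
#' @param validationFraction fraction of non-test patients used for
#'   validation (default 0.1).
#' @param seed seed for a reproducible plan.
#' @return A [FoldPlan-class].
#' @examples
#' coh <- generateCohort(nPatients = 8, seed = 1,
#'                       nFramesRange = c(6L, 8L))
#' makeFolds(coh$manifest, k = 2, seed = 1)
#' @export
makeFolds <- function(manifest, k = 10L, validationFraction = 0.1,
                      seed = NULL) {
  stopifnot(all(c("patient_id", "clip_label") %in% names(manifest)))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  # majority class per patient
  tab <- table(manifest$patient_id, manifest$clip_label)
  cls <- colnames(tab)[max.col(tab, ties.method = "first")]
  names(cls) <- rownames(tab)
  counts <- table(cls)
  short <- names(counts)[counts < k]
  if (length(short) || length(counts) < 2L)
    stop("need at least ", k, " patients per class for ", k,
         "-fold patient-grouped cross-validation; got ",
         paste(names(counts), as.integer(counts), collapse = ", "))
  .withSeed(seed, {
    # deal shuffled patients class by class, continuing around the folds
    # so fold sizes stay balanced overall as well as per class
    assignment <- integer(0)
    off <- 0L
    for (cl in names(counts)) {
      pts <- sample(names(cls)[cls == cl])
      idx <- ((off + seq_along(pts) - 1L) %% k) + 1L
      assignment <- c(assignment, setNames(idx, pts))
      off <- (off + length(pts)) %% k
    }
    folds <- vector("list", k)
    for (f in seq_len(k)) {
      test <- names(assignment)[assignment == f]
      rest <- setdiff(names(assignment), test)
      val <- character()
      for (cl in names(counts)) {
        pool <- rest[cls[rest] == cl]
        nVal <- max(1L, ceiling(validationFraction * length(pool)))
        val <- c(val, sample(pool, min(nVal, length(pool) - 1L)))
      }
      folds[[f]] <- list(train = setdiff(rest, val), validation = val,
                         test = test)
    }
    new("FoldPlan", k = k, assignment = assignment, folds = folds,
        validationFraction = validationFraction,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  })
}

#' Patient sets of one fold
#'
#' @param plan a [FoldPlan-class].
#' @param fold fold index in `1:k`.
#' @return List with character vectors `train`, `validation`, `test`.
#' @export
foldSets <- function(plan, fold) {
  stopifnot(is(plan, "FoldPlan"), fold >= 1L, fold <= plan@k)
  plan@folds[[fold]]
}

#' Route clips between the frame-training and clip-inference pools
#'
#' Frame-level supervision is only valid on homogeneous clips (the clip
#' label holds for every frame), and clips used for clip-level
#' validation must not have fed frame training. The manifest's `batch`
#' marker stands in for a labelling-date cutoff: the frame pool is the
#' homogeneous clips labelled at or before the cutoff; the clip pool is
#' all heterogeneous clips plus the homogeneous clips labelled after it.
#' The two pools never share a clip id.
#'
#' @param manifest a cohort manifest with columns `homogeneity` and
#'   `batch`.
#' @param cutoff batch marker cutoff (default 1).
#' @return List of two manifest subsets, `framePool` and `clipPool`.
#' @examples
#' coh <- generateCohort(nPatients = 6, seed = 2,
#'                       nFramesRange = c(6L, 8L))
#' pools <- routePools(coh$manifest)
#' intersect(pools$framePool$clip_id, pools$clipPool$clip_id)
#' @export
routePools <- function(manifest, cutoff = 1L) {
  stopifnot(all(c("homogeneity", "batch", "clip_id") %in% names(manifest)))
  homo <- manifest$homogeneity == "homogeneous"
  frameSel <- homo & manifest$batch <= cutoff
  framePool <- manifest[frameSel, , drop = FALSE]
  clipPool <- manifest[!frameSel, , drop = FALSE]
  stopifnot(length(intersect(framePool$clip_id, clipPool$clip_id)) == 0L)
  list(framePool = framePool, clipPool = clipPool)
}

#' Per-fold data volume summary
#'
#' Mean and standard deviation, across folds, of the number of
#' patients, clips and frames per class in each of the train,
#' validation and test sets — the usual cross-validation reporting
#' shape.
#'
#' @param plan a [FoldPlan-class].
#' @param manifest the cohort manifest.
#' @return A data.frame with one row per class x set and columns
#'   `patients_mean`, `patients_sd`, `clips_mean`, `clips_sd`,
#'   `frames_mean`, `frames_sd`.
#' @export
foldSummary <- function(plan, manifest) {
  sets <- c("train", "validation", "test")
  classes <- sort(unique(manifest$clip_label))
  out <- expand.grid(class = classes, set = sets,
                     stringsAsFactors = FALSE)
  for (m in c("patients", "clips", "frames"))
    out[[paste0(m, "_mean")]] <- out[[paste0(m, "_sd")]] <- NA_real_
  for (r in seq_len(nrow(out))) {
    vals <- vapply(seq_len(plan@k), function(f) {
      pts <- plan@folds[[f]][[out$set[r]]]
      sub <- manifest[manifest$patient_id %in% pts &
                      manifest$clip_label == out$class[r], , drop = FALSE]
      c(length(unique(sub$patient_id)), nrow(sub), sum(sub$n_frames))
    }, numeric(3))
    for (i in seq_along(c("patients", "clips", "frames"))) {
      m <- c("patients", "clips", "frames")[i]
      out[[paste0(m, "_mean")]][r] <- mean(vals[i, ])
      out[[paste0(m, "_sd")]][r] <- sd(vals[i, ])
    }
  }
  out
}

#' Serialize a fold plan to JSON
#'
#' @param plan a [FoldPlan-class].
#' @param path output file.
#' @export
writeFoldPlan <- function(plan, path) {
  obj <- list(k = plan@k,
              validationFraction = plan@validationFraction,
              seed = plan@seed,
              assignment = as.list(plan@assignment),
              folds = plan@folds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a fold plan from JSON
#'
#' @param path file written by [writeFoldPlan()].
#' @return A [FoldPlan-class].
#' @export
readFoldPlan <- function(path) {
  obj <- jsonlite::read_json(path)
  folds <- lapply(obj$folds, function(s)
    list(train = as.character(unlist(s$train)),
         validation = as.character(unlist(s$validation)),
         test = as.character(unlist(s$test))))
  seed <- obj$seed
  new("FoldPlan", k = as.integer(obj$k),
      assignment = setNames(as.integer(unlist(obj$assignment)),
                            names(obj$assignment)),
      folds = folds, validationFraction = obj$validationFraction,
      seed = if (is.null(seed) || is.character(seed)) NA_real_
             else as.numeric(seed))
}
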