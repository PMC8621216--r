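#' Create a phantom generator configuration
#'
#' Defaults give a 128 x 128 sector scan with the pleural line at one
#' quarter depth, three A-line reverberations and three B-line rays of
#' 4 px width.
#'
#' @param imageHeight,imageWidth frame dimensions in pixels.
#' @param sectorAngle full sector opening angle, degrees.
#' @param pleuralDepthFraction pleural line depth as a fraction of image
#'   height, in (0.05, 0.5).
#' @param nALines number of A-line reverberations in A frames.
#' @param bLineCount number of B-line rays in B frames.
#' @param bLineWidth ray width in pixels at the pleural line.
#' @param speckleSigma multiplicative speckle noise level.
#' @param brightnessJitter per-frame brightness jitter fraction.
#' @return A [PhantomConfig-class] object.
#' @examples
#' cfg <- phantomConfig(bLineCount = 5L)
#' cfg
#' @export
phantomConfig <- function(imageHeight = 128L, imageWidth = 128L,
                          sectorAngle = 70, pleuralDepthFraction = 0.25,
                          nALines = 3L, bLineCount = 3L, bLineWidth = 4,
                          speckleSigma = 0.12, brightnessJitter = 0.08) {
  new("PhantomConfig",
      imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth),
      sectorAngle = sectorAngle,
      pleuralDepthFraction = pleuralDepthFraction,
      nALines = as.integer(nALines), bLineCount = as.integer(bLineCount),
      bLineWidth = bLineWidth, speckleSigma = speckleSigma,
      brightnessJitter = brightnessJitter)
}

# Sector geometry in pixel coordinates. The (virtual) probe apex sits
# above the top edge so the fan widens with depth like a phased-array
# scan; rho/theta are polar coordinates about the apex and rhoP is the
# radius of the pleural arc.
.sectorGeometry <- function(cfg) {
  H <- cfg@imageHeight; W <- cfg@imageWidth
  apexRow <- -0.15 * H
  apexCol <- (W + 1) / 2
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  dr <- rows - apexRow
  dc <- cols - apexCol
  rho <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)           # 0 = straight down
  angleRad <- cfg@sectorAngle * pi / 180
  rmin <- 0.05 * H - apexRow       # skin surface just below the top edge
  rmax <- 1.02 * H - apexRow
  mask <- abs(theta) <= angleRad / 2 & rho >= rmin & rho <= rmax
  rhoP <- cfg@pleuralDepthFraction * H - apexRow
  list(apexRow = apexRow, apexCol = apexCol, rho = rho, theta = theta,
       mask = mask, angleRad = angleRad, rmin = rmin, rmax = rmax,
       rhoP = rhoP)
}

.sectorInfo <- function(geom) {
  geom[c("apexRow", "apexCol", "angleRad", "rmin", "rmax", "rhoP")]
}

# classify severity from ray count and pleural-line coverage:
# mild = fewer than 3 rays; otherwise moderate/severe split at 50%
# coverage of the pleural line
.classifySeverity <- function(count, coverage) {
  if (count == 0L) "none"
  else if (count < 3L) "mild"
  else if (coverage < 0.5) "moderate"
  else "severe"
}

# fraction of the pleural arc covered by rays, for a config
.rayCoverage <- function(cfg, geom, count = cfg@bLineCount) {
  extent <- geom$rhoP * geom$angleRad   # pleural arc length, px
  min(1, count * cfg@bLineWidth / extent)
}

# ray count and width realizing a requested severity grade
.severityParams <- function(severity, cfg, geom) {
  extent <- geom$rhoP * geom$angleRad
  switch(severity,
    none = list(count = 0L, width = cfg@bLineWidth),
    mild = list(count = sample(1:2, 1), width = cfg@bLineWidth),
    moderate = {
      count <- sample(3:4, 1)
      width <- min(cfg@bLineWidth, 0.35 * extent / count)
      list(count = count, width = max(1.5, width))
    },
    severe = {
      count <- sample(5:7, 1)
      cov <- runif(1, 0.55, 0.75)
      list(count = count, width = cov * extent / count)
    },
    stop("unknown severity: ", severity)
  )
}

# draw ray centre angles with a minimal angular separation
.drawRayAngles <- function(n, geom, widthAngle) {
  if (n == 0L) return(numeric())
  half <- geom$angleRad / 2 * 0.85
  for (attempt in 1:50) {
    ang <- sort(runif(n, -half, half))
    if (n == 1L || min(diff(ang)) > widthAngle * 0.9) return(ang)
  }
  # fall back to evenly spaced rays with jitter when the sector is crowded
  base <- seq(-half, half, length.out = n + 2L)[2:(n + 1L)]
  base + runif(n, -0.1, 0.1) * geom$angleRad / n
}

# Render the noiseless artifact content for one frame in polar
# coordinates: bright pleural arc, A-line reverberations at integer
# multiples of the pleural depth (A frames), or vertical rays running
# from the pleural arc to the far field (B frames).
.renderContent <- function(cfg, geom, frameLabel, rayAngles, widthAngle,
                           opacity) {
  img <- matrix(0.10, cfg@imageHeight, cfg@imageWidth)
  gauss <- function(x, sigma) exp(-x^2 / (2 * sigma^2))
  img <- img + 0.85 * gauss(geom$rho - geom$rhoP, 1.6)  # pleural line
  if (frameLabel == "A") {
    depthP <- geom$rhoP - geom$rmin
    for (k in seq_len(cfg@nALines)) {
      rhoK <- geom$rmin + (k + 1) * depthP
      img <- img + 0.50 * 0.72^(k - 1) * gauss(geom$rho - rhoK, 1.8)
    }
  } else {
    sigA <- widthAngle / 2.355    # FWHM -> sd
    below <- geom$rho >= geom$rhoP - 1
    for (ang in rayAngles) {
      ray <- 0.80 * opacity * gauss(geom$theta - ang, sigA)
      img <- img + ray * below
    }
  }
  img
}

#' Generate one synthetic sector-scan frame
#'
#' A-labelled frames contain a bright pleural band and `nALines`
#' horizontal reverberations at integer multiples of the pleural depth;
#' B-labelled frames contain the pleural band plus `bLineCount` bright
#' vertical rays running from the pleural line to the far field.
#' Multiplicative speckle and a global brightness jitter are applied,
#' and everything outside the scan sector is exactly 0. Uses the
#' current R random number stream; fix it with `set.seed()` for
#' reproducible frames.
#'
#' @param cfg a [PhantomConfig-class].
#' @param frameLabel `"A"` or `"B"`.
#' @param opacity ray opacity in \[0, 1\] (used to model B lines coming
#'   in and out of view across a clip); ignored for A frames.
#' @param rayAngles optional fixed ray centre angles (radians from the
#'   vertical); drawn at random when `NULL`.
#' @param rayWidth optional ray width in pixels, default `cfg@bLineWidth`.
#' @return A [LUSFrame-class].
#' @examples
#' set.seed(1)
#' fr <- generateFrame(phantomConfig(), "B")
#' range(fr@pixels)
#' @export
generateFrame <- function(cfg, frameLabel = c("A", "B"), opacity = 1,
                          rayAngles = NULL, rayWidth = NULL) {
  stopifnot(is(cfg, "PhantomConfig"))
  validObject(cfg)
  if (length(frameLabel) != 1L || !frameLabel %in% c("A", "B"))
    stop("frameLabel must be one of 'A', 'B'")
  geom <- .sectorGeometry(cfg)
  width <- if (is.null(rayWidth)) cfg@bLineWidth else rayWidth
  widthAngle <- width / geom$rhoP
  if (frameLabel == "B") {
    if (is.null(rayAngles))
      rayAngles <- .drawRayAngles(cfg@bLineCount, geom, widthAngle)
  } else {
    rayAngles <- numeric()
  }
  img <- .renderContent(cfg, geom, frameLabel, rayAngles, widthAngle,
                        opacity)
  n <- length(img)
  speckle <- exp(cfg@speckleSigma * rnorm(n) - cfg@speckleSigma^2 / 2)
  img <- img * speckle * runif(1, 1 - cfg@brightnessJitter,
                               1 + cfg@brightnessJitter)
  img <- pmin(pmax(img, 0), 1)
  img[!geom$mask] <- 0
  new("LUSFrame", pixels = img, frameLabel = frameLabel,
      rayAngles = rayAngles, rayWidthAngle = widthAngle,
      sector = .sectorInfo(geom))
}

#' Pixel mask of the B-line rays of a synthetic frame or clip
#'
#' Reconstructs, from the stored ray geometry, the logical matrix of
#' pixels lying on a B-line ray (below the pleural line, inside the
#' sector). Used to check that Grad-CAM importance concentrates on the
#' rays.
#'
#' @param object a [LUSFrame-class] or [LUSClip-class] with ray geometry.
#' @return A logical matrix of the frame dimensions.
#' @export
rayPixelMask <- function(object) {
  s <- object@sector
  if (is(object, "LUSFrame")) d <- dim(object@pixels)
  else d <- dim(object@frames)[1:2]
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  rho <- sqrt((rows - s$apexRow)^2 + (cols - s$apexCol)^2)
  theta <- atan2(cols - s$apexCol, rows - s$apexRow)
  inSector <- abs(theta) <= s$angleRad / 2 & rho >= s$rmin & rho <= s$rmax
  below <- rho >= s$rhoP - 1
  onRay <- matrix(FALSE, d[1], d[2])
  for (ang in object@rayAngles)
    onRay <- onRay | abs(theta - ang) <= object@rayWidthAngle / 2
  onRay & below & inSector
}

# sinusoidal "tidal respiration" phase in [0, 1]; B rays are visible
# (frame labelled B) while the phase is at or above .B_VIS, so B frames
# form contiguous runs occupying a minority of the clip (heterogeneous
# clips mostly show A frames, with B lines coming briefly into view)
.B_VIS <- 0.7

.respirationPhase <- function(nFrames) {
  cycles <- runif(1, 1.2, 2.8)
  phi0 <- runif(1, 0, 2 * pi)
  0.5 + 0.5 * sin(2 * pi * cycles * seq_len(nFrames) / nFrames + phi0)
}

#' Generate a synthetic lung ultrasound clip
#'
#' Builds an ordered stack of frames realizing per-frame labels. For
#' heterogeneous B clips the frame labels, when not given, follow a
#' smooth sinusoidal respiration phase: B rays fade in and out and the
#' frame is labelled B while the phase is at or above 0.5, giving
#' contiguous B-frame runs like tidal respiration. Ray geometry is
#' drawn once per clip and shared by all B frames.
#'
#' @param cfg a [PhantomConfig-class].
#' @param clipId,patientId identifiers.
#' @param clipLabel `"A"` or `"B"`.
#' @param severity `"none"` (A clips) or `"mild"`, `"moderate"`,
#'   `"severe"` (B clips). When given for a B clip, the ray count and
#'   width are drawn to realize that grade; `NULL` keeps `cfg` as is and
#'   derives the grade from its geometry.
#' @param homogeneity `"homogeneous"` or `"heterogeneous"` (B only).
#' @param nFrames number of frames (ignored when `frameLabels` given).
#' @param frameLabels optional explicit per-frame `"A"`/`"B"` sequence;
#'   must be consistent with `clipLabel` and `homogeneity`.
#' @param seed optional seed for reproducible generation.
#' @return A [LUSClip-class]; its manifest row is available through
#'   [manifestRow()].
#' @examples
#' clip <- generateClip(phantomConfig(), "c1", "p1", "B",
#'                      severity = "moderate",
#'                      homogeneity = "heterogeneous", nFrames = 30,
#'                      seed = 7)
#' table(frameLabels(clip))
#' @export
generateClip <- function(cfg, clipId, patientId, clipLabel = c("A", "B"),
                         severity = NULL,
                         homogeneity = c("homogeneous", "heterogeneous"),
                         nFrames = 60L, frameLabels = NULL, seed = NULL) {
  clipLabel <- match.arg(clipLabel)
  homogeneity <- match.arg(homogeneity)
  if (clipLabel == "A" && homogeneity == "heterogeneous")
    stop("heterogeneity only applies to B clips: an A clip has no B ",
         "frames to come in and out of view")
  if (is.null(severity)) severity <- if (clipLabel == "A") "none" else NULL
  if (!is.null(severity) && (severity == "none") != (clipLabel == "A"))
    stop("severity must be 'none' iff the clip label is 'A'")
  .withSeed(seed, {
    geom <- .sectorGeometry(cfg)
    if (is.null(frameLabels)) {
      if (homogeneity == "homogeneous") {
        frameLabels <- rep(clipLabel, nFrames)
        phase <- rep(1, nFrames)
      } else {
        for (i in 1:100) {
          phase <- .respirationPhase(nFrames)
          frameLabels <- ifelse(phase >= .B_VIS, "B", "A")
          runs <- rle(frameLabels)
          okRun <- any(runs$lengths[runs$values == "B"] >= 3L)
          if (okRun && any(frameLabels == "A")) break
        }
      }
    } else {
      nFrames <- length(frameLabels)
      if (!all(frameLabels %in% c("A", "B")))
        stop("frameLabels must be 'A' or 'B'")
      if ((clipLabel == "B") != any(frameLabels == "B"))
        stop("clipLabel contradicts frameLabels")
      homo <- length(unique(frameLabels)) == 1L
      if ((homogeneity == "homogeneous") != homo)
        stop("homogeneity flag contradicts frameLabels")
      # smooth half-wave opacity over each contiguous B run
      phase <- rep(1, nFrames)
      r <- rle(frameLabels == "B")
      pos <- 1L
      for (j in seq_along(r$lengths)) {
        len <- r$lengths[j]
        if (r$values[j] && homogeneity == "heterogeneous")
          phase[pos:(pos + len - 1L)] <-
            .B_VIS + (1 - .B_VIS) * sin(pi * (seq_len(len) - 0.5) / len)
        pos <- pos + len
      }
    }
    if (clipLabel == "B") {
      if (!is.null(severity)) {
        sp <- .severityParams(severity, cfg, geom)
      } else {
        sp <- list(count = cfg@bLineCount, width = cfg@bLineWidth)
        if (sp$count == 0L)
          stop("a B clip needs bLineCount >= 1")
        severity <- .classifySeverity(sp$count, .rayCoverage(cfg, geom))
      }
      widthAngle <- sp$width / geom$rhoP
      rayAngles <- .drawRayAngles(sp$count, geom, widthAngle)
    } else {
      rayAngles <- numeric(); widthAngle <- cfg@bLineWidth / geom$rhoP
      sp <- list(count = 0L, width = cfg@bLineWidth)
    }
    arr <- array(0, c(cfg@imageHeight, cfg@imageWidth, nFrames))
    for (i in seq_len(nFrames)) {
      # visible opacity rescaled from the supra-threshold phase
      op <- if (frameLabels[i] == "B")
        0.65 + 0.35 * pmin(1, (phase[i] - .B_VIS) / (1 - .B_VIS)) else 0
      fr <- generateFrame(cfg, frameLabels[i], opacity = op,
                          rayAngles = rayAngles, rayWidth = sp$width)
      arr[, , i] <- fr@pixels
    }
    new("LUSClip", frames = arr, frameLabels = frameLabels,
        clipId = as.character(clipId), patientId = as.character(patientId),
        clipLabel = clipLabel, severity = severity,
        homogeneity = homogeneity, rayAngles = rayAngles,
        rayWidthAngle = widthAngle, sector = .sectorInfo(geom))
  })
}

#' Manifest row for a clip
#'
#' @param clip a [LUSClip-class].
#' @param path optional storage path recorded in the row.
#' @param batch labelling-batch marker (1 = labelled before the
#'   frame-training cutoff, 2 = after); see [routePools()].
#' @return A one-row data.frame with columns `patient_id`, `clip_id`,
#'   `path`, `clip_label`, `severity`, `homogeneity`, `n_frames`, `batch`.
#' @export
manifestRow <- function(clip, path = NA_character_, batch = 1L) {
  data.frame(patient_id = clip@patientId, clip_id = clip@clipId,
             path = path, clip_label = clip@clipLabel,
             severity = clip@severity, homogeneity = clip@homogeneity,
             n_frames = nFrames(clip), batch = as.integer(batch),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic patient cohort
#'
#' Emulates the structure of a clinical archive: each patient
#' contributes several clips of one class; a fixed fraction of B clips
#' is heterogeneous; homogeneous clips carry a labelling-batch marker
#' splitting them between the frame-training pool and the clip-inference
#' pool (see [routePools()]). Class and heterogeneity fractions are
#' realized as exact rounded counts.
#'
#' @param nPatients number of patients.
#' @param clipsPerPatient integer range `c(min, max)` of clips per patient.
#' @param bPatientFraction fraction of patients whose clips are B clips.
#' @param heterogeneousFraction fraction of B clips that are heterogeneous.
#' @param severityMix named probabilities for `mild`, `moderate`,
#'   `severe` B clips.
#' @param frameTrainFraction fraction of homogeneous clips labelled
#'   before the cutoff (batch 1, eligible for frame training).
#' @param nFramesRange integer range of frames per clip.
#' @param cfg a [PhantomConfig-class].
#' @param seed seed for reproducible cohorts.
#' @param outDir if given, clips are written as PNG frame directories
#'   under `outDir` (see [writeClip()]) together with `manifest.csv`,
#'   and the `path` column is filled in.
#' @return A list with `manifest` (data.frame) and `clips` (named list
#'   of [LUSClip-class], by clip id).
#' @examples
#' coh <- generateCohort(nPatients = 4, seed = 1,
#'                       nFramesRange = c(8L, 10L))
#' coh$manifest[, c("patient_id", "clip_id", "clip_label", "homogeneity")]
#' @export
generateCohort <- function(nPatients = 40L, clipsPerPatient = c(2L, 4L),
                           bPatientFraction = 0.38,
                           heterogeneousFraction = 0.44,
                           severityMix = c(mild = 1, moderate = 1,
                                           severe = 1) / 3,
                           frameTrainFraction = 0.6,
                           nFramesRange = c(30L, 60L),
                           cfg = phantomConfig(), seed = NULL,
                           outDir = NULL) {
  stopifnot(nPatients >= 2L,
            bPatientFraction >= 0, bPatientFraction <= 1,
            heterogeneousFraction >= 0, heterogeneousFraction <= 1,
            frameTrainFraction >= 0, frameTrainFraction <= 1)
  .withSeed(seed, {
    nB <- round(bPatientFraction * nPatients)
    classes <- sample(rep(c("B", "A"), c(nB, nPatients - nB)))
    patientIds <- sprintf("P%03d", seq_len(nPatients))
    rows <- list(); clips <- list()
    for (p in seq_len(nPatients)) {
      nChoices <- seq(clipsPerPatient[1], clipsPerPatient[2])
      nClips <- nChoices[sample.int(length(nChoices), 1)]
      for (ci in seq_len(nClips)) {
        cid <- sprintf("%s_C%02d", patientIds[p], ci)
        lab <- classes[p]
        rows[[cid]] <- data.frame(patient_id = patientIds[p],
                                  clip_id = cid, clip_label = lab,
                                  stringsAsFactors = FALSE)
      }
    }
    man <- do.call(rbind, rows)
    # exact heterogeneity count among B clips
    bIdx <- which(man$clip_label == "B")
    nHet <- round(heterogeneousFraction * length(bIdx))
    het <- rep(FALSE, nrow(man))
    if (nHet > 0) het[sample(bIdx, nHet)] <- TRUE
    man$homogeneity <- ifelse(het, "heterogeneous", "homogeneous")
    man$severity <- ifelse(man$clip_label == "A", "none",
                           sample(names(severityMix), nrow(man),
                                  replace = TRUE, prob = severityMix))
    man$n_frames <- as.integer(round(runif(nrow(man), nFramesRange[1],
                                           nFramesRange[2])))
    # labelling-batch marker: only homogeneous clips can predate the cutoff
    homoIdx <- which(!het)
    nEarly <- round(frameTrainFraction * length(homoIdx))
    man$batch <- 2L
    if (nEarly > 0) man$batch[sample(homoIdx, nEarly)] <- 1L
    for (i in seq_len(nrow(man))) {
      clips[[man$clip_id[i]]] <-
        generateClip(cfg, man$clip_id[i], man$patient_id[i],
                     man$clip_label[i],
                     severity = man$severity[i],
                     homogeneity = man$homogeneity[i],
                     nFrames = man$n_frames[i])
    }
    man$path <- NA_character_
    man <- man[, c("patient_id", "clip_id", "path", "clip_label",
                   "severity", "homogeneity", "n_frames", "batch")]
    rownames(man) <- NULL
    if (!is.null(outDir)) {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      for (cid in names(clips)) {
        d <- file.path(outDir, cid)
        writeClip(clips[[cid]], d)
        man$path[man$clip_id == cid] <- d
      }
      write.csv(man, file.path(outDir, "manifest.csv"), row.names = FALSE)
    }
    list(manifest = man, clips = clips)
  })
}
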