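cfgSmall <- phantomConfig(imageHeight = 64L, imageWidth = 64L,
                          bLineWidth = 3)

test_that("generated frames are masked, bounded and deterministic", {
  set.seed(11)
  fr <- generateFrame(cfgSmall, "A")
  expect_true(all(fr@pixels >= 0 & fr@pixels <= 1))

  # recompute the sector from the stored geometry: outside it, exactly 0
  s <- fr@sector
  H <- nrow(fr@pixels); W <- ncol(fr@pixels)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  rho <- sqrt((rows - s$apexRow)^2 + (cols - s$apexCol)^2)
  theta <- atan2(cols - s$apexCol, rows - s$apexRow)
  outside <- !(abs(theta) <= s$angleRad / 2 & rho >= s$rmin &
               rho <= s$rmax)
  expect_true(all(fr@pixels[outside] == 0))
  expect_gt(mean(fr@pixels > 0), 0.4)       # the fan fills the frame

  set.seed(99); f1 <- generateFrame(cfgSmall, "B")
  set.seed(99); f2 <- generateFrame(cfgSmall, "B")
  expect_identical(f1@pixels, f2@pixels)

  expect_error(generateFrame(cfgSmall, "C"), "frameLabel")
})

test_that("A and B frames are separable by the ray-energy oracle", {
  set.seed(42)
  n <- 1000
  correct <- 0
  for (i in seq_len(n)) {
    lab <- sample(c("A", "B"), 1)
    fr <- generateFrame(cfgSmall, lab)
    correct <- correct + (oracleFrameLabel(fr) == lab)
  }
  expect_gte(correct / n, 0.99)
})

test_that("A frames have no vertical ray below the pleura", {
  set.seed(7)
  for (i in 1:25) {
    fr <- generateFrame(cfgSmall, "A")
    expect_identical(oracleFrameLabel(fr), "A")
    expect_length(fr@rayAngles, 0)
  }
})

test_that("severity recomputed from generated geometry matches request", {
  set.seed(3)
  for (i in 1:100) {
    sev <- sample(c("mild", "moderate", "severe"), 1)
    clip <- generateClip(cfgSmall, "c", "p", "B", severity = sev,
                         nFrames = 2L)
    count <- length(clip@rayAngles)
    extent <- clip@sector$rhoP * clip@sector$angleRad
    coverage <- count * clip@rayWidthAngle * clip@sector$rhoP / extent
    expect_identical(oracleSeverity(count, coverage), sev)
  }
})

test_that("wide-coverage ray configurations grade as severe", {
  # 4 rays covering > 50% of the pleural arc
  geomExtent <- function(cfg) {
    s <- generateFrame(cfg, "A")@sector
    s$rhoP * s$angleRad
  }
  cfg <- phantomConfig(imageHeight = 64L, imageWidth = 64L,
                       bLineCount = 4L,
                       bLineWidth = ceiling(0.55 * geomExtent(
                         phantomConfig(imageHeight = 64L,
                                       imageWidth = 64L)) / 4))
  set.seed(5)
  clip <- generateClip(cfg, "c", "p", "B", nFrames = 1L)
  expect_identical(severity(clip), "severe")
})

test_that("clip construction respects labels, homogeneity and geometry", {
  clip <- generateClip(cfgSmall, "c1", "p1", "B", severity = "mild",
                       homogeneity = "homogeneous", nFrames = 30L,
                       seed = 2)
  expect_identical(frameLabels(clip), rep("B", 30))
  expect_identical(clipLabel(clip), "B")

  labs <- c(rep("A", 10), rep("B", 10), rep("A", 10))
  het <- generateClip(cfgSmall, "c2", "p1", "B", severity = "moderate",
                      homogeneity = "heterogeneous", frameLabels = labs,
                      seed = 3)
  expect_identical(clipLabel(het), "B")
  expect_identical(sum(frameLabels(het) == "B"), 10L)

  # sector mask (zero set) identical across all frames of a clip
  zeroSets <- apply(het@frames == 0, 3, identity, simplify = FALSE)
  for (z in zeroSets[-1]) expect_identical(z, zeroSets[[1]])

  # generated heterogeneous clips: contiguous B runs, mostly A frames
  set.seed(8)
  fracs <- replicate(20, {
    cl <- generateClip(cfgSmall, "x", "p", "B", severity = "mild",
                       homogeneity = "heterogeneous", nFrames = 60L)
    r <- rle(frameLabels(cl) == "B")
    expect_gte(max(r$lengths[r$values]), 3)
    mean(frameLabels(cl) == "B")
  })
  expect_lt(mean(fracs), 0.5)

  expect_error(generateClip(cfgSmall, "c", "p", "A",
                            homogeneity = "heterogeneous"),
               "heterogeneity")
  expect_error(generateClip(cfgSmall, "c", "p", "B", severity = "mild",
                            homogeneity = "homogeneous",
                            frameLabels = labs),
               "homogeneity")
  expect_error(generateClip(cfgSmall, "c", "p", "A", severity = "mild"),
               "severity")
})

test_that("cohorts are reproducible with consistent manifests", {
  tiny <- phantomConfig(imageHeight = 32L, imageWidth = 32L)
  coh <- generateCohort(nPatients = 10L, cfg = tiny, seed = 5,
                        nFramesRange = c(4L, 6L))
  man <- coh$manifest
  # each clip maps to exactly one patient and one stored clip object
  expect_identical(anyDuplicated(man$clip_id), 0L)
  expect_setequal(names(coh$clips), man$clip_id)
  byClip <- tapply(man$patient_id, man$clip_id, function(x)
    length(unique(x)))
  expect_true(all(byClip == 1))
  # labels in the manifest agree with the generated objects
  for (cid in man$clip_id) {
    expect_identical(clipLabel(coh$clips[[cid]]),
                     man$clip_label[man$clip_id == cid])
    expect_identical(homogeneity(coh$clips[[cid]]),
                     man$homogeneity[man$clip_id == cid])
  }
  # heterogeneous clips only ever carry the B label
  expect_true(all(man$clip_label[man$homogeneity == "heterogeneous"]
                  == "B"))

  allA <- generateCohort(nPatients = 6L, bPatientFraction = 0,
                         cfg = tiny, seed = 1, nFramesRange = c(3L, 4L))
  expect_true(all(allA$manifest$clip_label == "A"))

  homoOnly <- generateCohort(nPatients = 6L, heterogeneousFraction = 0,
                             cfg = tiny, seed = 1,
                             nFramesRange = c(3L, 4L))
  expect_true(all(homoOnly$manifest$homogeneity == "homogeneous"))

  again <- generateCohort(nPatients = 10L, cfg = tiny, seed = 5,
                          nFramesRange = c(4L, 6L))
  expect_identical(man, again$manifest)
  expect_identical(coh$clips[[man$clip_id[1]]]@frames,
                   again$clips[[man$clip_id[1]]]@frames)
})

test_that("clips survive a PNG round trip", {
  clip <- generateClip(phantomConfig(imageHeight = 32L, imageWidth = 32L),
                       "c9", "p9", "B", severity = "mild",
                       nFrames = 3L, seed = 4)
  dir <- withr::local_tempdir()
  writeClip(clip, dir)
  back <- readClip(dir)
  expect_identical(frameLabels(back), frameLabels(clip))
  expect_identical(clipLabel(back), "B")
  # 8-bit PNG quantization
  expect_lt(max(abs(back@frames - clip@frames)), 1 / 255)
  expect_equal(rayPixelMask(back), rayPixelMask(clip))
})
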