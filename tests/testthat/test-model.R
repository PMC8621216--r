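test_that("parameter count matches the closed-form architecture sum", {
  # default plan: (2,2,3) convs of (64,128,256) 3x3 filters + 2-way head
  m <- buildFrameClassifier(c(128L, 128L))
  handCount <- (9 * 1 * 64 + 64) + (9 * 64 * 64 + 64) +
    (9 * 64 * 128 + 128) + (9 * 128 * 128 + 128) +
    (9 * 128 * 256 + 256) + 2 * (9 * 256 * 256 + 256) +
    (256 * 2 + 2)
  expect_identical(nParameters(m), handCount)
  expect_identical(handCount, 1734850)
  expect_equal(lusBline:::.cnn_num_params(lusBline:::.liveNet(m)),
               handCount)

  tiny <- tinyClassifier()
  expect_equal(lusBline:::.cnn_num_params(lusBline:::.liveNet(tiny)),
               nParameters(tiny))
})

test_that("the forward pass yields normalized probability pairs", {
  m <- tinyClassifier(seed = 2)
  set.seed(1)
  x <- array(runif(16 * 16 * 5), c(16, 16, 5))
  p <- predictFrames(m, x)
  expect_identical(nrow(p), 5L)
  expect_equal(p$pA + p$pB, rep(1, 5), tolerance = 1e-6)
  expect_true(all(p$pA >= 0 & p$pA <= 1))
  expect_identical(p$predictedClass, ifelse(p$pB > p$pA, "B", "A"))
})

test_that("a zeroed final layer is indifferent between classes", {
  m <- tinyClassifier(seed = 3)
  w <- m@weights
  last <- length(w)
  w[[last]]$W[] <- 0
  w[[last]]$b[] <- 0
  m0 <- buildFrameClassifier(c(16L, 16L), blockFilters = c(4L, 6L, 8L),
                             blockConvs = c(1L, 1L, 1L), dropout = 0,
                             seed = 3, weights = w)
  p <- predictFrames(m0, array(runif(16 * 16 * 3), c(16, 16, 3)))
  expect_equal(p$pA, rep(0.5, 3), tolerance = 1e-6)
})

test_that("input shapes must match the two-pool downsampling factor", {
  expect_error(buildFrameClassifier(c(30L, 30L)), "divisible by 4")
  # block-3 feature maps sit at exactly 1/4 of the input resolution
  m <- tinyClassifier(inputShape = c(32L, 32L))
  A <- lusBline:::.cnn_block_activations(lusBline:::.liveNet(m),
                                         matrix(runif(32 * 32), 32, 32))
  expect_identical(dim(A)[1:2], c(8L, 8L))
})

test_that("initialization and training are deterministic under a seed", {
  m1 <- tinyClassifier(seed = 9)
  m2 <- tinyClassifier(seed = 9)
  expect_identical(m1@weights, m2@weights)

  set.seed(4)
  x <- array(runif(16 * 16 * 12), c(16, 16, 12))
  y <- rep(c("A", "B"), 6)
  cfg <- trainConfig(epochs = 2, batchSize = 4, learningRate = 1e-3,
                     seed = 5)
  t1 <- trainFrameClassifier(tinyClassifier(seed = 9), x, y,
                             config = cfg, augment = NULL)
  t2 <- trainFrameClassifier(tinyClassifier(seed = 9), x, y,
                             config = cfg, augment = NULL)
  expect_equal(t1@history$trainLoss, t2@history$trainLoss,
               tolerance = 1e-7)
  expect_identical(t1@weights, t2@weights)
})

test_that("zero epochs leaves the initialization untouched", {
  m <- tinyClassifier(seed = 12)
  before <- m@weights
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  out <- trainFrameClassifier(m, x, c("A", "B", "A", "B"),
                              config = trainConfig(epochs = 0),
                              augment = NULL)
  expect_identical(out@weights, before)
  expect_false(out@trained)
})

test_that("training reduces the loss on a separable toy problem", {
  set.seed(30)
  n <- 24
  x <- array(0, c(16, 16, n)); y <- character(n)
  for (i in seq_len(n)) {
    y[i] <- c("A", "B")[1 + i %% 2]
    base <- if (y[i] == "B") 0.75 else 0.25
    x[, , i] <- matrix(pmin(1, pmax(0, rnorm(256, base, 0.1))), 16, 16)
  }
  m <- trainFrameClassifier(tinyClassifier(seed = 1), x, y,
                            config = trainConfig(epochs = 25,
                                                 batchSize = 8,
                                                 learningRate = 3e-3,
                                                 seed = 2),
                            augment = NULL)
  h <- m@history$trainLoss
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
  p <- predictFrames(m, x)
  expect_gt(mean(p$predictedClass == y), 0.9)
})

test_that("frame predictions are stateless and order-preserving", {
  m <- tinyClassifier(seed = 21)
  set.seed(2)
  x <- array(runif(16 * 16 * 6), c(16, 16, 6))
  x[, , 4] <- x[, , 2]                      # duplicated frame
  p <- predictFrames(m, x)
  expect_equal(p$pB[4], p$pB[2], tolerance = 1e-7)

  perm <- c(3, 1, 6, 2, 5, 4)
  pPerm <- predictFrames(m, x[, , perm])
  expect_equal(pPerm$pB, p$pB[perm], tolerance = 1e-7)

  expect_error(predictFrames(m, array(0, c(16, 16, 0))), "empty")
})

test_that("training requires both classes", {
  m <- tinyClassifier()
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  expect_error(trainFrameClassifier(m, x, rep("A", 4), augment = NULL),
               "both classes")
})

test_that("models predict identically after serialization", {
  m <- tinyClassifier(seed = 31)
  set.seed(3)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  p0 <- predictFrames(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, path)
  back <- readRDS(path)                     # stale backend pointer
  p1 <- predictFrames(back, x)
  expect_equal(p1$pB, p0$pB, tolerance = 1e-7)
})
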