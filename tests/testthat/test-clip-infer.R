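test_that("the contiguity rule matches its defining examples", {
  d <- classifyClip(c(0.9, 0.8, 0.95), t = 0.7, tau = 3)
  expect_identical(d@yHat, 1L)
  expect_identical(d@window, c(1L, 3L))

  d <- classifyClip(c(0.9, 0.6, 0.9, 0.9), t = 0.7, tau = 2)
  expect_identical(d@yHat, 1L)
  expect_identical(d@window, c(3L, 4L))

  d <- classifyClip(c(0.9, 0.6, 0.9), t = 0.7, tau = 2)
  expect_identical(d@yHat, 0L)
  expect_length(d@window, 0)

  # n < tau: the window index range is empty, decision is A
  for (t in c(0.5, 0.7, 0.9))
    expect_identical(classifyClip(c(0.9, 0.9), t = t, tau = 3)@yHat, 0L)

  # inclusive comparison: pB == t counts as a B frame
  expect_identical(classifyClip(c(0.7, 0.7), t = 0.7, tau = 2)@yHat, 1L)

  expect_error(classifyClip(numeric(), t = 0.7, tau = 3), "empty")
  expect_error(classifyClip(c(0.2, 1.4), t = 0.7, tau = 3), "\\[0, 1\\]")
})

test_that("decisions equal a brute-force all-windows scan on random input", {
  set.seed(101)
  tGrid <- seq(0.5, 0.9, by = 0.1)
  for (i in 1:60) {
    n <- sample(1:60, 1)
    pB <- switch(sample(3, 1),
                 runif(n),
                 round(runif(n), 1),                 # many boundary ties
                 pmin(1, pmax(0, rbinom(n, 1, 0.4) * runif(n, 0.5, 1) +
                                runif(n, 0, 0.3))))
    for (t in tGrid) {
      for (tau in c(1:5, 10, 20, 40)) {
        expect_identical(classifyClip(pB, t = t, tau = tau)@yHat,
                         bruteForceClipDecision(pB, t, tau),
                         info = sprintf("n=%d t=%.1f tau=%d", n, t, tau))
      }
    }
  }
})

test_that("per-clip decisions are monotone in t and tau", {
  set.seed(55)
  for (i in 1:200) {
    pB <- runif(sample(1:60, 1))
    t <- sample(seq(0.5, 0.9, 0.1), 1)
    tau <- sample(1:10, 1)
    y <- classifyClip(pB, t = t, tau = tau)@yHat
    if (y == 1L) {
      tLo <- max(0.5, t - 0.1)
      tauLo <- max(1L, tau - sample(0:3, 1))
      expect_identical(classifyClip(pB, t = tLo, tau = tauLo)@yHat, 1L)
    }
  }
})

test_that("tau = 1 reduces to thresholding the maximum probability", {
  set.seed(77)
  for (i in 1:100) {
    pB <- runif(sample(1:40, 1))
    t <- runif(1, 0.5, 0.95)
    expect_identical(classifyClip(pB, t = t, tau = 1)@yHat,
                     as.integer(max(pB) >= t))
  }
})

test_that("probabilities outside the triggering window cannot matter", {
  set.seed(33)
  for (i in 1:50) {
    pB <- runif(40)
    d <- classifyClip(pB, t = 0.6, tau = 3)
    if (d@yHat == 1L) {
      lowered <- pB * 0.1
      lowered[d@window[1]:d@window[2]] <- pB[d@window[1]:d@window[2]]
      expect_identical(classifyClip(lowered, t = 0.6, tau = 3)@yHat, 1L)
    }
  }
})

test_that("clip averaging shows the heterogeneous false-negative mode", {
  expect_identical(classifyClipAveraging(rep(1, 10))@yHat, 1L)
  expect_identical(classifyClipAveraging(rep(0.5, 7), 0.5)@yHat, 1L)

  # short burst of B frames in a long A background
  pB <- c(rep(0.9, 10), rep(0.1, 40))
  expect_equal(mean(pB), 0.26)
  expect_identical(classifyClipAveraging(pB, 0.5)@yHat, 0L)
  expect_identical(classifyClip(pB, t = 0.7, tau = 3)@yHat, 1L)

  expect_error(classifyClipAveraging(numeric()), "empty")
})

test_that("the threshold sweep reproduces hand-enumerated surfaces", {
  probs <- list(rep(0.6, 20),                       # A clip
                c(rep(0.1, 5), rep(0.95, 5), rep(0.1, 10)),  # B, run of 5
                rep(c(0.95, 0.1), 10))              # B, isolated spikes
  labels <- c("A", "B", "B")
  sw <- thresholdSweep(probs, labels, tValues = c(0.7, 0.9),
                       tauValues = 1:5)
  g <- sweepGrid(sw)
  expect_identical(nrow(g), 10L)                    # complete grid
  at <- function(t, tau) g[g$t == t & g$tau == tau, ]
  expect_equal(at(0.9, 1)$sensitivity, 1.0)
  expect_equal(at(0.9, 3)$sensitivity, 0.5)         # spike clip lost
  expect_true(all(g$specificity[g$t == 0.9] == 1.0))
  # at t = 0.7 the constant-0.6 A clip is still below threshold
  expect_true(all(g$specificity[g$t == 0.7] == 1.0))

  expect_error(thresholdSweep(probs[1], labels[1], tauValues = 1:2),
               "both A and B")
})

test_that("sweep surfaces are monotone along tau and t", {
  set.seed(12)
  probs <- lapply(1:40, function(i) runif(50))
  labels <- rep(c("A", "B"), 20)
  sw <- thresholdSweep(probs, labels, tauValues = 1:25)
  g <- sweepGrid(sw)
  for (t in sw@tValues) {
    sub <- g[g$t == t, ]
    sub <- sub[order(sub$tau), ]
    expect_true(all(diff(sub$sensitivity) <= 1e-12))
    expect_true(all(diff(sub$specificity) >= -1e-12))
  }
  for (tau in sw@tauValues) {
    sub <- g[g$tau == tau, ]
    sub <- sub[order(sub$t), ]
    expect_true(all(diff(sub$specificity) >= -1e-12))
  }
})

test_that("operating point selection maximizes and breaks ties low", {
  probs <- list(rep(0.95, 12), c(rep(0.95, 4), rep(0.1, 8)),
                rep(0.1, 12), c(rep(0.95, 1), rep(0.1, 11)))
  labels <- c("B", "B", "A", "A")
  sw <- thresholdSweep(probs, labels, tValues = c(0.5, 0.7),
                       tauValues = 1:6)
  op <- selectOperatingPoint(sw)
  # tau must exceed the A clip's single-frame spike but stay within the
  # shorter B run
  expect_gt(op@tau, 1L)
  expect_lte(op@tau, 4L)
  expect_equal(attr(op, "sensitivity"), 1.0)
  expect_equal(attr(op, "specificity"), 1.0)

  # all grid points equal: smallest tau then smallest t wins
  flat <- thresholdSweep(list(rep(0.99, 10), rep(0, 10)), c("B", "A"),
                         tValues = c(0.5, 0.7), tauValues = 1:4)
  opFlat <- selectOperatingPoint(flat)
  expect_identical(opFlat@tau, 1L)
  expect_identical(opFlat@t, 0.5)
})

test_that("spiky A clips push the selected contiguity threshold above 1", {
  set.seed(90)
  probs <- list(); labels <- character()
  for (i in 1:25) {                 # B clips: solid runs of high pB
    p <- runif(60, 0, 0.3)
    s <- sample(1:40, 1)
    p[s:(s + 12)] <- runif(13, 0.9, 1)
    probs[[length(probs) + 1]] <- p; labels <- c(labels, "B")
  }
  for (i in 1:25) {                 # A clips: isolated 5% spike frames
    p <- runif(60, 0, 0.3)
    spikes <- sample(seq(1, 60, by = 7), 3)
    p[spikes] <- 0.95
    probs[[length(probs) + 1]] <- p; labels <- c(labels, "A")
  }
  sw <- thresholdSweep(probs, labels, tauValues = 1:10)
  op <- selectOperatingPoint(sw)
  expect_gt(op@tau, 1L)
})

test_that("prediction tables classify clip by clip", {
  pred <- data.frame(clipId = rep(c("a", "b"), each = 4),
                     frameIndex = rep(4:1, 2),       # unordered input
                     pB = c(0.1, 0.9, 0.9, 0.2, 0.2, 0.1, 0.3, 0.2))
  out <- classifyClips(pred, thresholdSetting(0.7, 2L))
  expect_identical(out$yHat[out$clipId == "a"], 1L)
  expect_identical(out$yHat[out$clipId == "b"], 0L)
  expect_identical(out$windowStart[out$clipId == "a"], 2L)
})
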