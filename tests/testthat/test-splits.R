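test_that("folds partition patients with grouped, disjoint sets", {
  man <- fakeManifest(20L, bFraction = 0.5, seed = 3)  # 10 per class
  plan <- makeFolds(man, k = 10, seed = 1)
  pts <- unique(man$patient_id)

  testSets <- lapply(seq_len(plan@k), function(f) foldSets(plan, f)$test)
  expect_identical(sort(unlist(testSets)), sort(pts))   # union = all
  expect_identical(anyDuplicated(unlist(testSets)), 0L) # pairwise disjoint
  for (s in testSets) expect_length(s, 2L)              # 20 / 10

  for (f in seq_len(plan@k)) {
    sets <- foldSets(plan, f)
    expect_identical(anyDuplicated(c(sets$train, sets$validation,
                                     sets$test)), 0L)
    # every clip of a patient lands in exactly one set
    for (set in sets) {
      ids <- man$clip_id[man$patient_id %in% set]
      others <- setdiff(unlist(sets), set)
      expect_length(intersect(ids,
                              man$clip_id[man$patient_id %in% others]), 0)
    }
    # both classes present in every set
    for (set in sets) {
      labs <- unique(man$clip_label[man$patient_id %in% set])
      expect_setequal(labs, c("A", "B"))
    }
  }
})

test_that("fold plans are deterministic and serializable", {
  man <- fakeManifest(24L, seed = 2)
  p1 <- makeFolds(man, k = 4, seed = 7)
  p2 <- makeFolds(man, k = 4, seed = 7)
  expect_identical(p1@assignment, p2@assignment)
  expect_identical(p1@folds, p2@folds)

  path <- withr::local_tempfile(fileext = ".json")
  writeFoldPlan(p1, path)
  back <- readFoldPlan(path)
  expect_identical(back@assignment[names(p1@assignment)], p1@assignment)
  for (f in seq_len(p1@k)) {
    expect_setequal(back@folds[[f]]$train, p1@folds[[f]]$train)
    expect_setequal(back@folds[[f]]$test, p1@folds[[f]]$test)
  }
})

test_that("too few patients per class is rejected with a diagnostic", {
  man <- fakeManifest(8L, seed = 1)
  expect_error(makeFolds(man, k = 10), "patients per class")
})

test_that("pool routing separates frame training from clip inference", {
  man <- fakeManifest(30L, seed = 4)
  pools <- routePools(man)
  expect_length(intersect(pools$framePool$clip_id,
                          pools$clipPool$clip_id), 0)
  expect_identical(nrow(pools$framePool) + nrow(pools$clipPool),
                   nrow(man))
  # the frame pool is homogeneous and pre-cutoff only
  expect_true(all(pools$framePool$homogeneity == "homogeneous"))
  expect_true(all(pools$framePool$batch <= 1L))
  # every heterogeneous clip routes to the clip pool
  het <- man$clip_id[man$homogeneity == "heterogeneous"]
  expect_true(all(het %in% pools$clipPool$clip_id))

  # all-homogeneous, all before the cutoff: clip pool empty
  man2 <- man
  man2$homogeneity <- "homogeneous"
  man2$batch <- 1L
  pools2 <- routePools(man2)
  expect_identical(nrow(pools2$clipPool), 0L)

  # 153 heterogeneous of 873 clips: the clip pool holds all 153
  man3 <- data.frame(patient_id = sprintf("P%03d", rep(1:291, each = 3)),
                     clip_id = sprintf("C%04d", 1:873),
                     clip_label = "B", homogeneity = "homogeneous",
                     batch = 1L, stringsAsFactors = FALSE)
  man3$homogeneity[sample.int(873, 153)] <- "heterogeneous"
  man3$batch[man3$homogeneity == "heterogeneous"] <- 2L
  pools3 <- routePools(man3)
  expect_identical(sum(pools3$clipPool$homogeneity == "heterogeneous"),
                   153L)
  expect_length(intersect(pools3$framePool$clip_id,
                          pools3$clipPool$clip_id), 0)
})

test_that("fold summaries report mean and SD per class and set", {
  man <- fakeManifest(20L, seed = 5)
  plan <- makeFolds(man, k = 4, seed = 2)
  s <- foldSummary(plan, man)
  expect_setequal(unique(s$set), c("train", "validation", "test"))
  expect_setequal(unique(s$class), c("A", "B"))
  expect_true(all(is.finite(s$patients_mean)))
  expect_true(all(s$frames_mean >= 0))
  # test-set patient means add up to the cohort total across classes
  tot <- sum(s$patients_mean[s$set == "test"]) * plan@k
  expect_equal(tot, length(unique(man$patient_id)))
})
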