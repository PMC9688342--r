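test_that("learning-rate schedule decays exponentially to the floor", {
  cfg <- optimizerConfig()
  expect_equal(lrSchedule(0, cfg), 0.001)
  expect_equal(lrSchedule(1, cfg), 0.00095)
  expect_equal(lrSchedule(100, cfg), 0.0001) # 0.95^100 clamps to the floor
  lrs <- lrSchedule(0:200, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(lrs >= cfg$lrFloor))
  expect_error(lrSchedule(-1, cfg), "epoch")
  expect_error(optimizerConfig(lr0 = 1e-5, lrFloor = 1e-4), "lrFloor")
})

test_that("cross-validation folds partition the cases evenly", {
  ids <- sprintf("case%02d", 1:60)
  plan <- makeFolds(ids, k = 5, seed = 3)
  sizes <- table(plan$assignments)
  expect_true(all(sizes == 12)) # 60 cases, 5 folds: 12 held out each
  # partition property for arbitrary sizes and seeds
  for (n in c(10, 13, 47)) {
    p <- makeFolds(seq_len(n), k = 5, seed = n)
    test <- lapply(1:5, function(f) foldSplit(p, f)$test)
    expect_setequal(unlist(test), as.character(seq_len(n)))
    expect_equal(sum(lengths(test)), n)
    expect_lte(diff(range(lengths(test))), 1)
    for (f in 1:5)
      expect_length(intersect(foldSplit(p, f)$train, foldSplit(p, f)$test), 0)
  }
  expect_identical(makeFolds(ids, seed = 9)$assignments,
                   makeFolds(ids, seed = 9)$assignments)
  expect_error(makeFolds(1:3, k = 5), "folds")
})

test_that("epoch subsets respect the 20 percent cap and balance classes", {
  pool <- list(`0` = 1:900, `1` = 901:1000)
  sub <- sampleEpochSubset(pool, seed = 1)
  expect_lte(sum(lengths(sub)), 0.2 * 1000)
  expect_equal(unname(lengths(sub)), c(100L, 100L)) # minority oversampled
  expect_true(all(sub$`1` %in% 901:1000))
  # different seeds draw different subsets
  s2 <- sampleEpochSubset(pool, seed = 2)
  expect_lt(length(intersect(sub$`0`, s2$`0`)) / 100, 1)
  # extra cap for desk-scale runs
  s3 <- sampleEpochSubset(pool, maxTotal = 40, seed = 3)
  expect_equal(unname(lengths(s3)), c(20L, 20L))
  expect_error(sampleEpochSubset(list(a = 1:3, b = integer(0))), "empty")
})

test_that("UNet training checkpoints the best validation Dice and is seeded", {
  cases <- lapply(1:3, tinyCase)
  val <- lapply(4:4, tinyCase)
  spec <- tinyUNetSpec(nClasses = 2L)
  roi <- c(50, 200, 280)
  m1 <- trainUNet(spec, cases, val, epochs = 3L, pairsPerEpoch = 24L,
                  batchSize = 4L, valPatches = 4L, roiExtent = roi,
                  seed = 7L)
  log1 <- attr(m1, "log")
  expect_identical(nrow(log1), 3L)
  expect_equal(m1@bestMetric, max(log1$valDice))
  # loss decreases from the first to the last epoch on a learnable phantom
  expect_lt(log1$meanLoss[3], log1$meanLoss[1])
  # identical seed reproduces the loss sequence exactly
  m2 <- trainUNet(spec, cases, val, epochs = 3L, pairsPerEpoch = 24L,
                  batchSize = 4L, valPatches = 4L, roiExtent = roi,
                  seed = 7L)
  expect_identical(attr(m2, "log")$meanLoss, log1$meanLoss)
  expect_identical(m1@params, m2@params)
})

test_that("multi-class UNet training runs with class weights", {
  cases <- lapply(1:2, tinyCase)
  spec <- tinyUNetSpec(nClasses = 6L)
  m <- trainUNet(spec, cases, cases[1], epochs = 1L, pairsPerEpoch = 8L,
                 batchSize = 4L, valPatches = 2L,
                 roiExtent = c(50, 200, 280), seed = 1L)
  expect_s4_class(m, "TrainedModel")
  pr <- predictPatch(m, array(runif(16^3), rep(16L, 3)))
  expect_identical(dim(pr)[4], 6L)
})

test_that("multi-view training improves the loss and is deterministic", {
  cases <- lapply(1:2, tinyCase)
  val <- lapply(3:3, tinyCase)
  spec <- tinyMVSpec(nClasses = 6L)
  m1 <- trainMV(spec, cases, val, epochs = 3L, maxPairsPerEpoch = 96L,
                valVoxelsPerCase = 30L, seed = 5L)
  log1 <- attr(m1, "log")
  expect_identical(nrow(log1), 3L)
  expect_equal(m1@bestMetric, max(log1$valDice))
  expect_lt(log1$meanLoss[3], log1$meanLoss[1])
  m2 <- trainMV(spec, cases, val, epochs = 3L, maxPairsPerEpoch = 96L,
                valVoxelsPerCase = 30L, seed = 5L)
  expect_identical(attr(m2, "log")$meanLoss, log1$meanLoss)
})

test_that("ensembles share the spec and derive member seeds from the base", {
  cases <- lapply(1:2, tinyCase)
  spec <- tinyUNetSpec(nClasses = 2L)
  ens <- trainEnsemble(trainUNet, spec, cases, cases[2], nMembers = 2L,
                       baseSeed = 11L, epochs = 1L, pairsPerEpoch = 8L,
                       batchSize = 4L, valPatches = 2L,
                       roiExtent = c(50, 200, 280))
  expect_length(ensembleMembers(ens), 2L)
  # member 1 reproduces a standalone run with the same seed
  solo <- trainUNet(spec, cases, cases[2], epochs = 1L, pairsPerEpoch = 8L,
                    batchSize = 4L, valPatches = 2L,
                    roiExtent = c(50, 200, 280), seed = 11L)
  expect_identical(ensembleMembers(ens)[[1]]@params, solo@params)
  # members differ from each other
  expect_false(identical(ensembleMembers(ens)[[1]]@params,
                         ensembleMembers(ens)[[2]]@params))
})
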