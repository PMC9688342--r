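test_that("UNet spec validates and builds reproducibly", {
  expect_error(unetSpec(patchSize = 30L, depth = 3L), "divisible")
  s <- tinyUNetSpec(nClasses = 6L)
  m1 <- buildUNet(s, seed = 42)
  m2 <- buildUNet(s, seed = 42)
  expect_identical(m1@params, m2@params)
  m3 <- buildUNet(s, seed = 43)
  expect_false(identical(m1@params, m3@params))
})

test_that("UNet maps a patch to a per-voxel softmax of the right shape", {
  s <- tinyUNetSpec(nClasses = 6L)
  m <- buildUNet(s, seed = 1)
  set.seed(2)
  p <- array(runif(16^3), rep(16L, 3))
  pr <- predictPatch(m, p)
  expect_identical(dim(pr), c(16L, 16L, 16L, 6L))
  sums <- apply(pr, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_gte(min(pr), 0)
  # binary spec gives two output channels
  pr2 <- predictPatch(buildUNet(tinyUNetSpec(nClasses = 2L), seed = 1), p)
  expect_identical(dim(pr2)[4], 2L)
  # inference is deterministic (dropout off, running statistics)
  mDrop <- buildUNet(unetSpec(16L, 2L, 4L, 6L, dropout = 0.5), seed = 1)
  expect_identical(predictPatch(mDrop, p), predictPatch(mDrop, p))
})

test_that("C++ engine agrees with the R reference network", {
  ns <- asNamespace("lnlevelseg")
  s <- unetSpec(patchSize = 16L, depth = 3L, baseFilters = 4L,
                nClasses = 3L, dropout = 0)
  m <- buildUNet(s, seed = 42)
  set.seed(5)
  x <- array(runif(16^3 * 2), c(16, 16, 16, 1, 2))
  eng <- ns$.eng_new(m@params, unclass(s))
  pe <- ns$.eng_fwd(eng, x, TRUE)
  fw <- ns$unetForward(m@params, x, s, training = TRUE)
  expect_lt(max(abs(pe - fw$probs)), 1e-5)
  gp <- array(rnorm(length(pe)), dim(pe))
  ge <- ns$flattenParams(ns$.eng_bwd(eng, gp))
  gr <- ns$flattenParams(ns$unetBackward(fw$params, s, fw$cache, gp))
  # single-precision ties in pooling/ReLU can reroute a few entries, so
  # compare in relative Frobenius norm per parameter array; biases of
  # convolutions feeding a batch norm are skipped (their true gradient is
  # exactly zero, so both sides only hold rounding noise there)
  keys <- setdiff(names(gr), grep("\\.b$", names(gr), value = TRUE))
  keys <- c(keys, "head.b")
  for (k in keys) {
    rel <- sqrt(sum((ge[[k]] - gr[[k]])^2) / (sum(gr[[k]]^2) + 1e-4))
    expect_lt(rel, 0.02)
  }
  # after merging running statistics, inference agrees too
  pm <- ns$mergeBNStats(m@params, ns$.eng_get_bn(eng))
  pi2 <- ns$unetForward(pm, x, s, training = FALSE)$probs
  expect_lt(max(abs(ns$.eng_fwd(eng, x, FALSE) - pi2)), 1e-5)
})

test_that("multi-view field of view spans 4/8/16 cm at 1.25 mm spacing", {
  s <- mvSpec()
  expect_equal(fieldOfView(s, 1.25), c(40, 80, 160))
  expect_error(mvSpec(nScales = 2L, strides = c(1L, 2L, 4L)), "stride")
})

test_that("extractViews samples the three planes at strided offsets", {
  set.seed(4)
  arr <- array(rnorm(24^3), rep(24L, 3))
  v <- scanVolume(arr)
  s <- tinyMVSpec()
  vox <- c(12L, 11L, 13L)
  vs <- extractViews(v, vox, s)
  expect_identical(dim(vs), c(8L, 8L, 3L, 3L))
  # axial scale-0 patch equals a direct crop around the voxel
  crop <- arr[vox[1] + 1 + (-4:3), vox[2] + 1 + (-4:3), vox[3] + 1]
  expect_identical(vs[, , 1, 1], crop)
  # scale-1 samples every other voxel in the sagittal plane
  sag <- arr[vox[1] + 1, vox[2] + 1 + 2 * (-4:3), vox[3] + 1 + 2 * (-4:3)]
  expect_identical(vs[, , 2, 2], sag)
  # constant volume gives constant views; border voxels use edge padding
  cv <- scanVolume(array(3, rep(12L, 3)))
  vs2 <- extractViews(cv, c(0L, 0L, 0L), s)
  expect_true(all(vs2 == 3))
  expect_error(extractViews(v, c(24L, 0L, 0L), s), "outside")
})

test_that("multi-view classifier outputs order-preserving probabilities", {
  s <- tinyMVSpec(nClasses = 6L)
  m <- buildMV(s, seed = 7)
  m2 <- buildMV(s, seed = 7)
  expect_identical(m@params, m2@params)
  set.seed(8)
  arr <- array(rnorm(24^3), rep(24L, 3))
  vox <- cbind(c(5L, 10L, 15L), c(6L, 11L, 16L), c(7L, 12L, 17L))
  vs <- extractViews(arr, vox, s)
  q <- predictViews(m, vs)
  expect_identical(dim(q), c(3L, 6L))
  expect_lt(max(abs(rowSums(q) - 1)), 1e-6)
  # batch is order-preserving: each row equals its single-voxel prediction
  for (i in 1:3) {
    qi <- predictViews(m, extractViews(arr, vox[i, ], s))
    expect_equal(unname(q[i, ]), unname(qi[1, ]), tolerance = 1e-6)
  }
  # 5-class spec (sequential configuration) gives 5 outputs
  q5 <- predictViews(buildMV(tinyMVSpec(nClasses = 5L), seed = 1), vs)
  expect_identical(ncol(q5), 5L)
})

test_that("multi-view training gradients match finite differences", {
  ns <- asNamespace("lnlevelseg")
  s <- mvSpec(nScales = 2L, inPlaneSamples = 4L, strides = c(1L, 2L),
              viewFilters = c(2L), denseUnits = 4L, nClasses = 3L,
              dropout = 0)
  m <- buildMV(s, seed = 3)
  set.seed(9)
  views <- array(rnorm(4 * 4 * 3 * 2 * 2), c(4, 4, 3, 2, 2))
  p <- rbind(c(1, 0, 0), c(0, 0, 1))
  lossAt <- function(params) {
    q <- ns$mvForward(params, views, s, training = TRUE)$probs
    categoricalCrossEntropy(p, q)
  }
  fw <- ns$mvForward(m@params, views, s, training = TRUE)
  glog <- fw$probs - p
  gr <- ns$flattenParams(ns$mvBackward(fw$params, s, fw$cache, glog))
  pp <- m@params
  flat <- ns$flattenParams(pp)
  for (k in c("s1vax.conv1.W", "dense1.W", "dense2.b", "s2vcor.bn1.gamma")) {
    set.seed(10)
    idx <- sample(length(flat[[k]]), min(3, length(flat[[k]])))
    for (i in idx) {
      e <- 1e-5
      up <- pp
      up[[strsplit(k, ".", fixed = TRUE)[[1]]]][i] <-
        flat[[k]][i] + e
      dn <- pp
      dn[[strsplit(k, ".", fixed = TRUE)[[1]]]][i] <-
        flat[[k]][i] - e
      num <- (lossAt(up) - lossAt(dn)) / (2 * e)
      expect_lt(abs(num - gr[[k]][i]), 1e-3 * max(1, abs(num)))
    }
  }
})

test_that("a trained UNet is translation-covariant on patch interiors", {
  # quick-fit a tiny binary net on phantoms; predictions for the same
  # physical voxels must agree when the patch placement shifts by 8
  cases <- lapply(1:2, tinyCase)
  spec <- tinyUNetSpec(nClasses = 2L)
  m <- trainUNet(spec, cases, cases[2], epochs = 5L, pairsPerEpoch = 48L,
                 batchSize = 8L, valPatches = 4L,
                 roiExtent = c(50, 200, 280), seed = 3L)
  test <- tinyCase(9)
  win <- applyWindow(voxelData(test$volume), windowSetting())
  # a 32^3 region around the level band, and the same region shifted by 8
  c0 <- c(4L, 20L, 26L)
  cropA <- win[c0[1] + 1:32, c0[2] + 1:32, c0[3] + 1:32]
  cropB <- win[c0[1] + 9:40, c0[2] + 1:32, c0[3] + 1:32]
  pA <- predictPatch(m, cropA)
  pB <- predictPatch(m, cropB)
  aA <- pA[, , , 2] > 0.5
  aB <- pB[, , , 2] > 0.5
  # overlap interior: voxels at least 4 from either patch border
  agree <- mean(aA[13:28, 5:28, 5:28] == aB[5:20, 5:28, 5:28])
  expect_gte(agree, 0.95)
})
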