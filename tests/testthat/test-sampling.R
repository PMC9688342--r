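blobCase <- function(cornerVox, dims = c(32L, 32L, 32L), size = 4L) {
  lab <- array(0L, dims)
  lab[cornerVox[1] + seq_len(size), cornerVox[2] + seq_len(size),
      cornerVox[3] + seq_len(size)] <- 1L
  labelVolume(lab, spacing = rep(1.25, 3), nClasses = 6L)
}

fullROI <- function() roiBox("left", anchor = c(0, 0, 0),
                             extent = c(38.75, 38.75, 38.75))

test_that("center distribution is the per-axis moments of the centroids", {
  # one case: sd is zero on all axes
  one <- fitCenterDistribution(list(blobCase(c(10, 10, 10))), fullROI(),
                               patchSize = 16L)
  expect_equal(unname(one$sd), c(0, 0, 0))
  # two cases 10 mm apart on x only: mean midway, population sd 5 mm
  two <- fitCenterDistribution(list(blobCase(c(8, 10, 10)),
                                    blobCase(c(16, 10, 10))),
                               fullROI(), patchSize = 16L)
  expect_equal(unname(two$sd), c(5, 0, 0), tolerance = 1e-10)
  expect_equal(unname(two$mean[1]), 1.25 * ((8 + 16) / 2 + 1.5),
               tolerance = 1e-9)
  # phantom cohort: mean equals a brute-force centroid average
  labs <- lapply(1:4, function(s) tinyCase(s)$labels)
  roi <- defaultROIs(labs[[1]], extent = c(60, 200, 280))$left
  smp <- fitCenterDistribution(labs, roi, patchSize = 16L)
  cl <- lnlevelseg:::clampROI(roi, labs[[1]])
  centers <- vapply(labs, function(l) {
    idx <- which(voxelData(l) > 0L, arr.ind = TRUE)
    mm <- (idx - 1) * 1.25
    keep <- mm[, 1] >= cl$lo[1] & mm[, 1] <= cl$hi[1] &
      mm[, 2] >= cl$lo[2] & mm[, 2] <= cl$hi[2] &
      mm[, 3] >= cl$lo[3] & mm[, 3] <= cl$hi[3]
    colMeans(mm[keep, , drop = FALSE])
  }, numeric(3))
  expect_equal(unname(smp$mean), unname(rowMeans(centers)), tolerance = 1e-9)
  expect_error(fitCenterDistribution(list(blobCase(c(28, 28, 28))),
                                     roiBox("left", c(0, 0, 0), rep(10, 3))),
               "foreground")
})

test_that("patch sampling is truncated to the ROI and seeded", {
  ph <- tinyCase(1)
  roi <- defaultROIs(ph$volume, extent = c(60, 200, 280))$left
  smp <- fitCenterDistribution(list(ph$labels), roi, patchSize = 16L)
  # sd = 0 (single case): every draw is centered on the mean
  p1 <- samplePatch(smp, ph$volume, ph$labels, seed = 1)
  p2 <- samplePatch(smp, ph$volume, ph$labels, seed = 99)
  expect_identical(p1$corner, p2$corner)
  expect_identical(dim(p1$hu), c(16L, 16L, 16L))
  # inflate sd and check the truncation contract on many draws
  smp$sd <- c(20, 20, 20)
  cl <- lnlevelseg:::clampROI(roi, ph$volume)
  set.seed(5)
  corners <- t(replicate(2000, samplePatch(smp, ph$volume, ph$labels)$corner))
  loMm <- sweep(corners * 1.25, 2, cl$lo, "-")
  hiMm <- sweep((corners + 16) * 1.25, 2, cl$hi, "-")
  expect_true(all(loMm > -1.25 - 1e-9)) # inside clamped ROI (voxel grid)
  expect_true(all(hiMm < 1.25 + 1e-9))
  # empirical centers concentrate near the sampler mean
  centersMm <- (corners + 8) * 1.25
  expect_lt(max(abs(colMeans(centersMm) - smp$mean)), 2.5)
  # ROI smaller than the patch is rejected
  small <- roiBox("left", c(0, 0, 0), c(12, 12, 12))
  smp2 <- fitCenterDistribution(list(blobCase(c(2, 2, 2))), small,
                                patchSize = 16L)
  expect_error(samplePatch(smp2, ph$volume, ph$labels), "smaller")
})

test_that("augmentation events fire at the configured rates", {
  pol <- augmentationPolicy()
  set.seed(42)
  n <- 50000
  ev <- replicate(n, {
    e <- augmentationEvents(pol)
    c(e$flip, e$rotate, e$contrast)
  })
  rates <- rowMeans(ev)
  expect_lt(abs(rates[1] - 0.5), 0.01)
  expect_lt(abs(rates[2] - 0.4), 0.01)
  expect_lt(abs(rates[3] - 0.4), 0.01)
})

test_that("augmentation transforms behave as contracted", {
  ph <- tinyCase(2)
  roi <- defaultROIs(ph$volume, extent = c(60, 200, 280))$left
  smp <- fitCenterDistribution(list(ph$labels), roi, patchSize = 16L)
  pr <- samplePatch(smp, ph$volume, ph$labels, seed = 3)
  pol <- augmentationPolicy()
  none <- list(flip = FALSE, rotate = FALSE, plane = "sagittal", angle = 0,
               contrast = FALSE, center = 0, width = 700)
  # no events: image is just the windowed raw patch
  a0 <- augmentPatch(pr, pol, events = none)
  expect_identical(a0$labels, pr$labels)
  expect_equal(a0$image, applyWindow(pr$hu, windowSetting(0, 700)))
  # flipping is a left-right involution
  flipOnly <- modifyList(none, list(flip = TRUE))
  a1 <- augmentPatch(pr, pol, events = flipOnly)
  expect_identical(a1$labels[dim(a1$labels)[1]:1, , ], pr$labels)
  expect_equal(a1$image[dim(a1$image)[1]:1, , ], a0$image)
  # label set never grows under rotation; intensities stay in [0, 1]
  rot <- modifyList(none, list(rotate = TRUE, angle = 4.5,
                               plane = "transversal"))
  a3 <- augmentPatch(pr, pol, events = rot)
  expect_true(all(unique(as.vector(a3$labels)) %in%
                    unique(as.vector(pr$labels))))
  expect_true(all(a3$image >= 0 & a3$image <= 1))
  # deterministic given seed
  b1 <- augmentPatch(pr, pol, seed = 11)
  b2 <- augmentPatch(pr, pol, seed = 11)
  expect_identical(b1$image, b2$image)
})
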