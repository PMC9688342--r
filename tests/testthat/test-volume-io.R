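test_that("NIfTI round trip preserves data, spacing and origin", {
  v <- scanVolume(array(7, c(8, 8, 8)), spacing = c(1.25, 1.25, 2.5),
                  origin = c(-10, 5, 3))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  r <- readVolume(f)
  expect_equal(voxelData(r), voxelData(v), tolerance = 1e-6)
  expect_equal(voxelSpacing(r), voxelSpacing(v), tolerance = 1e-6)
  expect_equal(voxelOrigin(r), voxelOrigin(v), tolerance = 1e-4)

  ph <- tinyCase(3)
  f2 <- tempfile(fileext = ".nii.gz")
  writeVolume(ph$volume, f2)
  r2 <- readVolume(f2)
  expect_lt(max(abs(voxelData(r2) - voxelData(ph$volume))), 1e-4)

  f3 <- tempfile(fileext = ".nii.gz")
  writeLabelMap(ph$labels, f3)
  l3 <- readLabelMap(f3)
  expect_identical(voxelData(l3), voxelData(ph$labels))
})

test_that("reading rejects missing files and non-3D images", {
  expect_error(readVolume(tempfile()), "not found")
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f)
  expect_error(readVolume(f), "3D")
})

test_that("isotropic resampling halves spacing and doubles the axis", {
  set.seed(1)
  v <- scanVolume(array(rnorm(20 * 20 * 16), c(20, 20, 16)),
                  spacing = c(1.25, 1.25, 2.5))
  r <- resampleIsotropic(v, 1.25)
  expect_equal(voxelSpacing(r), rep(1.25, 3))
  d <- dim(voxelData(r))
  expect_equal(d[1:2], c(20L, 20L))
  expect_true(abs(d[3] - 31L) <= 1) # 2.5 mm slices -> 1.25 mm doubles (+-1)
  # a volume already at the target spacing is returned unchanged
  vIso <- scanVolume(voxelData(v), spacing = rep(2.5, 3))
  expect_identical(voxelData(resampleIsotropic(vIso, 2.5)), voxelData(v))
  expect_error(resampleIsotropic(v, -1), "targetSpacing")
})

test_that("cubic resampling reproduces a linear intensity ramp", {
  ramp <- outer(outer((0:23) * 0.5, rep(0, 20), "+"), rep(0, 16), "+")
  v <- scanVolume(ramp, spacing = c(2.5, 2.5, 2.5))
  r <- resampleIsotropic(v, 1.25)
  got <- voxelData(r)
  expected <- (seq_len(dim(got)[1]) - 1) * 1.25 / 2.5 * 0.5
  # interior columns (away from the mirror boundary) follow the ramp
  interior <- 9:(dim(got)[1] - 8)
  expect_lt(max(abs(got[interior, 10, 8] - expected[interior])), 1e-3)
})

test_that("label resampling is nearest-neighbour and preserves volume", {
  lab <- array(0L, c(20, 20, 16))
  lab[5:12, 5:12, 4:11] <- 1L # 20 mm cube at 2.5 mm spacing
  lv <- labelVolume(lab, spacing = c(2.5, 2.5, 2.5), nClasses = 2L)
  r <- resampleLabels(lv, 1.25)
  expect_true(all(voxelData(r) %in% c(0L, 1L)))
  volBefore <- sum(lab) * 2.5^3
  volAfter <- sum(voxelData(r)) * 1.25^3
  expect_lt(abs(volAfter - volBefore) / volBefore, 0.05)
  # resampling cannot invent labels
  lab6 <- voxelData(tinyCase(2)$labels)
  lv6 <- labelVolume(lab6, spacing = rep(1.25, 3), nClasses = 6L)
  r6 <- resampleLabels(lv6, 2.0)
  expect_true(all(unique(as.vector(voxelData(r6))) %in%
                    unique(as.vector(lab6))))
})

test_that("intensity windowing maps the HU window linearly onto [0, 1]", {
  w <- windowSetting(0, 700)
  expect_equal(applyWindow(0, w), 0.5)
  expect_equal(applyWindow(-700, w), 0)
  expect_equal(applyWindow(175, w), 0.75) # (175 + 350) / 700
  expect_error(windowSetting(0, -5), "width")
  # monotone non-decreasing
  x <- seq(-1000, 1000, by = 7)
  y <- applyWindow(x, w)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 1))
  # ScanVolume in, ScanVolume out
  v <- scanVolume(array(c(-5000, 0, 5000, 40), c(2, 2, 1)))
  vw <- applyWindow(v, w)
  expect_s4_class(vw, "ScanVolume")
  expect_equal(range(voxelData(vw)), c(0, 1))
})
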