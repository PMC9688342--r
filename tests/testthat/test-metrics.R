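test_that("Dice coefficient matches counts and conventions", {
  a <- array(FALSE, c(4, 4, 4))
  b <- a
  a[1:4] <- TRUE
  b[3:6] <- TRUE
  expect_equal(dsc(a, b), 0.5) # |A| = |B| = 4, overlap 2
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, array(FALSE, c(4, 4, 4))), 0)
  expect_equal(dsc(array(FALSE, c(4, 4, 4)), array(FALSE, c(4, 4, 4))), 1)
  expect_equal(dsc(a, b), dsc(b, a))
  expect_error(dsc(a, array(FALSE, c(4, 4, 2))), "geometry")
})

test_that("surface distances match a brute-force all-pairs oracle", {
  sp <- c(1.25, 1.25, 2.5)
  surfOracle <- function(m) {
    d <- dim(m)
    keep <- array(FALSE, d)
    for (i in which(m)) {
      ai <- arrayInd(i, d)
      exposed <- FALSE
      for (ax in 1:3) for (s in c(-1, 1)) {
        p <- ai
        p[ax] <- p[ax] + s
        if (any(p < 1) || any(p > d)) exposed <- TRUE
        else if (!m[p[1], p[2], p[3]]) exposed <- TRUE
      }
      keep[i] <- exposed
    }
    keep
  }
  directed <- function(A, B) {
    pa <- which(surfOracle(A), arr.ind = TRUE)
    pb <- which(surfOracle(B), arr.ind = TRUE)
    apply(pa, 1, function(p) {
      dd <- sweep(pb, 2, p, "-")
      dd <- sweep(dd, 2, sp, "*")
      sqrt(min(rowSums(dd^2)))
    })
  }
  # two single-voxel masks 10 mm apart
  a <- array(FALSE, c(8, 8, 8))
  a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(8, 8, 8))
  b[2, 2, 6] <- TRUE # 4 slices * 2.5 mm = 10 mm
  expect_equal(hausdorffDistance(a, b, sp), 10)
  expect_equal(meanSurfaceDistance(a, b, sp), 10)
  expect_equal(hausdorffDistance(a, a, sp), 0)
  expect_equal(meanSurfaceDistance(a, a, sp), 0)
  expect_true(is.na(hausdorffDistance(a, array(FALSE, c(8, 8, 8)), sp)))
  # random masks against the O(n^2) oracle
  for (s in 1:3) {
    A <- randomMask(c(6, 6, 6), 0.3, seed = s)
    B <- randomMask(c(6, 6, 6), 0.3, seed = s + 10)
    dab <- directed(A, B)
    dba <- directed(B, A)
    expect_equal(hausdorffDistance(A, B, sp), max(max(dab), max(dba)),
                 tolerance = 1e-12)
    expect_equal(meanSurfaceDistance(A, B, sp),
                 (mean(dab) + mean(dba)) / 2, tolerance = 1e-12)
    expect_equal(hausdorffDistance(A, B, sp), hausdorffDistance(B, A, sp))
  }
})

test_that("PTV expansion is an exact Euclidean dilation of selected levels", {
  ph <- tinyCase(1)
  # single voxel, 4 mm margin: matches the brute-force ball oracle
  m <- array(0L, c(12, 12, 12))
  m[6, 6, 6] <- 2L
  lab <- labelVolume(m, nClasses = 6L)
  got <- voxelData(expandPTV(lab, levels = 2, marginMm = 4)) > 0L
  oracle <- bruteDistance(m > 0L, rep(1.25, 3)) <= 4 + 1e-9
  expect_identical(got, oracle)
  # margin 0 returns the union of the selected levels
  u0 <- expandPTV(ph$labels, levels = 2:4, marginMm = 0)
  expect_identical(voxelData(u0) > 0L, voxelData(ph$labels) %in% 2:4 &
                     array(TRUE, dim(voxelData(u0))))
  # PI-PV contains PII-PIV, and the margin is monotone
  p15 <- voxelData(expandPTV(ph$labels, 1:5, 4))
  p24 <- voxelData(expandPTV(ph$labels, 2:4, 4))
  expect_true(all(p24 <= p15))
  p2 <- voxelData(expandPTV(ph$labels, 1:5, 2))
  expect_true(all(p2 <= p15))
  expect_error(expandPTV(ph$labels, levels = 7), "level")
})

test_that("post-processing fills holes, keeps the largest component, relabels", {
  # solid block with an interior hole, plus a small distant speckle
  lab <- array(0L, c(16, 16, 16))
  lab[3:10, 3:10, 3:10] <- 2L
  lab[6, 6, 6] <- 0L # one-voxel interior hole
  lab[14:15, 14, 14] <- 3L # 2-voxel far component
  lv <- labelVolume(lab, nClasses = 6L)
  pp <- voxelData(postprocessCombined(lv))
  expect_identical(sum(pp == 3L), 0L) # speckle removed
  expect_identical(pp[6, 6, 6], 2L) # hole filled with the majority label
  expect_identical(sum(pp > 0L), 8L * 8L * 8L)
  # idempotence
  pp2 <- postprocessCombined(postprocessCombined(lv))
  expect_identical(voxelData(pp2), pp)
  # empty foreground warns and returns unchanged
  empty <- labelVolume(array(0L, c(4, 4, 4)), nClasses = 6L)
  expect_warning(out <- postprocessCombined(empty), "empty")
  expect_identical(voxelData(out), voxelData(empty))
  # speckled phantom: surviving component matches a size census oracle
  ph <- tinyCase(2)
  noisy <- voxelData(ph$labels)
  set.seed(3)
  spots <- sample(which(noisy == 0L), 30)
  noisy[spots] <- 5L
  pn <- postprocessCombined(labelVolume(noisy, nClasses = 6L))
  comp <- lnlevelseg:::.label_components(noisy > 0L, dim(noisy), 26L)
  largest <- which.max(tabulate(comp[comp > 0L]))
  # fresh phantom has no interior holes, so the survivor is exactly the
  # largest component of the speckled map
  expect_identical(voxelData(pn) > 0L, array(comp == largest, dim(comp)))
})

test_that("ICC (two-way mixed, single, consistency) matches the ANOVA oracle", {
  expect_equal(iccConsistency(1:6, 1:6), 1)
  expect_equal(iccConsistency(1:6, 1:6 + 5), 1) # offset-invariant
  set.seed(8)
  v1 <- rnorm(6, 50, 10)
  v2 <- v1 + rnorm(6, 2, 3)
  # from-scratch two-way ANOVA decomposition
  x <- cbind(v1, v2)
  n <- 6
  k <- 2
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sse <- sum((x - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  expect_equal(iccConsistency(v1, v2), (msr - mse) / (msr + mse),
               tolerance = 1e-10)
  expect_warning(out <- iccConsistency(rep(1, 5), rep(1, 5)), "constant")
  expect_true(is.na(out))
  expect_error(iccConsistency(1:2, 1:2), "3")
})

test_that("volume outside the reference is additive and in mL", {
  d <- c(10, 10, 10)
  ref <- array(FALSE, d)
  ref[2:5, 2:5, 2:5] <- TRUE
  pred <- ref
  expect_equal(volumeOutside(pred, ref, rep(1.25, 3)), 0)
  pred[8, 8, 8] <- TRUE # one extra voxel at 1.25 mm spacing
  expect_equal(volumeOutside(pred, ref, rep(1.25, 3)), 1.25^3 / 1000)
  pred[9, 9, 9] <- TRUE
  expect_equal(volumeOutside(pred, ref, rep(1.25, 3)), 2 * 1.25^3 / 1000)
  expect_equal(volumeOutside(ref, pred, rep(1.25, 3)), 0) # subset
})

test_that("the per-case report covers all structures and both PTVs", {
  ph <- tinyCase(4)
  pred <- ph$labels # self-comparison: perfect agreement everywhere
  rep <- segmentationReport(pred, ph$labels)
  expect_setequal(rep$structure,
                  c("I", "II", "III", "IV", "V", "I-V", "PI-PV", "PII-PIV"))
  expect_true(all(abs(rep$dsc - 1) < 1e-12))
  expect_true(all(rep$hd == 0))
  expect_true(all(rep$volOutside == 0))
  expect_equal(rep$volPred, rep$volRef)
  # a shifted prediction degrades Dice and creates outside volume
  shift <- voxelData(ph$labels)
  shift <- shift[c(3:dim(shift)[1], 1, 2), , ]
  rep2 <- segmentationReport(labelVolume(shift, nClasses = 6L), ph$labels)
  expect_true(all(rep2$dsc < 1))
  expect_true(all(rep2$volOutside[rep2$structure == "I-V"] > 0))
})

test_that("paired model comparison returns Bonferroni-adjusted p-values", {
  set.seed(2)
  a <- matrix(rnorm(30, 0.8, 0.05), 10, 3,
              dimnames = list(NULL, c("I", "II", "III")))
  b <- a - matrix(rnorm(30, 0.05, 0.01), 10, 3)
  cmp <- compareModels(a, b)
  expect_identical(nrow(cmp), 3L)
  expect_true(all(cmp$pBonferroni >= cmp$p))
  expect_true(all(cmp$pBonferroni <= 1))
  expect_true(all(cmp$p < 0.05)) # a consistently exceeds b
})
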