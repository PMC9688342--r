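test_that("class weights follow inverse-frequency balancing", {
  mk <- function(counts) {
    v <- rep(seq_along(counts), counts)
    labelVolume(array(c(v, rep(0, 16)), c(length(v) + 16, 1, 1)),
                nClasses = length(counts) + 1L)
  }
  # equally frequent classes: all weights 1
  expect_equal(unname(computeClassWeights(mk(c(50, 50, 50)))), rep(1, 3))
  # counts 100 and 300: weights 2 and 2/3
  expect_equal(unname(computeClassWeights(mk(c(100, 300)))),
               c(2, 2 / 3), tolerance = 1e-12)
  # absent class errors with its name
  bad <- labelVolume(array(c(0L, 1L, 3L, 3L), c(4, 1, 1)), nClasses = 4L)
  expect_error(computeClassWeights(bad), "2")
  # phantom cohort matches a histogram oracle
  labs <- lapply(1:3, function(s) tinyCase(s)$labels)
  w <- computeClassWeights(labs)
  counts <- rowSums(vapply(labs, function(l)
    tabulate(voxelData(l), nbins = 5L), numeric(5)))
  expect_equal(unname(w), sum(counts) / (5 * counts), tolerance = 1e-12)
})

test_that("binary soft Dice loss matches hand counts", {
  a <- array(0, c(2, 2, 2))
  b <- a
  a[c(1, 2, 3, 4)] <- 1
  b[c(3, 4, 5, 6)] <- 1 # |A| = |B| = 4, overlap 2
  expect_equal(diceLoss(a, b, eps = 0), 0.5)
  expect_lt(diceLoss(b, b), 1e-5) # perfect overlap, up to smoothing
  disj <- array(0, c(2, 2, 2))
  disj[7:8] <- 1
  expect_gt(diceLoss(a, disj), 1 - 1e-5) # disjoint masks
  expect_error(diceLoss(array(0, c(2, 2)), array(0, c(4, 1))), "shape")
  # permutation invariance
  set.seed(3)
  p <- array(runif(27), c(3, 3, 3))
  r <- array(runif(27) < 0.4, c(3, 3, 3)) + 0
  perm <- sample(27)
  expect_equal(diceLoss(p, r),
               diceLoss(array(p[perm], dim(p)), array(r[perm], dim(r))))
})

test_that("Dice loss gradient matches finite differences on a 3^3 patch", {
  set.seed(7)
  pred <- array(runif(27, 0.05, 0.95), c(3, 3, 3))
  ref <- array(runif(27) < 0.5, c(3, 3, 3)) + 0
  g <- lnlevelseg:::diceLossGrad(pred, ref)
  num <- array(0, dim(pred))
  for (i in seq_len(27)) {
    e <- 1e-6
    up <- pred
    up[i] <- up[i] + e
    dn <- pred
    dn[i] <- dn[i] - e
    num[i] <- (diceLoss(up, ref) - diceLoss(dn, ref)) / (2 * e)
  }
  expect_lt(max(abs(g - num)), 1e-4)
})

test_that("multi-class Dice loss is the weighted sum of class losses", {
  set.seed(11)
  ref <- array(sample(0:2, 64, TRUE), c(4, 4, 4))
  probs <- array(runif(64 * 3), c(4, 4, 4, 3))
  s <- array(rep(apply(probs, 1:3, sum), 3), dim(probs))
  probs <- probs / s
  w <- c(1.5, 0.5)
  got <- multiclassDiceLoss(probs, ref, w)
  manual <- w[1] * diceLoss(probs[, , , 2], ref == 1) +
    w[2] * diceLoss(probs[, , , 3], ref == 2)
  expect_equal(got, manual, tolerance = 1e-12)
  # perfect one-hot prediction is (numerically) zero loss
  onehot <- array(0, dim(probs))
  for (m in 0:2) onehot[, , , m + 1] <- (ref == m) + 0
  expect_lt(multiclassDiceLoss(onehot, ref, c(1, 1)), 1e-4)
  # single foreground class with unit weight reduces to the binary loss
  ref2 <- array(sample(0:1, 64, TRUE), c(4, 4, 4))
  p2 <- array(runif(64, 0.1, 0.9), c(4, 4, 4))
  probs2 <- array(c(1 - p2, p2), c(4, 4, 4, 2))
  expect_equal(multiclassDiceLoss(probs2, ref2, 1), diceLoss(p2, ref2 == 1))
  expect_error(multiclassDiceLoss(probs, ref, c(1, 1, 1)), "weight")
})

test_that("categorical cross-entropy matches closed forms", {
  # one-hot p with q = p: zero (up to the numerical clip)
  p <- diag(3)
  expect_lt(categoricalCrossEntropy(p, p), 1e-5)
  # uniform q over 6 classes, one observation: log 6
  p6 <- matrix(c(1, 0, 0, 0, 0, 0), 1)
  q6 <- matrix(rep(1 / 6, 6), 1)
  expect_equal(categoricalCrossEntropy(p6, q6), log(6), tolerance = 1e-9)
  # two observations with true-class probabilities 0.5 and 0.25
  p2 <- rbind(c(1, 0), c(0, 1))
  q2 <- rbind(c(0.5, 0.5), c(0.75, 0.25))
  expect_equal(categoricalCrossEntropy(p2, q2), log(2) + log(4),
               tolerance = 1e-9)
  # rows of q must sum to one
  expect_error(categoricalCrossEntropy(p2, rbind(c(0.5, 0.3), c(0.5, 0.5))),
               "sum")
})
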