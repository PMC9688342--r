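# Shared fixtures: small phantoms and tiny network specs built in code.

# compact phantom on a 72 x 72 x 96 grid; the default anatomy fits, only
# the cranio-caudal jitter is reduced to keep structures inside the grid
tinyPhantomSpec <- function(seed = 1L, ...) {
  phantomSpec(shape = c(72L, 72L, 96L), spacing = 1.25,
              jitterMm = c(2, 4, 8), seed = seed, ...)
}

tinyCase <- function(seed = 1L, ...) generatePhantom(tinyPhantomSpec(seed, ...))

tinyUNetSpec <- function(nClasses = 2L, patchSize = 16L) {
  unetSpec(patchSize = patchSize, depth = 2L, baseFilters = 4L,
           nClasses = nClasses, dropout = 0)
}

tinyMVSpec <- function(nClasses = 6L) {
  mvSpec(nScales = 3L, inPlaneSamples = 8L, strides = c(1L, 2L, 4L),
         viewFilters = c(4L, 8L), denseUnits = 16L, nClasses = nClasses,
         dropout = 0)
}

# small random binary mask with a fixed seed
randomMask <- function(dims, p = 0.2, seed = 1L) {
  set.seed(seed)
  array(runif(prod(dims)) < p, dims)
}

# brute-force exact Euclidean distance from every voxel to the nearest
# TRUE voxel (mm); independent oracle for the distance-transform paths
bruteDistance <- function(mask, spacing) {
  d <- dim(mask)
  pts <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    dd <- sweep(pts, 2, idx[i, ], "-")
    dd <- sweep(dd, 2, spacing, "*")
    out[i] <- sqrt(min(rowSums(dd^2)))
  }
  out
}
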