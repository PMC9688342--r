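test_that("phantom generation is deterministic and well-formed", {
  a <- tinyCase(7)
  b <- tinyCase(7)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(voxelData(a$labels), voxelData(b$labels))
  expect_setequal(unique(as.vector(voxelData(a$labels))), 0:5)
  expect_identical(dim(voxelData(a$volume)), dim(voxelData(a$labels)))
  # different seeds differ (noise and positioning jitter)
  c <- tinyCase(8)
  expect_false(identical(voxelData(a$labels), voxelData(c$labels)))
})

test_that("levels II, III and IV never share an axial slice when upright", {
  lab <- voxelData(tinyCase(3)$labels)
  for (z in seq_len(dim(lab)[3])) {
    present <- unique(as.vector(lab[, , z]))
    expect_lte(sum(c(2L, 3L, 4L) %in% present), 1L)
  }
})

test_that("phantom is mirror-symmetric and one 26-component per side", {
  lab <- voxelData(tinyCase(5)$labels)
  d <- dim(lab)
  expect_identical(lab, lab[d[1]:1, , ])
  # independent flood-fill oracle for the component count of one side
  half <- lab
  half[(d[1] / 2 + 1):d[1], , ] <- 0L
  mask <- half > 0L
  seeds <- which(mask)
  visited <- array(FALSE, d)
  queue <- seeds[1]
  visited[seeds[1]] <- TRUE
  nbr <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  while (length(queue)) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    ci <- arrayInd(cur, d)
    for (k in seq_len(nrow(nbr))) {
      p <- ci + nbr[k, ]
      if (any(p < 1) || any(p > d)) next
      li <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
      if (mask[li] && !visited[li]) {
        visited[li] <- TRUE
        queue <- c(queue, li)
      }
    }
  }
  expect_true(all(visited[mask])) # a single connected component
})

test_that("labelled volume is stable across seeds at fixed geometry", {
  vols <- vapply(1:6, function(s) {
    lab <- voxelData(tinyCase(s)$labels)
    sum(lab > 0L) * 1.25^3
  }, numeric(1))
  expect_lt((max(vols) - min(vols)) / mean(vols), 0.1)
})

test_that("hole filling is a no-op on fresh phantoms", {
  lab <- tinyCase(2)$labels
  pp <- postprocessCombined(lab)
  expect_identical(voxelData(pp), voxelData(lab))
})

test_that("angulation rotates rigidly and near-invertibly", {
  ph <- tinyCase(4)
  # zero angles: identity
  id <- angulate(ph$volume, ph$labels, 0, 0)
  expect_identical(voxelData(id$labels), voxelData(ph$labels))
  expect_error(angulate(ph$volume, ph$labels, 25, 0), "20")
  # +10 then -10 degrees pitch: near-inverse up to interpolation loss
  r1 <- angulate(ph$volume, ph$labels, 10, 0)
  r2 <- angulate(r1$volume, r1$labels, -10, 0)
  expect_gte(dsc(binarizeLabels(r2$labels), binarizeLabels(ph$labels)), 0.95)
  # label set preserved under rotation
  expect_true(all(unique(as.vector(voxelData(r1$labels))) %in% 0:5))
})

test_that("pitch makes levels II and III share an axial slice", {
  ph <- generatePhantom(phantomSpec(seed = 2))
  rot <- angulate(ph$volume, ph$labels, 10, 0)
  lab <- voxelData(rot$labels)
  share <- FALSE
  for (z in seq_len(dim(lab)[3])) {
    sl <- lab[, , z]
    if (any(sl == 2L) && any(sl == 3L)) {
      share <- TRUE
      break
    }
  }
  expect_true(share)
})
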