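# Training orchestration: optimizer settings, learning-rate decay,
# cross-validation folds, epoch construction and ensemble training.

#' Optimizer configuration
#'
#' Adam with the standard moments and an exponential learning-rate decay:
#' 5 percent per epoch down to a floor.
#'
#' @param lr0 Initial learning rate (default 0.001).
#' @param beta1,beta2,epsilon Adam moments and stabilizer (defaults 0.9,
#'   0.999, 1e-7).
#' @param decayRate Multiplicative decay per epoch (default 0.95).
#' @param lrFloor Minimum learning rate (default 0.0001).
#' @return An \code{OptimizerConfig} list.
#' @export
optimizerConfig <- function(lr0 = 0.001, beta1 = 0.9, beta2 = 0.999,
                            epsilon = 1e-7, decayRate = 0.95,
                            lrFloor = 0.0001) {
  stopifnot(lrFloor > 0, lrFloor <= lr0, decayRate > 0, decayRate < 1)
  structure(list(lr0 = lr0, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 decayRate = decayRate, lrFloor = lrFloor),
            class = "OptimizerConfig")
}

#' Exponentially decayed learning rate
#'
#' \code{max(lr0 * decayRate^epoch, lrFloor)}: non-increasing in the epoch
#' and bounded below by the floor.
#'
#' @param epoch Zero-based epoch index.
#' @param cfg An \code{\link{optimizerConfig}}.
#' @return The learning rate for that epoch.
#' @export
lrSchedule <- function(epoch, cfg = optimizerConfig()) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  pmax(cfg$lr0 * cfg$decayRate^epoch, cfg$lrFloor)
}

#' Deterministic k-fold partition of cases
#'
#' Shuffles the case identifiers under the seed and deals them round-robin
#' into k folds, so fold sizes differ by at most one and the test folds
#' partition the cases (60 cases in 5 folds give 12 held-out cases each).
#'
#' @param caseIds Vector of case identifiers.
#' @param k Number of folds (default 5).
#' @param seed RNG seed (default 1).
#' @return A \code{FoldPlan} list: \code{k}, and \code{assignments}, a
#'   named integer vector mapping case id to fold index.
#' @export
makeFolds <- function(caseIds, k = 5L, seed = 1L) {
  n <- length(caseIds)
  if (k > n) stop("more folds than cases")
  perm <- withSeed(seed, sample(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(k), n)
  names(fold) <- as.character(caseIds)
  structure(list(k = as.integer(k), assignments = fold), class = "FoldPlan")
}

#' Test/train case ids of one fold
#'
#' @param plan A \code{\link{makeFolds}} result.
#' @param fold Fold index in \code{1..k}.
#' @return List with \code{train} and \code{test} id vectors.
#' @export
foldSplit <- function(plan, fold) {
  stopifnot(inherits(plan, "FoldPlan"), fold >= 1, fold <= plan$k)
  ids <- names(plan$assignments)
  list(train = ids[plan$assignments != fold],
       test = ids[plan$assignments == fold])
}

#' Per-epoch training subset with minority oversampling
#'
#' Draws at most \code{maxFraction} of the pooled training pairs for one
#' epoch and balances the classes by random oversampling: each class
#' contributes \code{floor(subset / M)} pairs, sampled without replacement
#' where the class pool suffices and with replacement otherwise.
#'
#' @param voxelPool Named list of per-class item index vectors.
#' @param maxFraction Maximum fraction of the pool per epoch (default 0.2).
#' @param maxTotal Optional additional cap on the subset size (the 20
#'   percent rule is an upper bound; small experiments can draw less).
#' @param seed Optional seed.
#' @return Named list of per-class sampled index vectors (equal sizes).
#' @export
sampleEpochSubset <- function(voxelPool, maxFraction = 0.2, maxTotal = Inf,
                              seed = NULL) {
  sizes <- lengths(voxelPool)
  if (any(sizes == 0)) stop("empty class pool: ",
                            paste(names(voxelPool)[sizes == 0], collapse = ","))
  M <- length(voxelPool)
  target <- floor(min(maxFraction * sum(sizes), maxTotal) / M)
  if (target < 1) target <- 1L
  draw <- function() lapply(voxelPool, function(idx) {
    if (length(idx) >= target) sample(idx, target)
    else sample(idx, target, replace = TRUE)
  })
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

# macro-averaged hard Dice of an argmax prediction vs reference labels,
# over foreground classes present in either map
macroDice <- function(predLab, refLab, M) {
  ds <- c()
  for (m in seq_len(M - 1L)) {
    a <- predLab == m
    b <- refLab == m
    if (!any(a) && !any(b)) next
    ds <- c(ds, 2 * sum(a & b) / (sum(a) + sum(b)))
  }
  if (length(ds) == 0) return(NA_real_)
  mean(ds)
}

#' Train a patch-based UNet
#'
#' Each epoch samples \code{pairsPerEpoch} patches from the unilateral
#' ROIs of randomly drawn training cases via the truncated-Gaussian
#' sampler, augments and windows them, and optimizes the class-weighted
#' multi-class soft Dice loss (binary Dice when M = 2) with Adam under the
#' exponential learning-rate schedule. After every epoch the validation
#' DSC is computed on patches sampled from the validation cases, and the
#' checkpoint with the highest validation DSC (not the last) is returned.
#'
#' @param spec A \code{\link{unetSpec}}.
#' @param cases List of training cases, each a list with \code{volume}
#'   (\linkS4class{ScanVolume}, raw HU) and \code{labels}
#'   (\linkS4class{LabelVolume}).
#' @param valCases Validation cases (same structure); used for checkpoint
#'   selection.
#' @param optimizer An \code{\link{optimizerConfig}}.
#' @param epochs Number of epochs (default 100).
#' @param pairsPerEpoch Patches sampled per epoch (default 4096).
#' @param batchSize Patches per optimizer step (default 2).
#' @param valPatches Validation patches sampled per epoch (default 16).
#' @param policy An \code{\link{augmentationPolicy}}; use probabilities 0
#'   to disable stochastic augmentation (windowing still applies).
#' @param classWeights Foreground class weights for M > 2
#'   (\code{\link{computeClassWeights}}); computed from \code{cases} when
#'   \code{NULL}.
#' @param roiExtent Extent of the two unilateral sampling ROIs in mm
#'   (default \code{c(280, 200, 280)}, the clinical ROI; desk-scale
#'   phantoms narrower than two ROI widths use a smaller lateral extent
#'   so the sides stay distinct).
#' @param seed RNG seed; the run is deterministic given the seed.
#' @param verbose Print per-epoch progress.
#' @return A \linkS4class{TrainedModel} with the best checkpoint and a
#'   \code{log} attribute (data.frame of epoch, meanLoss, valDice, lr).
#' @export
trainUNet <- function(spec, cases, valCases, optimizer = optimizerConfig(),
                      epochs = 100L, pairsPerEpoch = 4096L, batchSize = 2L,
                      valPatches = 16L, policy = augmentationPolicy(),
                      classWeights = NULL, roiExtent = c(280, 200, 280),
                      seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "UNetSpec"), length(cases) >= 1L)
  M <- spec$nClasses
  binary <- M == 2L
  if (!binary && is.null(classWeights))
    classWeights <- computeClassWeights(lapply(cases, `[[`, "labels"))
  withSeed(seed, {
    model <- buildUNet(spec)
    params <- model@params
    eng <- .eng_new(params, unclass(spec))
    state <- adamInit(params)
    # per-side samplers fitted on the training labels
    rois <- defaultROIs(cases[[1]]$volume, extent = roiExtent)
    samplers <- lapply(rois, function(r)
      fitCenterDistribution(lapply(cases, `[[`, "labels"), r,
                            patchSize = spec$patchSize))
    drawBatch <- function(fromCases, n, augment = TRUE) {
      imgs <- array(0, c(rep(spec$patchSize, 3), 1L, n))
      labs <- array(0L, c(rep(spec$patchSize, 3), n))
      for (i in seq_len(n)) {
        cs <- fromCases[[sample.int(length(fromCases), 1)]]
        sm <- samplers[[sample.int(length(samplers), 1)]]
        pr <- samplePatch(sm, cs$volume, cs$labels)
        ev <- if (augment) NULL else
          list(flip = FALSE, rotate = FALSE, plane = "sagittal", angle = 0,
               contrast = FALSE, center = policy$windowMuCenter,
               width = policy$windowMuWidth)
        ap <- augmentPatch(pr, policy, events = ev)
        imgs[, , , 1L, i] <- ap$image
        lb <- ap$labels
        if (binary) lb <- (lb > 0L) + 0L
        labs[, , , i] <- lb
      }
      list(x = imgs, y = labs)
    }
    best <- list(metric = -Inf, params = params)
    log <- data.frame()
    nBatches <- max(1L, floor(pairsPerEpoch / batchSize))
    for (ep in seq_len(epochs)) {
      lr <- lrSchedule(ep - 1L, optimizer)
      losses <- numeric(nBatches)
      for (bt in seq_len(nBatches)) {
        bb <- drawBatch(cases, batchSize)
        probs <- .eng_fwd(eng, bb$x, TRUE)
        dm <- dim(probs)
        N <- dm[5]
        gprobs <- array(0, dm)
        lsum <- 0
        for (i in seq_len(N)) {
          pi4 <- array(probs[, , , , i], dm[1:4])
          yi <- array(bb$y[, , , i], dm[1:3])
          if (binary) {
            lsum <- lsum + diceLoss(pi4[, , , 2L], yi)
            g <- array(0, dm[1:4])
            g[, , , 2L] <- diceLossGrad(pi4[, , , 2L], yi)
          } else {
            lsum <- lsum + multiclassDiceLoss(pi4, yi, classWeights)
            g <- multiclassDiceLossGrad(pi4, yi, classWeights)
          }
          gprobs[, , , , i] <- g / N
        }
        loss <- lsum / N
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep, ", batch ", bt)
        losses[bt] <- loss
        grads <- .eng_bwd(eng, gprobs)
        upd <- adamStep(params, grads, state, lr,
                        optimizer$beta1, optimizer$beta2, optimizer$epsilon)
        params <- upd$params
        state <- upd$state
        .eng_set_weights(eng, params)
      }
      # validation DSC on patches from held-out cases, no augmentation
      vb <- drawBatch(valCases, valPatches, augment = FALSE)
      vDice <- numeric(0)
      for (i0 in seq(1, valPatches, by = batchSize)) {
        ii <- i0:min(i0 + batchSize - 1L, valPatches)
        vx <- vb$x[, , , , ii, drop = FALSE]
        vp <- .eng_fwd(eng, vx, FALSE)
        for (j in seq_along(ii)) {
          pl <- hardLabels(array(vp[, , , , j], dim(vp)[1:4]))
          vDice <- c(vDice, macroDice(pl, array(vb$y[, , , ii[j]],
                                                dim(vp)[1:3]), M))
        }
      }
      valDice <- mean(vDice, na.rm = TRUE)
      log <- rbind(log, data.frame(epoch = ep, meanLoss = mean(losses),
                                   valDice = valDice, lr = lr))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val DSC %.4f, lr %.5f",
                        ep, mean(losses), valDice, lr))
      if (is.finite(valDice) && valDice > best$metric)
        best <- list(metric = valDice,
                     params = mergeBNStats(params, .eng_get_bn(eng)))
    }
    out <- new("TrainedModel", kind = "unet", spec = unclass(spec),
               params = best$params, bestMetric = best$metric)
    attr(out, "log") <- log
    out
  })
}

# fold the engine's batch-norm running statistics back into a parameter
# snapshot (nested lists keyed the same way)
mergeBNStats <- function(params, stats) {
  for (blk in names(stats))
    for (bn in names(stats[[blk]])) {
      params[[c(blk, bn, "rmean")]] <- stats[[blk]][[bn]]$rmean
      params[[c(blk, bn, "rvar")]] <- stats[[blk]][[bn]]$rvar
    }
  params
}

# argmax labels from a (X,Y,Z,M) probability array; ties toward the lower
# class index (background wins ties)
hardLabels <- function(probs, classes = 0:(dim(probs)[4] - 1L)) {
  d <- dim(probs)
  m <- matrix(probs, prod(d[1:3]), d[4])
  array(classes[max.col(m, ties.method = "first")], d[1:3])
}

#' Train a multi-view voxel classifier
#'
#' Builds the per-voxel training pool from all voxels inside the 15 mm
#' evaluation masks of the training cases (or inside the reference
#' foreground for the sequential M = 5 variant), then optimizes the
#' categorical cross-entropy with Adam. Every epoch draws a fresh random
#' subset of at most \code{maxFraction} of the pool, oversamples minority
#' classes to balance, and consumes it in minibatches. The checkpoint
#' with the best validation DSC (macro-averaged hard Dice over the
#' validation voxel sample) is kept.
#'
#' @param spec An \code{\link{mvSpec}}.
#' @param cases,valCases Case lists as in \code{\link{trainUNet}}.
#' @param optimizer An \code{\link{optimizerConfig}}.
#' @param epochs Number of epochs (default 1000).
#' @param batchSize Voxels per optimizer step (default 32).
#' @param maxFraction Per-epoch pool fraction (default 0.2).
#' @param maxPairsPerEpoch Additional cap on the per-epoch subset size
#'   (the 20 percent rule is an upper bound; desk-scale experiments can
#'   draw fewer voxels per epoch).
#' @param maskMarginMm Evaluation-mask expansion margin in mm (default 15);
#'   ignored when \code{foregroundOnly}.
#' @param foregroundOnly When TRUE (sequential configuration), train only
#'   on reference foreground voxels with classes 1..5.
#' @param valVoxelsPerCase Validation voxels sampled per validation case
#'   (default 200).
#' @param window The \code{\link{windowSetting}} applied to volumes.
#' @param seed RNG seed.
#' @param verbose Print per-epoch progress.
#' @return A \linkS4class{TrainedModel} of kind \code{"mv"} with a
#'   \code{log} attribute.
#' @export
trainMV <- function(spec, cases, valCases, optimizer = optimizerConfig(),
                    epochs = 1000L, batchSize = 32L, maxFraction = 0.2,
                    maxPairsPerEpoch = Inf, maskMarginMm = 15,
                    foregroundOnly = FALSE, valVoxelsPerCase = 200L,
                    window = windowSetting(), seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "MVSpec"))
  M <- spec$nClasses
  classes <- if (foregroundOnly) seq_len(M) else 0:(M - 1L)
  withSeed(seed, {
    prep <- function(cs) {
      img <- applyWindow(cs$volume, window)
      lab <- voxelData(cs$labels)
      eligible <- if (foregroundOnly) lab > 0L else
        voxelData(expandMask(binarizeLabels(cs$labels), maskMarginMm)) > 0L
      idx <- which(eligible)
      list(img = voxelData(img), lab = lab[idx], idx = idx,
           dim = dim(lab))
    }
    tr <- lapply(cases, prep)
    vl <- lapply(valCases, prep)
    # pool: global (case, voxel) pairs per class
    pool <- list()
    for (m in classes) {
      items <- list()
      for (ci in seq_along(tr)) {
        sel <- which(tr[[ci]]$lab == m)
        if (length(sel)) items[[length(items) + 1L]] <-
            cbind(ci, tr[[ci]]$idx[sel])
      }
      pool[[as.character(m)]] <- if (length(items)) do.call(rbind, items)
        else matrix(integer(0), 0, 2)
    }
    if (any(vapply(pool, nrow, integer(1)) == 0))
      stop("a class has no training voxels in the pool")
    poolIdx <- lapply(pool, function(p) seq_len(nrow(p)))
    model <- buildMV(spec)
    params <- model@params
    state <- adamInit(params)
    viewsFor <- function(set, caseIdx, voxLin) {
      out <- NULL
      for (ci in unique(caseIdx)) {
        rows <- which(caseIdx == ci)
        d <- set[[ci]]$dim
        lin <- voxLin[rows] - 1L
        vox <- cbind(lin %% d[1], (lin %/% d[1]) %% d[2],
                     lin %/% (d[1] * d[2]))
        vv <- .extract_views_batch(set[[ci]]$img, d, vox,
                                   spec$inPlaneSamples, spec$strides)
        if (is.null(out)) {
          out <- array(0, c(dim(vv)[1:4], length(voxLin)))
        }
        out[, , , , rows] <- vv
      }
      out
    }
    # fixed validation sample
    valItems <- do.call(rbind, lapply(seq_along(vl), function(ci) {
      n <- min(valVoxelsPerCase, length(vl[[ci]]$idx))
      sel <- sample.int(length(vl[[ci]]$idx), n)
      cbind(ci, vl[[ci]]$idx[sel], vl[[ci]]$lab[sel])
    }))
    best <- list(metric = -Inf, params = params)
    log <- data.frame()
    for (ep in seq_len(epochs)) {
      lr <- lrSchedule(ep - 1L, optimizer)
      sub <- sampleEpochSubset(poolIdx, maxFraction, maxPairsPerEpoch)
      items <- do.call(rbind, lapply(names(sub), function(m)
        cbind(pool[[m]][sub[[m]], , drop = FALSE],
              as.integer(m))))
      items <- items[sample.int(nrow(items)), , drop = FALSE]
      losses <- c()
      for (b0 in seq(1, nrow(items), by = batchSize)) {
        bi <- b0:min(b0 + batchSize - 1L, nrow(items))
        it <- items[bi, , drop = FALSE]
        views <- viewsFor(tr, it[, 1], it[, 2])
        fw <- mvForward(params, views, spec, training = TRUE)
        params <- fw$params
        q <- fw$probs
        p <- matrix(0, nrow(q), M)
        p[cbind(seq_len(nrow(q)), match(it[, 3], classes))] <- 1
        loss <- categoricalCrossEntropy(p, q) / nrow(q)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep)
        losses <- c(losses, loss)
        glogits <- (q - p) / nrow(q)
        grads <- mvBackward(params, spec, fw$cache, glogits)
        upd <- adamStep(params, grads, state, lr,
                        optimizer$beta1, optimizer$beta2, optimizer$epsilon)
        params <- upd$params
        state <- upd$state
      }
      # validation: macro Dice over the fixed voxel sample
      vq <- NULL
      for (b0 in seq(1, nrow(valItems), by = 256)) {
        bi <- b0:min(b0 + 255L, nrow(valItems))
        vv <- viewsFor(vl, valItems[bi, 1], valItems[bi, 2])
        vq <- rbind(vq, mvForward(params, vv, spec, training = FALSE)$probs)
      }
      predCls <- classes[max.col(vq, ties.method = "first")]
      valDice <- macroDiceVec(predCls, valItems[, 3], classes)
      log <- rbind(log, data.frame(epoch = ep, meanLoss = mean(losses),
                                   valDice = valDice, lr = lr))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val DSC %.4f", ep,
                        mean(losses), valDice))
      if (is.finite(valDice) && valDice > best$metric)
        best <- list(metric = valDice, params = params)
    }
    out <- new("TrainedModel", kind = "mv", spec = unclass(spec),
               params = best$params, bestMetric = best$metric)
    attr(out, "log") <- log
    out
  })
}

macroDiceVec <- function(pred, ref, classes) {
  fg <- classes[classes != 0L]
  ds <- c()
  for (m in fg) {
    a <- pred == m
    b <- ref == m
    if (!any(a) && !any(b)) next
    ds <- c(ds, 2 * sum(a & b) / (sum(a) + sum(b)))
  }
  if (!length(ds)) NA_real_ else mean(ds)
}

#' Train an ensemble of sequentially trained networks
#'
#' Trains \code{nMembers} models with member-distinct seeds derived
#' deterministically from \code{baseSeed} (\code{baseSeed + member - 1}).
#' At inference the members' class probabilities are summed and the
#' argmax decides the label (\code{\link{ensembleFuse}}).
#'
#' @param trainFun \code{\link{trainUNet}} or \code{\link{trainMV}}.
#' @param spec The architecture spec shared by all members.
#' @param cases,valCases Case lists as in \code{\link{trainUNet}}.
#' @param nMembers Ensemble size (default 5).
#' @param baseSeed Base RNG seed (default 1).
#' @param ... Further arguments to \code{trainFun}.
#' @return A \linkS4class{ModelEnsemble}.
#' @export
trainEnsemble <- function(trainFun, spec, cases, valCases, nMembers = 5L,
                          baseSeed = 1L, ...) {
  members <- lapply(seq_len(nMembers), function(i)
    trainFun(spec, cases, valCases, seed = baseSeed + i - 1L, ...))
  modelEnsemble(members)
}
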