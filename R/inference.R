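# Full-volume prediction: sliding-window center-crop UNet inference,
# evaluation-mask construction, mask-restricted multi-view classification,
# ensemble fusion and the three end-to-end configurations.

#' Binarize a label map (combined foreground structure)
#'
#' @param lab A \linkS4class{LabelVolume}.
#' @return A binary \linkS4class{LabelVolume} (nClasses 2): 1 where any
#'   foreground level is present.
#' @export
binarizeLabels <- function(lab) {
  labelVolume((voxelData(lab) > 0L) + 0L, voxelSpacing(lab),
              voxelOrigin(lab), nClasses = 2L)
}

# replicate-pad an array so that central core tiles exactly cover it;
# returns padded array and the lo-pad offsets
padForTiling <- function(arr, core, basePad) {
  d <- dim(arr)
  ntile <- ceiling(d / core)
  padded <- core * ntile + 2L * basePad
  ix <- lapply(1:3, function(i)
    pmin(pmax(seq_len(padded[i]) - basePad, 1L), d[i]))
  list(arr = arr[ix[[1]], ix[[2]], ix[[3]]], ntile = ntile,
       padLo = rep(basePad, 3))
}

#' Sliding-window center-crop prediction over a full volume
#'
#' Slides the model's cubic field of view (edge P) over the volume with
#' stride P/2 and keeps only the central (P/2)^3 voxels of every window,
#' so each voxel of the original volume is classified exactly once. The
#' volume is replicate-padded by P/4 on each side, plus whatever rounds
#' each dimension up to a multiple of P/2, so the central tiles exactly
#' cover the original grid.
#'
#' @param model A \linkS4class{TrainedModel} (kind \code{"unet"} or
#'   \code{"stub"}).
#' @param vol A \linkS4class{ScanVolume} in raw HU at the model's training
#'   spacing.
#' @param window \code{\link{windowSetting}} applied before prediction;
#'   \code{NULL} if \code{vol} is already normalized.
#' @return A \linkS4class{ProbabilityMap} aligned to \code{vol}.
#' @export
slidingWindowPredict <- function(model, vol, window = windowSetting()) {
  stopifnot(is(vol, "ScanVolume"))
  ps <- as.integer(model@spec$patchSize)
  core <- ps %/% 2L
  basePad <- ps %/% 4L
  M <- as.integer(model@spec$nClasses)
  arr <- voxelData(vol)
  if (!is.null(window)) arr <- applyWindow(arr, window)
  d <- dim(arr)
  if (any(d < 1L)) stop("empty volume")
  pad <- padForTiling(arr, core, basePad)
  out <- array(0, c(d, M))
  tiles <- as.matrix(expand.grid(tx = seq_len(pad$ntile[1]) - 1L,
                                 ty = seq_len(pad$ntile[2]) - 1L,
                                 tz = seq_len(pad$ntile[3]) - 1L))
  eng <- if (model@kind == "unet")
    .eng_new(model@params, model@spec) else NULL
  batch <- 8L
  cc <- basePad + seq_len(core)
  # constant windows (e.g. pure air) are bit-identical inputs to a
  # deterministic network, so one prediction per constant value suffices
  constCache <- list()
  writeTile <- function(w0, prSlice) {
    ox <- w0[1] + seq_len(core)
    oy <- w0[2] + seq_len(core)
    oz <- w0[3] + seq_len(core)
    keep <- list(ox <= d[1], oy <= d[2], oz <= d[3])
    out[ox[keep[[1]]], oy[keep[[2]]], oz[keep[[3]]], ] <<-
      prSlice[cc[keep[[1]]], cc[keep[[2]]], cc[keep[[3]]], , drop = FALSE]
  }
  pending <- list()
  flush <- function() {
    if (!length(pending)) return()
    xs <- array(0, c(ps, ps, ps, 1L, length(pending)))
    for (j in seq_along(pending)) xs[, , , 1L, j] <- pending[[j]]$patch
    pr <- if (is.null(eng)) predictPatch(model, array(xs, c(ps, ps, ps,
                                                            length(pending))))
          else .eng_fwd(eng, xs, FALSE)
    for (j in seq_along(pending)) {
      slice <- array(pr[, , , , j], c(ps, ps, ps, M))
      if (!is.null(pending[[j]]$key))
        constCache[[pending[[j]]$key]] <<- slice
      writeTile(pending[[j]]$w0, slice)
    }
    pending <<- list()
  }
  for (t in seq_len(nrow(tiles))) {
    w0 <- tiles[t, ] * core # 0-based window start in padded grid
    patch <- pad$arr[w0[1] + seq_len(ps), w0[2] + seq_len(ps),
                     w0[3] + seq_len(ps)]
    rng <- range(patch)
    key <- if (rng[1] == rng[2]) format(rng[1], digits = 17) else NULL
    if (!is.null(key) && !is.null(constCache[[key]])) {
      writeTile(w0, constCache[[key]])
    } else {
      pending[[length(pending) + 1L]] <- list(patch = patch, w0 = w0,
                                              key = key)
      if (!is.null(key)) flush() # cache it before more tiles arrive
      else if (length(pending) >= batch) flush()
    }
  }
  flush()
  probabilityMap(out, voxelSpacing(vol), voxelOrigin(vol), classes = 0:(M - 1L))
}

#' Expand a binary structure by a Euclidean margin (evaluation mask)
#'
#' A voxel belongs to the expanded mask iff its center lies within
#' \code{marginMm} (exact Euclidean distance in mm, anisotropy-aware) of
#' the input structure. The input is always a subset of the output and
#' masks are nested in the margin.
#'
#' @param lab A binary \linkS4class{LabelVolume} (any nonzero label counts
#'   as structure).
#' @param marginMm Expansion margin in mm (>= 0; default 15, the margin
#'   used to build the multi-view evaluation mask from the manual
#'   reference).
#' @return A binary \linkS4class{LabelVolume}.
#' @export
expandMask <- function(lab, marginMm = 15) {
  stopifnot(is(lab, "LabelVolume"))
  if (marginMm < 0) stop("margin must be >= 0")
  m <- voxelData(lab) > 0L
  if (!any(m)) return(binarizeLabels(lab))
  d2 <- .edt_sq(m, dim(m), voxelSpacing(lab))
  labelVolume((d2 <= marginMm^2 + 1e-9) + 0L, voxelSpacing(lab),
              voxelOrigin(lab), nClasses = 2L)
}

#' Classify only the voxels inside an evaluation mask
#'
#' Runs the multi-view classifier on every voxel of the mask (in batches,
#' so runtime is proportional to the mask size). Outside the mask the
#' output is the resting distribution: probability 1 on the background
#' channel when the model has one, else on its first class (those voxels
#' are not meaningful and are never read by the sequential configuration).
#'
#' @param model A \linkS4class{TrainedModel} (kind \code{"mv"} or
#'   \code{"stub"}).
#' @param vol A \linkS4class{ScanVolume} in raw HU.
#' @param mask A binary \linkS4class{LabelVolume} of eligible voxels.
#' @param window \code{\link{windowSetting}} applied before view
#'   extraction; \code{NULL} if already normalized.
#' @param classes Integer class labels of the model's output channels
#'   (default \code{0:(M-1)}; use \code{1:5} for the foreground-only
#'   sequential stage).
#' @param batchSize Voxels per forward pass (default 256).
#' @return A \linkS4class{ProbabilityMap} restricted to the mask.
#' @export
classifyMaskedVoxels <- function(model, vol, mask, window = windowSetting(),
                                 classes = NULL, batchSize = 256L) {
  stopifnot(is(vol, "ScanVolume"), is(mask, "LabelVolume"))
  checkSameGeometry(vol, mask, "volume and mask")
  M <- as.integer(model@spec$nClasses)
  if (is.null(classes)) classes <- 0:(M - 1L)
  stopifnot(length(classes) == M)
  arr <- voxelData(vol)
  if (!is.null(window)) arr <- applyWindow(arr, window)
  d <- dim(arr)
  out <- array(0, c(d, M))
  bg <- match(0L, classes)
  out[, , , if (is.na(bg)) 1L else bg] <- 1
  lin <- which(voxelData(mask) > 0L)
  if (!length(lin)) {
    warning("empty evaluation mask: returning all-background probabilities")
    return(probabilityMap(out, voxelSpacing(vol), voxelOrigin(vol),
                          classes = classes))
  }
  spec <- model@spec
  ip <- if (model@kind == "stub") 8L else spec$inPlaneSamples
  strides <- if (model@kind == "stub") 1L else spec$strides
  nvox <- prod(d)
  for (b0 in seq(1, length(lin), by = batchSize)) {
    bi <- b0:min(b0 + batchSize - 1L, length(lin))
    l0 <- lin[bi] - 1L
    vox <- cbind(l0 %% d[1], (l0 %/% d[1]) %% d[2], l0 %/% (d[1] * d[2]))
    q <- if (model@kind == "stub")
      matrix(model@spec$probs, length(bi), M, byrow = TRUE)
    else
      predictViews(model, .extract_views_batch(arr, d, vox, ip, strides))
    for (m in seq_len(M)) out[lin[bi] + (m - 1L) * nvox] <- q[, m]
  }
  probabilityMap(out, voxelSpacing(vol), voxelOrigin(vol), classes = classes)
}

#' Fuse an ensemble's probability maps into a label map
#'
#' Per voxel, the members' class probabilities are summed and the class
#' with the highest cumulated probability decides the label; ties break
#' deterministically toward the lower class index (background wins ties
#' with foreground).
#'
#' @param maps List of \linkS4class{ProbabilityMap} sharing geometry and
#'   class set.
#' @return A \linkS4class{LabelVolume}.
#' @export
ensembleFuse <- function(maps) {
  stopifnot(length(maps) >= 1L)
  cls <- maps[[1]]@classes
  for (m in maps[-1]) {
    checkSameGeometry(m, maps[[1]], "probability maps")
    if (!identical(m@classes, cls)) stop("class sets differ across members")
  }
  tot <- voxelData(maps[[1]])
  for (m in maps[-1]) tot <- tot + voxelData(m)
  lab <- hardLabels(tot, classes = cls)
  labelVolume(lab, voxelSpacing(maps[[1]]), voxelOrigin(maps[[1]]),
              nClasses = max(cls) + 1L)
}

#' Run one of the three end-to-end segmentation configurations
#'
#' \describe{
#'   \item{C1 (UNet)}{A 6-class patch-based UNet ensemble segments
#'     background and levels I-V directly via sliding-window inference;
#'     fused and post-processed.}
#'   \item{C2 (MV)}{A 6-class multi-view ensemble classifies every voxel
#'     inside the 15 mm expansion of the manual reference; fused and
#'     post-processed. Note the evaluation mask derives from the
#'     reference, as in the original protocol, which leaks reference
#'     extent information into the evaluation.}
#'   \item{C3 (UNet+MV)}{A binary UNet ensemble segments the combined
#'     I-V structure; the foreground is post-processed (hole fill,
#'     largest component) and then relabeled voxel-by-voxel into levels
#'     1-5 by a 5-class multi-view ensemble. The multi-view stage only
#'     relabels: the final foreground voxel set is exactly the
#'     post-processed UNet foreground.}
#' }
#'
#' @param config \code{"C1"}, \code{"C2"} or \code{"C3"}.
#' @param vol The \linkS4class{ScanVolume} to segment (raw HU).
#' @param unetEnsemble \linkS4class{ModelEnsemble} of UNets (C1: M = 6;
#'   C3: M = 2).
#' @param mvEnsemble \linkS4class{ModelEnsemble} of multi-view models
#'   (C2: M = 6; C3: M = 5).
#' @param refLabels Reference \linkS4class{LabelVolume}; required for C2's
#'   evaluation mask.
#' @param maskMarginMm C2 mask expansion margin (default 15).
#' @param window \code{\link{windowSetting}} for intensity normalization.
#' @param postprocess Apply combined-structure post-processing (default
#'   TRUE).
#' @return A \linkS4class{LabelVolume} with labels 0-5.
#' @export
runConfiguration <- function(config = c("C1", "C2", "C3"), vol,
                             unetEnsemble = NULL, mvEnsemble = NULL,
                             refLabels = NULL, maskMarginMm = 15,
                             window = windowSetting(), postprocess = TRUE) {
  config <- match.arg(config)
  nCls <- function(ens) as.integer(ens@members[[1]]@spec$nClasses)
  if (config == "C1") {
    stopifnot(!is.null(unetEnsemble))
    if (nCls(unetEnsemble) != 6L)
      stop("C1 expects a 6-class UNet ensemble")
    maps <- lapply(ensembleMembers(unetEnsemble), slidingWindowPredict,
                   vol = vol, window = window)
    lab <- ensembleFuse(maps)
    if (postprocess) lab <- postprocessCombined(lab)
    return(lab)
  }
  if (config == "C2") {
    stopifnot(!is.null(mvEnsemble), !is.null(refLabels))
    if (nCls(mvEnsemble) != 6L)
      stop("C2 expects a 6-class multi-view ensemble")
    mask <- expandMask(binarizeLabels(refLabels), maskMarginMm)
    maps <- lapply(ensembleMembers(mvEnsemble), classifyMaskedVoxels,
                   vol = vol, mask = mask, window = window)
    lab <- ensembleFuse(maps)
    if (postprocess) lab <- postprocessCombined(lab)
    return(lab)
  }
  # C3: binary UNet foreground, post-processed, then MV relabeling
  stopifnot(!is.null(unetEnsemble), !is.null(mvEnsemble))
  if (nCls(unetEnsemble) != 2L)
    stop("C3 expects a binary (M = 2) UNet ensemble")
  if (nCls(mvEnsemble) != 5L)
    stop("C3 expects a 5-class (foreground levels) multi-view ensemble")
  maps <- lapply(ensembleMembers(unetEnsemble), slidingWindowPredict,
                 vol = vol, window = window)
  fg <- ensembleFuse(maps)
  if (postprocess) fg <- postprocessCombined(fg)
  mask <- binarizeLabels(fg)
  if (!any(voxelData(mask) > 0L)) {
    warning("UNet stage produced empty foreground")
    return(labelVolume(array(0L, dim(voxelData(vol))), voxelSpacing(vol),
                       voxelOrigin(vol), nClasses = 6L))
  }
  maps2 <- lapply(ensembleMembers(mvEnsemble), classifyMaskedVoxels,
                  vol = vol, mask = mask, window = window, classes = 1:5)
  lab2 <- ensembleFuse(maps2)
  out <- voxelData(lab2)
  out[voxelData(mask) == 0L] <- 0L
  # inside the mask every voxel keeps a level label: foreground preserved
  labelVolume(out, voxelSpacing(vol), voxelOrigin(vol), nClasses = 6L)
}
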