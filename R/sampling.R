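# Unilateral regions of interest, truncated-Gaussian patch sampling and the
# stochastic augmentation policy used during training.

#' Unilateral region of interest
#'
#' A fixed-extent box (default 280 x 200 x 280 mm) placed on one lateral
#' side of a volume. The nominal box is clamped to the volume bounds; the
#' clamped interval is what constrains patch sampling.
#'
#' @param side \code{"left"} or \code{"right"}.
#' @param anchor Physical corner (minimum corner) of the nominal box in mm.
#' @param extent Box extent in mm per axis (default \code{c(280, 200, 280)}).
#' @return An \code{ROIBox} list with fields \code{side}, \code{anchor},
#'   \code{extent}.
#' @export
roiBox <- function(side = c("left", "right"), anchor, extent = c(280, 200, 280)) {
  side <- match.arg(side)
  structure(list(side = side, anchor = as.numeric(anchor),
                 extent = as.numeric(extent)), class = "ROIBox")
}

#' Default unilateral ROIs for a volume
#'
#' Centers one nominal ROI box on each lateral half of the volume.
#'
#' @param vol A \linkS4class{ScanVolume} or \linkS4class{LabelVolume}.
#' @param extent ROI extent in mm (default \code{c(280, 200, 280)}).
#' @return List of two \code{\link{roiBox}} (left, right).
#' @export
defaultROIs <- function(vol, extent = c(280, 200, 280)) {
  ext <- (dim(voxelData(vol)) - 1) * voxelSpacing(vol)
  org <- voxelOrigin(vol)
  ctr <- function(cx) org + c(cx, ext[2] / 2, ext[3] / 2) - extent / 2
  # half centers at 1/4 and 3/4 of the left-right extent
  list(left = roiBox("left", ctr(ext[1] / 4), extent),
       right = roiBox("right", ctr(3 * ext[1] / 4), extent))
}

# clamp an ROI to the physical bounds of a volume; returns lo/hi in mm
clampROI <- function(roi, vol) {
  org <- voxelOrigin(vol)
  hiV <- org + (dim(voxelData(vol)) - 1) * voxelSpacing(vol)
  lo <- pmax(roi$anchor, org)
  hi <- pmin(roi$anchor + roi$extent, hiV)
  if (any(hi <= lo)) stop("ROI does not intersect the volume")
  list(lo = lo, hi = hi)
}

#' Fit the Gaussian patch-center distribution from training label maps
#'
#' For every case, the center of mass of the combined (binarized) level I-V
#' structure inside the ROI is computed in physical mm; the sampler's mean
#' is the per-axis mean of these centers and its standard deviation the
#' per-axis population standard deviation (divide by N) across cases.
#'
#' @param labelmaps List of \linkS4class{LabelVolume}.
#' @param roi An \code{\link{roiBox}}.
#' @param patchSize Patch edge length in voxels (default 64).
#' @return A \code{GaussianPatchSampler} list with fields \code{mean},
#'   \code{sd} (mm), \code{roi}, \code{patchSize}.
#' @export
fitCenterDistribution <- function(labelmaps, roi, patchSize = 64L) {
  stopifnot(length(labelmaps) >= 1L)
  centers <- vapply(labelmaps, function(lab) {
    cl <- clampROI(roi, lab)
    d <- dim(voxelData(lab))
    org <- voxelOrigin(lab)
    sp <- voxelSpacing(lab)
    idx <- which(voxelData(lab) > 0L, arr.ind = TRUE)
    mm <- sweep(sweep(idx - 1, 2, sp, "*"), 2, org, "+")
    keep <- mm[, 1] >= cl$lo[1] & mm[, 1] <= cl$hi[1] &
      mm[, 2] >= cl$lo[2] & mm[, 2] <= cl$hi[2] &
      mm[, 3] >= cl$lo[3] & mm[, 3] <= cl$hi[3]
    if (!any(keep))
      stop("a label map has no foreground inside the ROI")
    colMeans(mm[keep, , drop = FALSE])
  }, numeric(3))
  mu <- rowMeans(centers)
  sdp <- sqrt(rowMeans((centers - mu)^2)) # population sd
  structure(list(mean = mu, sd = sdp, roi = roi,
                 patchSize = as.integer(patchSize)),
            class = "GaussianPatchSampler")
}

# inverse-CDF draw from a normal truncated to [a, b]
rtruncnorm1 <- function(mu, sd, a, b) {
  if (sd <= 0) return(min(max(mu, a), b))
  pa <- pnorm(a, mu, sd)
  pb <- pnorm(b, mu, sd)
  if (pb - pa < 1e-12) return(min(max(mu, a), b))
  qnorm(runif(1, pa, pb), mu, sd)
}

#' Sample one training patch from the truncated-Gaussian center law
#'
#' The patch center is drawn per axis from a normal distribution truncated
#' to the interval that keeps the whole patch inside the (volume-clamped)
#' ROI, via the inverse CDF, so the "entirely within the ROI" constraint
#' holds for every draw and the sampler always terminates. With sd = 0 the
#' patch is centered on the mean.
#'
#' @param sampler A \code{\link{fitCenterDistribution}} result.
#' @param vol The \linkS4class{ScanVolume} to crop from (raw HU).
#' @param lab The paired \linkS4class{LabelVolume}.
#' @param seed Optional seed for a deterministic draw.
#' @return A \code{PatchPair} list: \code{hu} (raw intensities, patch
#'   cube), \code{labels} (integer cube), \code{corner} (0-based voxel
#'   index of the patch corner).
#' @export
samplePatch <- function(sampler, vol, lab, seed = NULL) {
  stopifnot(inherits(sampler, "GaussianPatchSampler"))
  checkSameGeometry(vol, lab, "volume and labels")
  ps <- sampler$patchSize
  sp <- voxelSpacing(vol)
  org <- voxelOrigin(vol)
  d <- dim(voxelData(vol))
  cl <- clampROI(sampler$roi, vol)
  half <- ps / 2 * sp
  a <- cl$lo + half
  b <- cl$hi - half
  if (any(b < a))
    stop("ROI is smaller than the patch on at least one axis")
  # voxel-index bounds of the clamped ROI, so rounding cannot push the
  # patch outside it
  loVox <- pmax(ceiling((cl$lo - org) / sp - 1e-9), 0)
  hiVox <- pmin(floor((cl$hi - org) / sp + 1e-9), d - 1)
  draw <- function() {
    ctr <- vapply(1:3, function(i)
      rtruncnorm1(sampler$mean[i], sampler$sd[i], a[i], b[i]), numeric(1))
    cv <- round((ctr - org) / sp)
    corner <- pmin(pmax(cv - ps / 2, loVox), hiVox - ps + 1)
    corner <- pmin(pmax(corner, 0), d - ps)
    corner
  }
  corner <- if (is.null(seed)) draw() else withSeed(seed, draw())
  ix <- lapply(1:3, function(i) (corner[i] + 1):(corner[i] + ps))
  list(hu = voxelData(vol)[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       labels = voxelData(lab)[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       corner = corner, spacing = sp)
}

#' Stochastic augmentation policy
#'
#' On-the-fly augmentation: left-right flipping with probability 0.5,
#' in-plane rotation (sagittal or transversal plane, fair coin) with
#' probability 0.4 and an angle uniform on [-5, +5] degrees, and contrast
#' adaptation with probability 0.4 in which the intensity window's center
#' and width are drawn from normal distributions (sd 3 percent of the
#' default 700 HU width, i.e. 21 HU). The (possibly re-sampled) window is
#' applied after the geometric transforms, so augmented images are always
#' normalized to [0, 1].
#'
#' @param pFlip,pRotate,pContrast Event probabilities (defaults 0.5, 0.4,
#'   0.4).
#' @param angleRange Rotation angle range in degrees (default c(-5, 5)).
#' @param windowMuCenter,windowSdCenter,windowMuWidth,windowSdWidth
#'   Window-sampling parameters in HU (defaults 0, 21, 700, 21).
#' @return An \code{AugmentationPolicy} list.
#' @export
augmentationPolicy <- function(pFlip = 0.5, pRotate = 0.4, pContrast = 0.4,
                               angleRange = c(-5, 5),
                               windowMuCenter = 0, windowSdCenter = 21,
                               windowMuWidth = 700, windowSdWidth = 21) {
  stopifnot(all(c(pFlip, pRotate, pContrast) >= 0),
            all(c(pFlip, pRotate, pContrast) <= 1),
            isTRUE(all.equal(angleRange[1], -angleRange[2])))
  structure(list(pFlip = pFlip, pRotate = pRotate, pContrast = pContrast,
                 angleRange = angleRange,
                 windowMuCenter = windowMuCenter,
                 windowSdCenter = windowSdCenter,
                 windowMuWidth = windowMuWidth,
                 windowSdWidth = windowSdWidth),
            class = "AugmentationPolicy")
}

#' Draw the augmentation events for one patch
#'
#' Separated from the patch transform so event frequencies can be audited
#' cheaply and specific transforms forced in tests.
#'
#' @param policy An \code{\link{augmentationPolicy}}.
#' @param seed Optional seed.
#' @return List: \code{flip} (logical), \code{rotate} (logical),
#'   \code{plane} ("sagittal" or "transversal"), \code{angle} (degrees),
#'   \code{contrast} (logical), \code{center}, \code{width} (HU; the
#'   defaults when no contrast event fires).
#' @export
augmentationEvents <- function(policy = augmentationPolicy(), seed = NULL) {
  draw <- function() {
    flip <- runif(1) < policy$pFlip
    rotate <- runif(1) < policy$pRotate
    plane <- if (runif(1) < 0.5) "sagittal" else "transversal"
    angle <- runif(1, policy$angleRange[1], policy$angleRange[2])
    contrast <- runif(1) < policy$pContrast
    ctr <- rnorm(1, policy$windowMuCenter, policy$windowSdCenter)
    wid <- rnorm(1, policy$windowMuWidth, policy$windowSdWidth)
    list(flip = flip, rotate = rotate, plane = plane, angle = angle,
         contrast = contrast,
         center = if (contrast) ctr else policy$windowMuCenter,
         width = if (contrast) max(wid, 1) else policy$windowMuWidth)
  }
  if (is.null(seed)) draw() else withSeed(seed, draw())
}

#' Augment a training patch
#'
#' Applies (in order) left-right flipping, in-plane rotation (image by
#' 3rd-order spline on the raw HU, labels by nearest neighbour) and
#' intensity windowing with the event's window. The label set never grows
#' and the returned image is normalized to [0, 1].
#'
#' @param pair A \code{PatchPair} from \code{\link{samplePatch}} (raw HU in
#'   \code{$hu}).
#' @param policy An \code{\link{augmentationPolicy}}.
#' @param seed Optional seed for the event draw.
#' @param events Optional pre-drawn \code{\link{augmentationEvents}}
#'   overriding the random draw.
#' @return The pair with \code{image} (windowed, in [0, 1]), \code{labels},
#'   and the applied \code{events}.
#' @export
augmentPatch <- function(pair, policy = augmentationPolicy(), seed = NULL,
                         events = NULL) {
  if (is.null(events)) events <- augmentationEvents(policy, seed)
  hu <- pair$hu
  lb <- pair$labels
  if (events$flip) {
    hu <- hu[dim(hu)[1]:1, , , drop = FALSE]
    lb <- lb[dim(lb)[1]:1, , , drop = FALSE]
  }
  if (events$rotate && abs(events$angle) > 1e-12) {
    R <- if (events$plane == "sagittal") rotX(events$angle * pi / 180)
         else rotZ(events$angle * pi / 180)
    d <- dim(hu)
    A <- t(R) # isotropic patch: voxel units
    cvox <- (d - 1) / 2
    b <- as.numeric(cvox - A %*% cvox)
    hu <- .affine_sample(.bspline_prefilter(hu, d), d, A, b, d, 3L)
    lb <- .affine_sample(lb + 0, d, A, b, d, 0L)
  }
  img <- applyWindow(hu, windowSetting(events$center, events$width))
  list(image = img, labels = lb, corner = pair$corner,
       spacing = pair$spacing, events = events)
}
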