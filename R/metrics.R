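# Post-processing of segmentations, PTV derivation and spatial/volumetric
# agreement metrics.

#' Post-process a multi-class segmentation via its combined structure
#'
#' Operates on the binarized combined level I-V structure: fills interior
#' holes (3D: background regions not 6-connected to the grid border),
#' then keeps only the largest 26-connected component. Individual level
#' labels are retained where the combined mask survives; filled hole
#' voxels take the majority label of their 26-neighbourhood (ties toward
#' the lower level). Applying the operation twice equals applying it
#' once.
#'
#' @param lab A \linkS4class{LabelVolume} (labels 0-5 or binary).
#' @return A post-processed \linkS4class{LabelVolume}.
#' @export
postprocessCombined <- function(lab) {
  stopifnot(is(lab, "LabelVolume"))
  v <- voxelData(lab)
  fg <- v > 0L
  if (!any(fg)) {
    warning("empty foreground: returned unchanged")
    return(lab)
  }
  d <- dim(v)
  holes <- .find_holes(fg, d)
  filled <- fg | holes
  comp <- .label_components(filled, d, 26L)
  sizes <- tabulate(comp[comp > 0L])
  keep <- comp == which.max(sizes)
  out <- v
  out[!keep] <- 0L
  fillHere <- holes & keep
  if (any(fillHere))
    out <- .relabel_fill(out, fillHere, d, nClasses(lab) - 1L)
  labelVolume(out, voxelSpacing(lab), voxelOrigin(lab),
              nClasses = nClasses(lab))
}

#' Expand selected levels into a planning target volume (PTV)
#'
#' The union of the selected level labels is dilated by an exact
#' Euclidean margin in mm (default 4 mm, the clinical CTV-to-PTV setup
#' margin). The input union is always a subset of the output, and the
#' operation is monotone in both the margin and the level set.
#'
#' @param lab A \linkS4class{LabelVolume}.
#' @param levels Level labels to combine (default \code{1:5} for PI-PV;
#'   use \code{2:4} for PII-PIV).
#' @param marginMm Dilation margin in mm (default 4).
#' @return A binary \linkS4class{LabelVolume}.
#' @export
expandPTV <- function(lab, levels = 1:5, marginMm = 4) {
  stopifnot(is(lab, "LabelVolume"), length(levels) >= 1)
  if (any(!levels %in% seq_len(nClasses(lab) - 1L)))
    stop("unknown level label")
  m <- voxelData(lab) %in% levels
  dim(m) <- dim(voxelData(lab))
  if (!any(m))
    return(labelVolume(m + 0L, voxelSpacing(lab), voxelOrigin(lab), 2L))
  d2 <- .edt_sq(m, dim(m), voxelSpacing(lab))
  labelVolume((d2 <= marginMm^2 + 1e-9) + 0L, voxelSpacing(lab),
              voxelOrigin(lab), nClasses = 2L)
}

asMaskArray <- function(x) {
  if (is(x, "LabelVolume")) voxelData(x) > 0L else x > 0L
}

#' Dice similarity coefficient of two binary masks
#'
#' \code{2|A.B| / (|A| + |B|)}; 1 when both masks are empty, 0 when
#' exactly one is.
#'
#' @param a,b Binary masks (\linkS4class{LabelVolume} or arrays) on the
#'   same grid.
#' @return Scalar in [0, 1].
#' @export
dsc <- function(a, b) {
  A <- asMaskArray(a)
  B <- asMaskArray(b)
  if (!identical(dim(A), dim(B))) stop("masks must share geometry")
  sa <- sum(A)
  sb <- sum(B)
  if (sa + sb == 0) return(1)
  2 * sum(A & B) / (sa + sb)
}

# border voxels of a mask: foreground with >= 1 of its 6 face neighbours
# background, counting the grid border as exposure
surfaceVoxels <- function(m) {
  d <- dim(m)
  exposed <- array(FALSE, d)
  shift <- function(arr, ax, by) {
    out <- array(TRUE, d) # outside the grid counts as background
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- idx[[ax]] - by
    keep <- src[[ax]] >= 1 & src[[ax]] <= d[ax]
    tgt <- idx
    tgt[[ax]] <- idx[[ax]][keep]
    src[[ax]] <- src[[ax]][keep]
    out[tgt[[1]], tgt[[2]], tgt[[3]]] <- !m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3)
    for (by in c(-1L, 1L))
      exposed <- exposed | shift(m, ax, by)
  m & exposed
}

surfaceDistances <- function(A, B, spacing) {
  sa <- surfaceVoxels(A)
  sb <- surfaceVoxels(B)
  dB <- sqrt(.edt_sq(sb, dim(B), spacing))
  dA <- sqrt(.edt_sq(sa, dim(A), spacing))
  list(ab = dB[sa], ba = dA[sb])
}

#' Hausdorff distance between two binary masks (mm)
#'
#' The maximum of the two directed maxima of exact Euclidean
#' surface-to-surface distances, with surfaces taken as the 6-connectivity
#' exposed border voxels. \code{NA} if either mask is empty.
#'
#' @param a,b Binary masks on the same grid.
#' @param spacing Voxel spacing in mm (taken from \code{a} when it is a
#'   \linkS4class{LabelVolume}).
#' @param percentile Surface-distance percentile (default 100, the exact
#'   Hausdorff; 95 gives HD95).
#' @return Distance in mm.
#' @export
hausdorffDistance <- function(a, b, spacing = NULL, percentile = 100) {
  A <- asMaskArray(a)
  B <- asMaskArray(b)
  if (!identical(dim(A), dim(B))) stop("masks must share geometry")
  if (is.null(spacing))
    spacing <- if (is(a, "LabelVolume")) voxelSpacing(a) else rep(1, 3)
  if (!any(A) || !any(B)) return(NA_real_)
  sd <- surfaceDistances(A, B, spacing)
  if (percentile >= 100) max(max(sd$ab), max(sd$ba))
  else max(stats::quantile(sd$ab, percentile / 100, names = FALSE),
           stats::quantile(sd$ba, percentile / 100, names = FALSE))
}

#' Mean surface distance between two binary masks (mm)
#'
#' Symmetric: the mean of the two directed mean surface distances.
#' \code{NA} if either mask is empty.
#'
#' @inheritParams hausdorffDistance
#' @return Distance in mm.
#' @export
meanSurfaceDistance <- function(a, b, spacing = NULL) {
  A <- asMaskArray(a)
  B <- asMaskArray(b)
  if (!identical(dim(A), dim(B))) stop("masks must share geometry")
  if (is.null(spacing))
    spacing <- if (is(a, "LabelVolume")) voxelSpacing(a) else rep(1, 3)
  if (!any(A) || !any(B)) return(NA_real_)
  sd <- surfaceDistances(A, B, spacing)
  (mean(sd$ab) + mean(sd$ba)) / 2
}

#' Intraclass correlation, two-way mixed, single measurement, consistency
#'
#' ICC(3,1) from the two-way ANOVA decomposition with k = 2 raters:
#' \code{(MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)}. Invariant
#' to a fixed offset between the raters (consistency form). \code{NA}
#' with a warning for constant input.
#'
#' @param v1,v2 Paired per-case measurements (equal length >= 3).
#' @return The ICC estimate.
#' @export
iccConsistency <- function(v1, v2) {
  n <- length(v1)
  if (length(v2) != n) stop("v1 and v2 must have equal length")
  if (n < 3) stop("need at least 3 cases")
  x <- cbind(v1, v2)
  if (stats::var(as.vector(x)) == 0) {
    warning("constant measurements: ICC undefined")
    return(NA_real_)
  }
  k <- 2
  grand <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Predicted volume outside the reference contour (mL)
#'
#' \code{|pred \\ ref|} times the voxel volume, in mL.
#'
#' @param pred,ref Binary masks on the same grid.
#' @param spacing Voxel spacing in mm (from \code{pred} when it is a
#'   \linkS4class{LabelVolume}).
#' @return Volume in mL.
#' @export
volumeOutside <- function(pred, ref, spacing = NULL) {
  A <- asMaskArray(pred)
  B <- asMaskArray(ref)
  if (!identical(dim(A), dim(B))) stop("masks must share geometry")
  if (is.null(spacing))
    spacing <- if (is(pred, "LabelVolume")) voxelSpacing(pred) else rep(1, 3)
  sum(A & !B) * prod(spacing) / 1000
}

maskVolumeMl <- function(m, spacing) sum(m) * prod(spacing) / 1000

#' Per-structure evaluation report for one case
#'
#' Computes DSC, Hausdorff distance, mean surface distance, predicted and
#' reference volumes and the predicted volume outside the reference, for
#' the individual levels I-V, the combined I-V structure and the two PTVs
#' (PI-PV and PII-PIV, 4 mm margin).
#'
#' @param pred Predicted \linkS4class{LabelVolume} (labels 0-5).
#' @param ref Reference \linkS4class{LabelVolume}.
#' @param ptvMarginMm PTV margin in mm (default 4).
#' @return A data.frame with one row per structure.
#' @export
segmentationReport <- function(pred, ref, ptvMarginMm = 4) {
  checkSameGeometry(pred, ref, "prediction and reference")
  sp <- voxelSpacing(pred)
  structures <- list(
    I = function(l) voxelData(l) == 1L, II = function(l) voxelData(l) == 2L,
    III = function(l) voxelData(l) == 3L, IV = function(l) voxelData(l) == 4L,
    V = function(l) voxelData(l) == 5L,
    `I-V` = function(l) voxelData(l) > 0L)
  rows <- lapply(names(structures), function(nm) {
    A <- structures[[nm]](pred)
    B <- structures[[nm]](ref)
    data.frame(structure = nm, dsc = dsc(A, B),
               hd = hausdorffDistance(A, B, sp),
               msd = meanSurfaceDistance(A, B, sp),
               volPred = maskVolumeMl(A, sp), volRef = maskVolumeMl(B, sp),
               volOutside = volumeOutside(A, B, sp))
  })
  ptvs <- list(`PI-PV` = 1:5, `PII-PIV` = 2:4)
  rows <- c(rows, lapply(names(ptvs), function(nm) {
    A <- voxelData(expandPTV(pred, ptvs[[nm]], ptvMarginMm)) > 0L
    B <- voxelData(expandPTV(ref, ptvs[[nm]], ptvMarginMm)) > 0L
    data.frame(structure = nm, dsc = dsc(A, B),
               hd = hausdorffDistance(A, B, sp),
               msd = meanSurfaceDistance(A, B, sp),
               volPred = maskVolumeMl(A, sp), volRef = maskVolumeMl(B, sp),
               volOutside = volumeOutside(A, B, sp))
  }))
  do.call(rbind, rows)
}

#' Paired comparison of two models' per-case metrics
#'
#' Thin wrapper over the two-sided Wilcoxon signed-rank test with
#' Bonferroni adjustment across structures; an optional report column,
#' not part of the core evaluation.
#'
#' @param a,b Numeric matrices or data.frames of per-case metric values
#'   (cases x structures) for the two models.
#' @return A data.frame with raw and Bonferroni-adjusted p-values per
#'   column.
#' @export
compareModels <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(identical(dim(a), dim(b)))
  p <- vapply(seq_len(ncol(a)), function(j)
    stats::wilcox.test(a[, j], b[, j], paired = TRUE, exact = FALSE)$p.value,
    numeric(1))
  data.frame(structure = colnames(a) %||% as.character(seq_len(ncol(a))),
             p = p, pBonferroni = stats::p.adjust(p, "bonferroni"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
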