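#' Read a 3D volume from a NIfTI file
#'
#' Reads a \code{.nii} or \code{.nii.gz} file into a
#' \linkS4class{ScanVolume}. The voxel spacing is taken from the NIfTI
#' pixdim and the origin from the translation column of the stored xform.
#'
#' @param path Path to an existing 3D NIfTI file.
#' @return A \linkS4class{ScanVolume}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr)) # plain array, no niftiImage class
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in ", path)
  xf <- RNifti::xform(img)
  scanVolume(arr, spacing = as.numeric(sp), origin = as.numeric(xf[1:3, 4]))
}

#' Write a volume to a NIfTI file
#'
#' Spacing and origin are stored in the NIfTI pixdim and a diagonal
#' qform/sform so that \code{readVolume(writeVolume(v, f))} reproduces the
#' grid, spacing and origin within float tolerance.
#'
#' @param vol A \linkS4class{ScanVolume}.
#' @param path Output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ScanVolume"))
  writeNiftiArray(voxelData(vol), voxelSpacing(vol), voxelOrigin(vol),
                  path, datatype = "double")
  invisible(path)
}

#' Read a label map from a NIfTI file
#'
#' @param path Path to a 3D integer-valued NIfTI file (labels 0..M-1).
#' @param nClasses Total class count including background (default 6).
#' @return A \linkS4class{LabelVolume}.
#' @export
readLabelMap <- function(path, nClasses = 6L) {
  v <- readVolume(path)
  d <- voxelData(v)
  if (max(abs(d - round(d))) > 1e-6)
    stop("label file contains non-integer values: ", path)
  labelVolume(round(d), spacing = voxelSpacing(v), origin = voxelOrigin(v),
              nClasses = nClasses)
}

#' Write a label map to a NIfTI file
#'
#' Labels are written as unsigned 8-bit integers (levels 0-5 fit easily).
#'
#' @param lab A \linkS4class{LabelVolume}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeLabelMap <- function(lab, path) {
  stopifnot(is(lab, "LabelVolume"))
  writeNiftiArray(voxelData(lab), voxelSpacing(lab), voxelOrigin(lab),
                  path, datatype = "uint8")
  invisible(path)
}

writeNiftiArray <- function(arr, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  m <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  m <- structure(m, code = 2L)
  RNifti::qform(img) <- m
  RNifti::sform(img) <- m
  RNifti::writeNifti(img, path, datatype = datatype)
}

#' Resample a volume to isotropic spacing
#'
#' Intensities are interpolated with a 3rd-order (cubic B-spline)
#' interpolant: the volume is prefiltered into spline coefficients and
#' sampled on the new grid. Grids share the voxel-center origin, so the
#' physical extent is preserved within one voxel.
#'
#' @param vol A \linkS4class{ScanVolume}.
#' @param targetSpacing Target isotropic voxel size in mm (default 1.25).
#' @return A \linkS4class{ScanVolume} at the target spacing.
#' @export
resampleIsotropic <- function(vol, targetSpacing = 1.25) {
  stopifnot(is(vol, "ScanVolume"))
  if (targetSpacing <= 0) stop("targetSpacing must be > 0")
  sp <- voxelSpacing(vol)
  if (max(abs(sp - targetSpacing)) < 1e-9) return(vol)
  d <- dim(voxelData(vol))
  newDim <- pmax(1L, as.integer(round((d - 1L) * sp / targetSpacing)) + 1L)
  coef <- .bspline_prefilter(voxelData(vol), d)
  A <- diag(targetSpacing / sp)
  out <- .affine_sample(coef, d, A, c(0, 0, 0), newDim, 3L)
  scanVolume(out, spacing = rep(targetSpacing, 3), origin = voxelOrigin(vol))
}

#' Resample a label map to isotropic spacing
#'
#' Uses nearest-neighbour interpolation only, so the output label set is a
#' subset of the input label set.
#'
#' @param lab A \linkS4class{LabelVolume}.
#' @param targetSpacing Target isotropic voxel size in mm (default 1.25).
#' @return A \linkS4class{LabelVolume} at the target spacing.
#' @export
resampleLabels <- function(lab, targetSpacing = 1.25) {
  stopifnot(is(lab, "LabelVolume"))
  if (targetSpacing <= 0) stop("targetSpacing must be > 0")
  sp <- voxelSpacing(lab)
  if (max(abs(sp - targetSpacing)) < 1e-9) return(lab)
  d <- dim(voxelData(lab))
  newDim <- pmax(1L, as.integer(round((d - 1L) * sp / targetSpacing)) + 1L)
  A <- diag(targetSpacing / sp)
  out <- .affine_sample(voxelData(lab) + 0, d, A, c(0, 0, 0), newDim, 0L)
  labelVolume(out, spacing = rep(targetSpacing, 3),
              origin = voxelOrigin(lab), nClasses = nClasses(lab))
}

#' CT intensity window
#'
#' A display/normalization window over CT intensities defined by its center
#' and width in HU. The default 0 [700] covers the soft-tissue range in
#' which the lymph node levels live.
#'
#' @param center Window center C_C in HU (default 0).
#' @param width Window width C_W in HU (default 700, must be > 0).
#' @return A \code{WindowSetting} list with elements \code{center} and
#'   \code{width}.
#' @export
windowSetting <- function(center = 0, width = 700) {
  if (width <= 0) stop("window width must be > 0")
  structure(list(center = center, width = width), class = "WindowSetting")
}

#' Apply an intensity window, mapping HU to [0, 1]
#'
#' Linear clamp: intensities at or below \code{center - width/2} map to 0,
#' at or above \code{center + width/2} map to 1, linear in between. The
#' map is monotone non-decreasing in the input.
#'
#' @param vol A \linkS4class{ScanVolume} (HU-like intensities) or a bare
#'   numeric array.
#' @param w A \code{\link{windowSetting}}.
#' @return The same type as \code{vol} with intensities in [0, 1].
#' @export
applyWindow <- function(vol, w = windowSetting()) {
  if (w$width <= 0) stop("window width must be > 0")
  f <- function(x) {
    y <- pmin(1, pmax(0, (x - (w$center - w$width / 2)) / w$width))
    dim(y) <- dim(x)
    y
  }
  if (is(vol, "ScanVolume"))
    scanVolume(f(voxelData(vol)), voxelSpacing(vol), voxelOrigin(vol))
  else f(vol)
}
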