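#' @import methods
#' @importFrom stats rnorm runif qnorm pnorm sd
#' @importFrom utils head tail
#' @useDynLib lnlevelseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ScanVolume: a 3D intensity grid with physical geometry
#'
#' The basic image container: a 3D scalar array (CT-like intensities in
#' Hounsfield units, or normalized intensities after windowing) together
#' with per-axis voxel spacing and the physical position of voxel
#' \code{(0,0,0)}. The physical position of voxel \code{(i,j,k)}
#' (0-based) is \code{origin + c(i,j,k) * spacing}, all in mm.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing Numeric length-3, voxel size in mm per axis (all > 0).
#' @slot origin Numeric length-3, physical coordinate of voxel (0,0,0) in mm.
#' @export
setClass("ScanVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"))

setValidity("ScanVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be length 3 and strictly positive")
  if (length(object@origin) != 3L)
    return("origin must be length 3")
  if (!all(is.finite(object@data)))
    return("data must be finite everywhere")
  TRUE
})

#' LabelVolume: an integer label map aligned to a ScanVolume
#'
#' Voxel-wise class labels on the same grid as a paired
#' \linkS4class{ScanVolume}: 0 is background and 1-5 are the lymph node
#' levels I-V. \code{nClasses} counts all classes including background
#' (6 for the full level map, 2 for a binary foreground map).
#'
#' @slot data 3D integer-valued array of labels.
#' @slot spacing,origin Geometry, as in \linkS4class{ScanVolume}.
#' @slot nClasses Total number of classes M including background.
#' @export
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 nClasses = "integer"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be length 3 and strictly positive")
  if (length(object@nClasses) != 1L || object@nClasses < 2L)
    return("nClasses must be a single integer >= 2")
  v <- object@data
  if (any(v != round(v)))
    return("labels must be integer-valued")
  if (min(v) < 0 || max(v) > object@nClasses - 1L)
    return(sprintf("labels must lie in {0,...,%d}", object@nClasses - 1L))
  TRUE
})

#' ProbabilityMap: per-voxel class probabilities on a volume grid
#'
#' A 4D array (x, y, z, class) of per-voxel class-probability vectors
#' q(a, m), aligned to a \linkS4class{ScanVolume}. Every voxel's
#' probabilities are non-negative and sum to 1 (within 1e-5). This is the
#' substrate for summed-probability ensemble fusion.
#'
#' @slot data 4D numeric array, last dimension indexes the M classes.
#' @slot spacing,origin Geometry, as in \linkS4class{ScanVolume}.
#' @slot classes Integer vector naming the class label of each channel
#'   (e.g. \code{0:5}, or \code{1:5} for the foreground-only relabeling
#'   stage of the sequential configuration).
#' @export
setClass("ProbabilityMap",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 classes = "integer"))

setValidity("ProbabilityMap", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4D array (x, y, z, class)")
  if (d[4] != length(object@classes))
    return("4th dimension must match length(classes)")
  if (min(object@data) < -1e-8)
    return("probabilities must be non-negative")
  TRUE
})

#' TrainedModel: a network specification plus learned parameters
#'
#' @slot kind One of \code{"unet"}, \code{"mv"} or \code{"stub"}.
#' @slot spec The architecture spec list (\code{\link{unetSpec}} or
#'   \code{\link{mvSpec}}; for stubs, a list with the fixed probability
#'   vector).
#' @slot params Named list of parameter arrays (weights, biases, batch-norm
#'   statistics).
#' @slot bestMetric Validation score of the saved checkpoint (the highest
#'   validation Dice seen during training; \code{NA} for untrained models).
#' @export
setClass("TrainedModel",
  representation(kind = "character", spec = "list", params = "list",
                 bestMetric = "numeric"))

setValidity("TrainedModel", function(object) {
  if (!object@kind %in% c("unet", "mv", "stub"))
    return("kind must be 'unet', 'mv' or 'stub'")
  TRUE
})

#' ModelEnsemble: an ordered collection of models fused by summed probability
#'
#' All members share the architecture spec and class set; at inference the
#' per-class probabilities of the members are summed and the argmax decides
#' the final label.
#'
#' @slot members List of \linkS4class{TrainedModel}.
#' @export
setClass("ModelEnsemble", representation(members = "list"))

setValidity("ModelEnsemble", function(object) {
  if (length(object@members) < 1L)
    return("ensemble needs at least one member")
  if (!all(vapply(object@members, is, logical(1), class2 = "TrainedModel")))
    return("all members must be TrainedModel objects")
  k <- vapply(object@members, function(m) m@kind, character(1))
  if (length(unique(k)) != 1L)
    return("all members must share the same kind")
  TRUE
})

# ---- generics and accessors ------------------------------------------------

#' Accessors for volume-like objects
#'
#' \code{voxelData} returns the raw array, \code{voxelSpacing} the per-axis
#' voxel size in mm, \code{voxelOrigin} the physical position of voxel
#' (0,0,0) in mm, and \code{nClasses} the class count of a label map.
#'
#' @param x A \linkS4class{ScanVolume}, \linkS4class{LabelVolume} or
#'   \linkS4class{ProbabilityMap}.
#' @return The corresponding slot value.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelData
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname voxelData
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname voxelData
setMethod("voxelData", "ScanVolume", function(x) x@data)
#' @rdname voxelData
setMethod("voxelData", "LabelVolume", function(x) x@data)
#' @rdname voxelData
setMethod("voxelData", "ProbabilityMap", function(x) x@data)
#' @rdname voxelData
setMethod("voxelSpacing", "ScanVolume", function(x) x@spacing)
#' @rdname voxelData
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname voxelData
setMethod("voxelSpacing", "ProbabilityMap", function(x) x@spacing)
#' @rdname voxelData
setMethod("voxelOrigin", "ScanVolume", function(x) x@origin)
#' @rdname voxelData
setMethod("voxelOrigin", "LabelVolume", function(x) x@origin)
#' @rdname voxelData
setMethod("voxelOrigin", "ProbabilityMap", function(x) x@origin)
#' @rdname voxelData
setMethod("nClasses", "LabelVolume", function(x) x@nClasses)
#' @rdname voxelData
setMethod("nClasses", "ProbabilityMap", function(x) length(x@classes))

#' Ensemble accessors
#'
#' @param x A \linkS4class{ModelEnsemble}.
#' @return \code{ensembleMembers} returns the list of member models.
#' @export
setGeneric("ensembleMembers", function(x) standardGeneric("ensembleMembers"))

#' @rdname ensembleMembers
setMethod("ensembleMembers", "ModelEnsemble", function(x) x@members)

setMethod("show", "ScanVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ScanVolume %d x %d x %d, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x "),
              paste(format(object@origin), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  tab <- table(factor(object@data, levels = 0:(object@nClasses - 1L)))
  cat(sprintf("LabelVolume %d x %d x %d, %d classes, spacing %s mm\n",
              d[1], d[2], d[3], object@nClasses,
              paste(format(object@spacing), collapse = " x ")))
  cat("  voxels per class:", paste(sprintf("%s=%d", names(tab), tab),
                                   collapse = " "), "\n")
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProbabilityMap %d x %d x %d over classes {%s}\n",
              d[1], d[2], d[3], paste(object@classes, collapse = ",")))
})

setMethod("show", "TrainedModel", function(object) {
  np <- sum(vapply(object@params, length, numeric(1)))
  cat(sprintf("TrainedModel kind '%s', %d parameter arrays (%d values)%s\n",
              object@kind, length(object@params), np,
              if (length(object@bestMetric) && is.finite(object@bestMetric))
                sprintf(", best validation DSC %.3f", object@bestMetric)
              else ""))
})

setMethod("show", "ModelEnsemble", function(object) {
  cat(sprintf("ModelEnsemble of %d '%s' members\n",
              length(object@members), object@members[[1]]@kind))
})

# ---- constructors ----------------------------------------------------------

#' Construct a ScanVolume
#'
#' @param data 3D numeric array.
#' @param spacing Voxel size in mm per axis.
#' @param origin Physical position of voxel (0,0,0) in mm.
#' @return A \linkS4class{ScanVolume}.
#' @export
scanVolume <- function(data, spacing = c(1.25, 1.25, 1.25),
                       origin = c(0, 0, 0)) {
  new("ScanVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelVolume
#'
#' @param data 3D integer-valued array with values in \code{0:(nClasses-1)}.
#' @param spacing,origin Geometry (see \code{\link{scanVolume}}).
#' @param nClasses Total class count including background (default 6:
#'   background plus lymph node levels I-V).
#' @return A \linkS4class{LabelVolume}.
#' @export
labelVolume <- function(data, spacing = c(1.25, 1.25, 1.25),
                        origin = c(0, 0, 0), nClasses = 6L) {
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), nClasses = as.integer(nClasses))
}

#' Construct a ProbabilityMap
#'
#' @param data 4D numeric array (x, y, z, class).
#' @param spacing,origin Geometry (see \code{\link{scanVolume}}).
#' @param classes Integer class label of each channel.
#' @return A \linkS4class{ProbabilityMap}.
#' @export
probabilityMap <- function(data, spacing = c(1.25, 1.25, 1.25),
                           origin = c(0, 0, 0),
                           classes = 0:(dim(data)[4] - 1L)) {
  new("ProbabilityMap", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), classes = as.integer(classes))
}

#' Construct a model ensemble
#'
#' @param members List of \linkS4class{TrainedModel} sharing a spec.
#' @return A \linkS4class{ModelEnsemble}.
#' @export
modelEnsemble <- function(members) new("ModelEnsemble", members = members)

# internal geometry helper: stop unless two grids agree
checkSameGeometry <- function(a, b, what = "objects") {
  if (!identical(dim(voxelData(a))[1:3], dim(voxelData(b))[1:3]) ||
      max(abs(voxelSpacing(a) - voxelSpacing(b))) > 1e-6 ||
      max(abs(voxelOrigin(a) - voxelOrigin(b))) > 1e-3)
    stop(sprintf("%s must share grid shape, spacing and origin", what))
  invisible(TRUE)
}
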