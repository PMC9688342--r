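#' Save / load trained models and ensembles
#'
#' Checkpoints are plain RDS files holding the spec, parameters and best
#' validation metric.
#'
#' @param model A \linkS4class{TrainedModel} or \linkS4class{ModelEnsemble}.
#' @param path Output file path.
#' @return \code{path} (save) or the restored object (load).
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel") || is(model, "ModelEnsemble"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!(is(obj, "TrainedModel") || is(obj, "ModelEnsemble")))
    stop("not a model checkpoint: ", path)
  obj
}
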