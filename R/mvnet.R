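# 2.5D multi-view multi-scale voxel classifier: view extraction around a
# query voxel and the branched 2D-convolutional network.

#' Multi-view network specification
#'
#' The classifier sees, for each query voxel, three orthogonal 2D views
#' (axial, sagittal, coronal) at each of three context pyramid scales.
#' Scale s samples every 2^s-th voxel in-plane, so with 32 in-plane
#' samples at 1.25 mm spacing the fields of view span 4, 8 and 16 cm.
#' Each of the nine view patches is processed by its own stack of 3x3 2D
#' convolutions (batch normalization before every activation, 2x
#' max-pooling between layers); the scale outputs are concatenated and
#' fused by a dense layer feeding the M-class softmax head. M is 6 for
#' the standalone configuration and 5 (foreground levels only) for the
#' sequential configuration.
#'
#' @param nScales Number of pyramid scales (default 3).
#' @param inPlaneSamples In-plane samples per view axis (default 32).
#' @param strides Voxel stride per scale (default \code{c(1, 2, 4)}).
#' @param viewFilters Filters of the per-view convolution stack
#'   (default \code{c(16, 32, 64)}).
#' @param denseUnits Units of the fusion dense layer (default 128).
#' @param nClasses Output classes M (default 6).
#' @param dropout Dropout fraction on the fusion layer during training
#'   (default 0.1).
#' @return An \code{MVSpec} list.
#' @export
mvSpec <- function(nScales = 3L, inPlaneSamples = 32L, strides = c(1L, 2L, 4L),
                   viewFilters = c(16L, 32L, 64L), denseUnits = 128L,
                   nClasses = 6L, dropout = 0.1) {
  if (length(strides) != nScales) stop("need one stride per scale")
  if (inPlaneSamples %% 2L^length(viewFilters) != 0L)
    stop("inPlaneSamples must be divisible by 2^(number of conv layers)")
  structure(list(nScales = as.integer(nScales),
                 inPlaneSamples = as.integer(inPlaneSamples),
                 strides = as.integer(strides),
                 viewFilters = as.integer(viewFilters),
                 denseUnits = as.integer(denseUnits),
                 nClasses = as.integer(nClasses), dropout = dropout),
            class = "MVSpec")
}

#' Physical field of view per pyramid scale
#'
#' @param spec An \code{\link{mvSpec}}.
#' @param spacing Isotropic voxel spacing in mm (default 1.25).
#' @return Numeric vector of in-plane spans in mm, one per scale
#'   (\code{inPlaneSamples * stride * spacing}).
#' @export
fieldOfView <- function(spec, spacing = 1.25) {
  spec$inPlaneSamples * spec$strides * spacing
}

#' Extract the multi-view, multi-scale patches around query voxels
#'
#' For each query voxel, returns the three orthogonal in-plane views at
#' each scale, sampling every \code{stride}-th voxel centered on the
#' voxel; samples outside the volume replicate the nearest edge voxel.
#' View order is axial (x, y), sagittal (y, z), coronal (x, z).
#'
#' @param vol A \linkS4class{ScanVolume} (typically windowed) or 3D array.
#' @param voxel A 0-based voxel index triple, or an n x 3 matrix of them.
#' @param spec An \code{\link{mvSpec}}.
#' @return Array of dim \code{c(inPlane, inPlane, 3, nScales, n)} (last
#'   dimension dropped for a single voxel): a ViewSet per query voxel.
#' @export
extractViews <- function(vol, voxel, spec = mvSpec()) {
  arr <- if (is(vol, "ScanVolume")) voxelData(vol) else vol
  single <- is.null(dim(voxel))
  vox <- if (single) matrix(as.integer(voxel), 1L) else {
    storage.mode(voxel) <- "integer"
    voxel
  }
  d <- dim(arr)
  if (any(vox < 0L) || any(sweep(vox, 2, d, ">=")))
    stop("query voxel outside the volume")
  out <- .extract_views_batch(arr, d, vox, spec$inPlaneSamples, spec$strides)
  if (single) {
    dm <- dim(out)
    dim(out) <- dm[1:4]
  }
  out
}

#' Build an (untrained) multi-view classifier
#'
#' @param spec An \code{\link{mvSpec}}.
#' @param seed Optional RNG seed for reproducible Glorot initialization.
#' @return A \linkS4class{TrainedModel} of kind \code{"mv"}.
#' @export
buildMV <- function(spec = mvSpec(), seed = NULL) {
  stopifnot(inherits(spec, "MVSpec"))
  build <- function() {
    p <- list()
    nf <- spec$viewFilters
    for (s in seq_len(spec$nScales))
      for (v in 1:3) {
        br <- list()
        cin <- 1L
        for (l in seq_along(nf)) {
          br[[paste0("conv", l)]] <- initConv(cin, nf[l], k = c(3L, 3L, 1L))
          br[[paste0("bn", l)]] <- initBN(nf[l])
          cin <- nf[l]
        }
        p[[branchName(s, v)]] <- br
      }
    featPerBranch <- (spec$inPlaneSamples / 2L^length(nf))^2 * nf[length(nf)]
    featTotal <- 3L * spec$nScales * featPerBranch
    p$dense1 <- list(
      W = glorotUniform(featTotal, spec$denseUnits, featTotal,
                        spec$denseUnits),
      b = numeric(spec$denseUnits))
    p$dense1bn <- initBN(spec$denseUnits)
    p$dense2 <- list(
      W = glorotUniform(spec$denseUnits, spec$nClasses, spec$denseUnits,
                        spec$nClasses),
      b = numeric(spec$nClasses))
    p
  }
  params <- if (is.null(seed)) build() else withSeed(seed, build())
  new("TrainedModel", kind = "mv", spec = unclass(spec), params = params,
      bestMetric = NA_real_)
}

branchName <- function(s, v) paste0("s", s, "v", c("ax", "sag", "cor")[v])

# batch norm over the rows of an (N, C) matrix
bnDenseFwd <- function(x, p, training, momentum = 0.9, eps = 1e-3) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    var <- colMeans(xc^2)
    p$rmean <- momentum * p$rmean + (1 - momentum) * mu
    p$rvar <- momentum * p$rvar + (1 - momentum) * var
  } else {
    mu <- p$rmean
    var <- p$rvar
    xc <- sweep(x, 2, mu)
  }
  invstd <- 1 / sqrt(var + eps)
  xhat <- sweep(xc, 2, invstd, "*")
  out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  list(out = out, xhat = xhat, invstd = invstd, p = p)
}

bnDenseBwd <- function(cache, p, gout) {
  m <- nrow(gout)
  xhat <- cache$xhat
  dgamma <- colSums(gout * xhat)
  dbeta <- colSums(gout)
  dxhat <- sweep(gout, 2, p$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  gx <- sweep(dxhat - outer(rep(1, m), s1 / m) - sweep(xhat, 2, s2 / m, "*"),
              2, cache$invstd, "*")
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}

# forward for a batch of ViewSets: views (ip, ip, 3, S, N)
mvForward <- function(params, views, spec, training = FALSE) {
  ip <- spec$inPlaneSamples
  S <- spec$nScales
  N <- dim(views)[5]
  nf <- spec$viewFilters
  L <- length(nf)
  feats <- list()
  cache <- list(branches = list())
  for (s in seq_len(S))
    for (v in 1:3) {
      nm <- branchName(s, v)
      pp <- params[[nm]]
      x <- array(views[, , v, s, ], c(ip, ip, 1L, 1L, N))
      bc <- list(x0 = x)
      for (l in seq_len(L)) {
        z <- convFwd(x, pp[[paste0("conv", l)]])
        bn <- bnFwd(z, pp[[paste0("bn", l)]], training)
        pp[[paste0("bn", l)]] <- bn$p
        r <- reluFwd(bn$out)
        mp <- .maxpool_fwd(r, dim(r), c(2L, 2L, 1L))
        bc[[paste0("bn", l)]] <- bn
        bc[[paste0("r", l)]] <- r
        bc[[paste0("mp", l)]] <- mp
        x <- mp$out
      }
      params[[nm]] <- pp
      bc$outdim <- dim(x)
      cache$branches[[nm]] <- bc
      feats[[nm]] <- t(matrix(x, ncol = N)) # N x feat
    }
  feat <- do.call(cbind, feats)
  z1 <- feat %*% params$dense1$W +
    matrix(params$dense1$b, nrow(feat), length(params$dense1$b), byrow = TRUE)
  b1 <- bnDenseFwd(z1, params$dense1bn, training)
  params$dense1bn <- b1$p
  r1 <- reluFwd(b1$out)
  if (training && spec$dropout > 0) {
    dmask <- matrix(runif(length(r1)) >= spec$dropout, nrow(r1)) /
      (1 - spec$dropout)
    cache$drop <- dmask
    r1 <- r1 * dmask
  }
  z2 <- r1 %*% params$dense2$W +
    matrix(params$dense2$b, nrow(r1), length(params$dense2$b), byrow = TRUE)
  mx <- apply(z2, 1, max)
  e <- exp(z2 - mx)
  probs <- e / rowSums(e)
  cache$feat <- feat
  cache$b1 <- b1
  cache$r1 <- r1
  cache$probs <- probs
  list(probs = probs, cache = cache, params = params)
}

# backward from gradient wrt logits of the softmax head (for CCE with
# softmax this is (q - p) / N directly)
mvBackward <- function(params, spec, cache, glogits) {
  grads <- list()
  grads$dense2 <- list(W = t(cache$r1) %*% glogits, b = colSums(glogits))
  gr1 <- glogits %*% t(params$dense2$W)
  if (!is.null(cache$drop)) gr1 <- gr1 * cache$drop
  gb1 <- reluBwd(cache$b1$out, gr1)
  bb1 <- bnDenseBwd(cache$b1, params$dense1bn, gb1)
  grads$dense1bn <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  grads$dense1 <- list(W = t(cache$feat) %*% bb1$gx, b = colSums(bb1$gx))
  gfeat <- bb1$gx %*% t(params$dense1$W)
  # split feature gradient back into branches
  S <- spec$nScales
  nf <- spec$viewFilters
  L <- length(nf)
  featPerBranch <- (spec$inPlaneSamples / 2L^L)^2 * nf[L]
  off <- 0L
  for (s in seq_len(S))
    for (v in 1:3) {
      nm <- branchName(s, v)
      bc <- cache$branches[[nm]]
      pp <- params[[nm]]
      gcols <- gfeat[, off + seq_len(featPerBranch), drop = FALSE]
      off <- off + featPerBranch
      gx <- array(t(gcols), bc$outdim)
      bg <- list()
      for (l in rev(seq_len(L))) {
        mp <- bc[[paste0("mp", l)]]
        r <- bc[[paste0("r", l)]]
        gx <- .maxpool_bwd(gx, mp$argmax, dim(r))
        gx <- reluBwd(r, gx)
        bb <- bnBwd(bc[[paste0("bn", l)]], pp[[paste0("bn", l)]], gx)
        xin <- if (l == 1L) bc$x0 else bc[[paste0("mp", l - 1L)]]$out
        cb <- convBwd(xin, pp[[paste0("conv", l)]], bb$gx)
        bg[[paste0("bn", l)]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
        bg[[paste0("conv", l)]] <- list(W = cb$gW, b = cb$gb)
        gx <- cb$gx
      }
      grads[[nm]] <- bg
    }
  grads
}

#' Classify a batch of ViewSets
#'
#' Runs the multi-view network in inference mode and returns one
#' probability vector per query voxel, order-preserving.
#'
#' @param model A \linkS4class{TrainedModel} of kind \code{"mv"} or
#'   \code{"stub"}.
#' @param views A ViewSet array from \code{\link{extractViews}} (4D for a
#'   single voxel, 5D for a batch).
#' @return An N x M matrix of class probabilities (rows sum to 1).
#' @export
predictViews <- function(model, views) {
  if (length(dim(views)) == 4L) dim(views) <- c(dim(views), 1L)
  N <- dim(views)[5]
  if (model@kind == "stub") {
    pv <- model@spec$probs
    return(matrix(pv, N, length(pv), byrow = TRUE))
  }
  if (model@kind != "mv") stop("predictViews expects an mv or stub model")
  mvForward(model@params, views, model@spec, training = FALSE)$probs
}
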