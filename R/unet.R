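# Residual patch-based 3D UNet: declarative spec, seeded construction and
# the forward/backward passes used by the trainer.

#' UNet architecture specification
#'
#' A residual 3D UNet operating on cubic patches: an encoder of residual
#' blocks (two 3x3x3 convolutions each, batch normalization before every
#' activation, identity shortcut with a 1x1x1 projection where channel
#' counts change), 2x max-pooling between levels, a nearest-neighbour
#' upsampling decoder with skip concatenation, and a softmax head with M
#' output classes per voxel. M is 6 for the direct multi-class
#' configuration and 2 for the foreground stage of the sequential
#' configuration.
#'
#' @param patchSize Cubic patch edge in voxels (default 64); must be
#'   divisible by \code{2^(depth-1)}.
#' @param depth Number of encoder levels (default 4).
#' @param baseFilters Filters at the first level, doubling per level
#'   (default 16).
#' @param nClasses Output classes M including background (default 6).
#' @param dropout Dropout fraction on the bottleneck during training
#'   (default 0.1; switched off at inference).
#' @return A \code{UNetSpec} list.
#' @export
unetSpec <- function(patchSize = 64L, depth = 4L, baseFilters = 16L,
                     nClasses = 6L, dropout = 0.1) {
  patchSize <- as.integer(patchSize)
  depth <- as.integer(depth)
  if (patchSize %% 2L^(depth - 1L) != 0L)
    stop("patchSize must be divisible by 2^(depth-1)")
  if (nClasses < 2L) stop("nClasses must be >= 2")
  structure(list(patchSize = patchSize, depth = depth,
                 baseFilters = as.integer(baseFilters),
                 nClasses = as.integer(nClasses), dropout = dropout,
                 kernel = c(3L, 3L, 3L)),
            class = "UNetSpec")
}

#' Build an (untrained) residual 3D UNet
#'
#' Parameters are initialized with Glorot-uniform draws from R's RNG, so
#' two builds under the same seed are identical.
#'
#' @param spec A \code{\link{unetSpec}}.
#' @param seed Optional RNG seed for reproducible initialization.
#' @return A \linkS4class{TrainedModel} of kind \code{"unet"} (untrained).
#' @export
buildUNet <- function(spec = unetSpec(), seed = NULL) {
  stopifnot(inherits(spec, "UNetSpec"))
  build <- function() {
    F0 <- spec$baseFilters
    D <- spec$depth
    p <- list()
    p$stem <- list(conv = initConv(1L, F0), bn = initBN(F0))
    for (d in seq_len(D)) {
      fin <- if (d == 1L) F0 else F0 * 2L^(d - 2L)
      fout <- F0 * 2L^(d - 1L)
      blk <- list(conv1 = initConv(fin, fout), bn1 = initBN(fout),
                  conv2 = initConv(fout, fout), bn2 = initBN(fout))
      if (fin != fout) {
        blk$proj <- initConv(fin, fout, k = c(1L, 1L, 1L))
        blk$projbn <- initBN(fout)
      }
      p[[paste0("enc", d)]] <- blk
    }
    for (d in rev(seq_len(D - 1L))) {
      fskip <- F0 * 2L^(d - 1L)
      fin <- F0 * 2L^d + fskip # upsampled + skip
      p[[paste0("dec", d)]] <- list(
        fuse = initConv(fin, fskip, k = c(1L, 1L, 1L)),
        fusebn = initBN(fskip),
        conv = initConv(fskip, fskip), bn = initBN(fskip))
    }
    p$head <- initConv(F0, spec$nClasses, k = c(1L, 1L, 1L))
    p
  }
  params <- if (is.null(seed)) build() else withSeed(seed, build())
  new("TrainedModel", kind = "unet", spec = unclass(spec), params = params,
      bestMetric = NA_real_)
}

resBlockFwd <- function(x, pp, training) {
  hasProj <- !is.null(pp$proj)
  if (hasProj) {
    scz <- convFwd(x, pp$proj)
    scb <- bnFwd(scz, pp$projbn, training)
    pp$projbn <- scb$p
    sc <- scb$out
  } else {
    scb <- NULL
    sc <- x
  }
  z1 <- convFwd(x, pp$conv1)
  b1 <- bnFwd(z1, pp$bn1, training)
  pp$bn1 <- b1$p
  r1 <- reluFwd(b1$out)
  z2 <- convFwd(r1, pp$conv2)
  b2 <- bnFwd(z2, pp$bn2, training)
  pp$bn2 <- b2$p
  out <- reluFwd(b2$out + sc)
  list(out = out, x = x, b1 = b1, r1 = r1, b2 = b2, scb = scb, pp = pp)
}

resBlockBwd <- function(cache, pp, gout) {
  gs <- reluBwd(cache$out, gout)
  bb2 <- bnBwd(cache$b2, pp$bn2, gs)
  cb2 <- convBwd(cache$r1, pp$conv2, bb2$gx)
  gr1 <- reluBwd(cache$r1, cb2$gx)
  bb1 <- bnBwd(cache$b1, pp$bn1, gr1)
  cb1 <- convBwd(cache$x, pp$conv1, bb1$gx)
  gx <- cb1$gx
  grads <- list(conv1 = list(W = cb1$gW, b = cb1$gb),
                bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
                conv2 = list(W = cb2$gW, b = cb2$gb),
                bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta))
  if (!is.null(pp$proj)) {
    bbp <- bnBwd(cache$scb, pp$projbn, gs)
    cbp <- convBwd(cache$x, pp$proj, bbp$gx)
    gx <- gx + cbp$gx
    grads$proj <- list(W = cbp$gW, b = cbp$gb)
    grads$projbn <- list(gamma = bbp$dgamma, beta = bbp$dbeta)
  } else {
    gx <- gx + gs
  }
  list(gx = gx, grads = grads)
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

# forward pass; x is (P,P,P,1,N). Returns probs plus caches for backward and
# (possibly updated) params when training.
unetForward <- function(params, x, spec, training = FALSE) {
  D <- spec$depth
  cache <- list()
  z <- convFwd(x, params$stem$conv)
  bs <- bnFwd(z, params$stem$bn, training)
  params$stem$bn <- bs$p
  a <- reluFwd(bs$out)
  cache$stem <- list(x = x, bn = bs, a = a)
  e <- vector("list", D)
  for (d in seq_len(D)) {
    inp <- if (d == 1L) a else {
      mp <- .maxpool_fwd(e[[d - 1L]]$out, dim(e[[d - 1L]]$out), c(2L, 2L, 2L))
      cache[[paste0("pool", d)]] <- mp
      mp$out
    }
    e[[d]] <- resBlockFwd(inp, params[[paste0("enc", d)]], training)
    params[[paste0("enc", d)]] <- e[[d]]$pp
  }
  u <- e[[D]]$out
  if (training && spec$dropout > 0) {
    dr <- dropoutFwd(u, spec$dropout)
    cache$drop <- dr$mask
    u <- dr$out
  }
  for (d in rev(seq_len(D - 1L))) {
    up <- .upsample_fwd(u, dim(u))
    ct <- catChannels(up, e[[d]]$out)
    pp <- params[[paste0("dec", d)]]
    z1 <- convFwd(ct, pp$fuse)
    f1 <- bnFwd(z1, pp$fusebn, training)
    pp$fusebn <- f1$p
    r1 <- reluFwd(f1$out)
    z2 <- convFwd(r1, pp$conv)
    f2 <- bnFwd(z2, pp$bn, training)
    pp$bn <- f2$p
    r2 <- reluFwd(f2$out)
    params[[paste0("dec", d)]] <- pp
    cache[[paste0("dec", d)]] <- list(uin = u, updim = dim(u), ct = ct,
                                      f1 = f1, r1 = r1, f2 = f2, r2 = r2)
    u <- r2
  }
  logits <- convFwd(u, params$head)
  probs <- softmaxCh(logits)
  cache$encs <- e
  cache$headin <- u
  cache$probs <- probs
  list(probs = probs, cache = cache, params = params)
}

# backward from a gradient wrt the softmax probabilities
unetBackward <- function(params, spec, cache, gprobs) {
  D <- spec$depth
  grads <- list()
  gz <- softmaxBwd(cache$probs, gprobs)
  ch <- convBwd(cache$headin, params$head, gz)
  grads$head <- list(W = ch$gW, b = ch$gb)
  gu <- ch$gx
  for (d in seq_len(D - 1L)) { # decoder levels, shallowest first
    cc <- cache[[paste0("dec", d)]]
    pp <- params[[paste0("dec", d)]]
    g2 <- reluBwd(cc$r2, gu)
    bb2 <- bnBwd(cc$f2, pp$bn, g2)
    cb2 <- convBwd(cc$r1, pp$conv, bb2$gx)
    g1 <- reluBwd(cc$r1, cb2$gx)
    bb1 <- bnBwd(cc$f1, pp$fusebn, g1)
    cb1 <- convBwd(cc$ct, pp$fuse, bb1$gx)
    grads[[paste0("dec", d)]] <- list(
      fuse = list(W = cb1$gW, b = cb1$gb),
      fusebn = list(gamma = bb1$dgamma, beta = bb1$dbeta),
      conv = list(W = cb2$gW, b = cb2$gb),
      bn = list(gamma = bb2$dgamma, beta = bb2$dbeta))
    gct <- cb1$gx
    nup <- cc$updim[4]
    gup <- gct[, , , seq_len(nup), , drop = FALSE]
    gskip <- gct[, , , nup + seq_len(dim(gct)[4] - nup), , drop = FALSE]
    # gradient into the deeper path and into this level's encoder skip
    gu <- list(deeper = .upsample_bwd(gup, cc$updim), skip = gskip)
    # stash skip grad; continue with deeper grad
    cache[[paste0("gskip", d)]] <- gu$skip
    gu <- gu$deeper
  }
  if (!is.null(cache$drop)) gu <- dropoutBwd(cache$drop, gu)
  # encoder, deepest first; add skip grads accumulated by the decoder
  for (d in rev(seq_len(D))) {
    if (d < D) {
      gsk <- cache[[paste0("gskip", d)]]
      gu <- gu + gsk
    }
    rb <- resBlockBwd(cache$encs[[d]], params[[paste0("enc", d)]], gu)
    grads[[paste0("enc", d)]] <- rb$grads
    if (d > 1L) {
      mp <- cache[[paste0("pool", d)]]
      gu <- .maxpool_bwd(rb$gx, mp$argmax, dim(cache$encs[[d - 1L]]$out))
    } else {
      gu <- rb$gx
    }
  }
  gs <- reluBwd(cache$stem$a, gu)
  bbs <- bnBwd(cache$stem$bn, params$stem$bn, gs)
  cbs <- convBwd(cache$stem$x, params$stem$conv, bbs$gx, needGx = FALSE)
  grads$stem <- list(conv = list(W = cbs$gW, b = cbs$gb),
                     bn = list(gamma = bbs$dgamma, beta = bbs$dbeta))
  grads
}

#' Predict class probabilities for a batch of patches
#'
#' Runs the network in inference mode (batch-norm running statistics,
#' dropout off). Accepts a single patch (3D array) or a batch
#' (4D array with the last dimension indexing patches).
#'
#' @param model A \linkS4class{TrainedModel} of kind \code{"unet"} or
#'   \code{"stub"}.
#' @param patch Normalized intensity patch(es) in [0, 1].
#' @return A (P, P, P, M, N) probability array (N dropped for a single
#'   patch input: (P, P, P, M)).
#' @export
predictPatch <- function(model, patch) {
  single <- length(dim(patch)) == 3L
  if (single) dim(patch) <- c(dim(patch), 1L)
  d4 <- dim(patch)
  x <- array(patch, c(d4[1:3], 1L, d4[4]))
  if (model@kind == "stub") {
    pv <- model@spec$probs
    M <- length(pv)
    out <- array(rep(pv, each = prod(d4[1:3])), c(d4[1:3], M, d4[4]))
  } else if (model@kind == "unet") {
    out <- unetForward(model@params, x, model@spec, training = FALSE)$probs
  } else {
    stop("predictPatch expects a unet or stub model")
  }
  if (single) {
    dm <- dim(out)
    dim(out) <- dm[1:4]
  }
  out
}

#' Constant-output stub model (testing utility)
#'
#' A degenerate model that predicts the same probability vector at every
#' voxel; handy for exercising inference plumbing (sliding-window
#' coverage, fusion, configuration wiring) independently of training.
#'
#' @param probs Probability vector over classes (will be normalized).
#' @param patchSize Patch size the stub pretends to use (default 64).
#' @return A \linkS4class{TrainedModel} of kind \code{"stub"}.
#' @export
stubModel <- function(probs, patchSize = 64L) {
  probs <- probs / sum(probs)
  new("TrainedModel", kind = "stub",
      spec = list(probs = probs, patchSize = as.integer(patchSize),
                  nClasses = length(probs)),
      params = list(), bestMetric = NA_real_)
}
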