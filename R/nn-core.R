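# Minimal convolutional network engine: forward/backward primitives over
# activations laid out as (X, Y, Z, C, N) arrays, Glorot initialization and
# an Adam optimizer. 2D layers reuse the 3D primitives with Z = 1.
# Internal; the public surface is unetSpec()/buildUNet()/mvSpec()/buildMV().

glorotUniform <- function(fanIn, fanOut, nrow, ncol) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# conv parameters: W is a (kx*ky*kz*Cin) x Cout matrix, b length Cout
initConv <- function(cin, cout, k = c(3L, 3L, 3L)) {
  kk <- prod(k)
  list(W = glorotUniform(kk * cin, kk * cout, kk * cin, cout),
       b = numeric(cout), k = as.integer(k))
}

initBN <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c))
}

convFwd <- function(x, p) {
  .conv_fwd(x, dim(x), p$W, p$b, p$k)
}

convBwd <- function(x, p, gout, needGx = TRUE) {
  .conv_bwd(x, dim(x), p$W, p$k, gout, needGx)
}

# batch norm over (X,Y,Z,N) per channel; training = use batch stats and
# update running stats, inference = use running stats
bnFwd <- function(x, p, training, momentum = 0.9, eps = 1e-3) {
  r <- .bn_fwd(x, dim(x), p$gamma, p$beta, p$rmean, p$rvar, training,
               momentum, eps)
  if (training) {
    p$rmean <- r$rmean
    p$rvar <- r$rvar
  }
  list(out = r$out, x = x, mu = r$mu, var = r$var, eps = eps, p = p)
}

bnBwd <- function(cache, p, gout) {
  r <- .bn_bwd(cache$x, dim(cache$x), p$gamma, cache$mu, cache$var,
               cache$eps, gout)
  list(gx = r$gx, dgamma = r$dgamma, dbeta = r$dbeta)
}

reluFwd <- function(x) .relu_fwd(x)

reluBwd <- function(out, gout) .relu_bwd(out, gout)

# softmax over the channel dimension of a (X,Y,Z,C,N) array
softmaxCh <- function(x) {
  d <- dim(x)
  V <- prod(d[1:3]); C <- d[4]; N <- d[5]
  dim(x) <- c(V, C, N)
  sl <- function(a, c) matrix(a[, c, ], V, N)
  mx <- sl(x, 1)
  if (C > 1) for (c in 2:C) mx <- pmax(mx, sl(x, c))
  e <- array(0, c(V, C, N))
  for (c in seq_len(C)) e[, c, ] <- exp(sl(x, c) - mx)
  s <- sl(e, 1)
  if (C > 1) for (c in 2:C) s <- s + sl(e, c)
  for (c in seq_len(C)) e[, c, ] <- sl(e, c) / s
  dim(e) <- d
  e
}

# gradient through softmax given grad wrt probabilities:
# dz_c = p_c * (g_c - sum_k g_k p_k)
softmaxBwd <- function(probs, gprobs) {
  d <- dim(probs)
  V <- prod(d[1:3]); C <- d[4]; N <- d[5]
  dim(probs) <- c(V, C, N)
  dim(gprobs) <- c(V, C, N)
  sl <- function(a, c) matrix(a[, c, ], V, N)
  dot <- sl(probs, 1) * sl(gprobs, 1)
  if (C > 1) for (c in 2:C) dot <- dot + sl(probs, c) * sl(gprobs, c)
  gz <- array(0, c(V, C, N))
  for (c in seq_len(C)) gz[, c, ] <- sl(probs, c) * (sl(gprobs, c) - dot)
  dim(gz) <- d
  gz
}

# spatial (channel-wise) dropout: drops whole channels per sample, the
# usual choice for convolutional feature maps; scale-preserving
dropoutFwd <- function(x, pdrop) {
  if (pdrop <= 0) return(list(out = x, mask = NULL))
  d <- dim(x)
  cm <- (runif(d[4] * d[5]) >= pdrop) / (1 - pdrop)
  mask <- array(rep(cm, each = prod(d[1:3])), d)
  list(out = x * mask, mask = mask)
}

dropoutBwd <- function(mask, gout) {
  if (is.null(mask)) gout else gout * mask
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  flat <- flattenParams(params)
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

# params and grads are nested lists; only numeric leaves named W, b, gamma,
# beta are trainable
flattenParams <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p)) {
      out <- c(out, flattenParams(p, key))
    } else if (nm %in% c("W", "b", "gamma", "beta")) {
      out[[key]] <- p
    }
  }
  out
}

assignFlat <- function(params, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    params[[path]] <- flat[[key]]
  }
  params
}

adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  fp <- flattenParams(params)
  fg <- flattenParams(grads)
  state$t <- state$t + 1L
  t <- state$t
  for (key in names(fp)) {
    g <- fg[[key]]
    if (is.null(g)) next
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^t)
    vhat <- state$v[[key]] / (1 - beta2^t)
    fp[[key]] <- fp[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = assignFlat(params, fp), state = state)
}
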