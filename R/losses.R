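# Segmentation losses: class-weighted multi-class soft Dice and categorical
# cross-entropy, plus inverse-frequency class weights.

#' Inverse-frequency class weights over foreground classes
#'
#' Balanced weighting computed over the foreground voxels of a collection
#' of label maps: \code{W_m = N_total / (M_fg * N_m)}, where \code{N_m} is
#' the voxel count of foreground class m, \code{N_total} the total
#' foreground count and \code{M_fg} the number of foreground classes.
#' Background (label 0) is excluded from all sums. Equally frequent
#' classes give all weights 1; rarer classes get proportionally larger
#' weights.
#'
#' @param labelmaps List of \linkS4class{LabelVolume} (or a single one).
#' @return Numeric vector of weights \code{W_m}, one per foreground class
#'   \code{1..M-1}, named by class label.
#' @export
computeClassWeights <- function(labelmaps) {
  if (is(labelmaps, "LabelVolume")) labelmaps <- list(labelmaps)
  M <- nClasses(labelmaps[[1]])
  fg <- seq_len(M - 1L)
  counts <- rep(0, M - 1L)
  for (lab in labelmaps) {
    tb <- tabulate(voxelData(lab), nbins = M - 1L)
    counts <- counts + tb
  }
  if (any(counts == 0))
    stop("foreground class absent from the collection: ",
         paste(fg[counts == 0], collapse = ", "))
  w <- sum(counts) / ((M - 1L) * counts)
  names(w) <- as.character(fg)
  w
}

#' Binary soft Dice loss
#'
#' \code{DL = 1 - 2 |A.B| / (|A| + |B| + eps)}, the soft Dice loss of a
#' predicted (possibly soft) map against a binary reference. The small
#' smoothing term \code{eps} is added to the denominator only, which keeps
#' the loss at 1 for disjoint non-empty masks while guarding the
#' otherwise unconstrained denominator of the Dice ratio.
#'
#' @param pred Numeric array in [0, 1] (soft prediction for the class).
#' @param ref Binary array (0/1) of the same shape.
#' @param eps Denominator smoothing (default 1e-5).
#' @return Scalar loss in [0, 1], differentiable in \code{pred}.
#' @export
diceLoss <- function(pred, ref, eps = 1e-5) {
  if (!identical(dim(pred), dim(ref)) &&
      !(is.null(dim(pred)) && is.null(dim(ref)) &&
        length(pred) == length(ref)))
    stop("pred and ref must have identical shape")
  1 - 2 * sum(pred * ref) / (sum(pred) + sum(ref) + eps)
}

# gradient of diceLoss wrt pred (used by the training loop)
diceLossGrad <- function(pred, ref, eps = 1e-5) {
  I <- sum(pred * ref)
  D <- sum(pred) + sum(ref) + eps
  (2 * I / D^2) - (2 * ref / D)
}

#' Class-weighted multi-class soft Dice loss
#'
#' The sum of per-foreground-class soft Dice losses weighted by the class
#' weights: \code{sum_m W_m * DL_m} for m over the foreground classes.
#' With a single foreground class and unit weight this reduces exactly to
#' \code{\link{diceLoss}}.
#'
#' @param pred 4D array (x, y, z, class) of per-voxel class probabilities
#'   (softmax output), channels ordered background first.
#' @param ref Integer array of reference labels \code{0..M-1}, same spatial
#'   shape.
#' @param w Weights for foreground classes \code{1..M-1}
#'   (\code{\link{computeClassWeights}}); default all 1.
#' @param eps Denominator smoothing passed to the per-class loss.
#' @return Scalar loss.
#' @export
multiclassDiceLoss <- function(pred, ref, w = NULL, eps = 1e-5) {
  d <- dim(pred)
  M <- d[4]
  if (!identical(d[1:3], dim(ref)[1:3]))
    stop("pred and ref must share spatial shape")
  if (is.null(w)) w <- rep(1, M - 1L)
  if (length(w) != M - 1L)
    stop("need one weight per foreground class (", M - 1L, ")")
  loss <- 0
  for (m in seq_len(M - 1L))
    loss <- loss + w[m] * diceLoss(pred[, , , m + 1L], ref == m, eps)
  loss
}

# gradient of multiclassDiceLoss wrt pred (4D array, same shape)
multiclassDiceLossGrad <- function(pred, ref, w = NULL, eps = 1e-5) {
  d <- dim(pred)
  M <- d[4]
  if (is.null(w)) w <- rep(1, M - 1L)
  g <- array(0, d)
  for (m in seq_len(M - 1L))
    g[, , , m + 1L] <- w[m] * diceLossGrad(pred[, , , m + 1L], ref == m, eps)
  g
}

#' Categorical cross-entropy
#'
#' \code{H(p, q) = -sum_m sum_a p(a, m) log q(a, m)} between the reference
#' distribution p (rows of one-hot or soft class memberships, one row per
#' observation) and the predicted distribution q. q is clipped to
#' \code{[1e-7, 1 - 1e-7]} before the log for numerical safety. Zero iff q
#' matches a one-hot p exactly.
#'
#' @param p Matrix of reference distributions, rows summing to 1.
#' @param q Matrix of predicted probabilities, same shape, rows summing to
#'   1 within tolerance.
#' @return Scalar, >= 0 (summed over observations).
#' @export
categoricalCrossEntropy <- function(p, q) {
  p <- rbind(p)
  q <- rbind(q)
  if (!identical(dim(p), dim(q)))
    stop("p and q must have identical shape")
  if (max(abs(rowSums(q) - 1)) > 1e-5)
    stop("rows of q must sum to 1")
  qc <- pmin(pmax(q, 1e-7), 1 - 1e-7)
  -sum(p * log(qc))
}
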