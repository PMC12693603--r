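# Multi-label loss functions for imbalanced odor data. All three operate on
# probability scores in (0,1) and are averaged over samples, summed over
# labels. Gradients are taken with respect to the pre-sigmoid logits and are
# used by the training loop.

.EPS_PROB <- 1e-7

.clamp_prob <- function(p) pmin(pmax(p, .EPS_PROB), 1 - .EPS_PROB)

#' Binary cross-entropy loss
#'
#' @param scores Probability matrix (molecules x labels), values in (0,1)
#'   (exact 0/1 are clamped to `[1e-7, 1 - 1e-7]`).
#' @param labels 0/1 matrix, same shape.
#' @return Scalar loss: mean over samples of the per-label sum.
#' @export
bce_loss <- function(scores, labels) {
  p <- .clamp_prob(as.matrix(unclass(scores)))
  y <- as.matrix(unclass(labels))
  stopifnot(all(dim(p) == dim(y)))
  -sum(y * log(p) + (1 - y) * log(1 - p)) / nrow(p)
}

#' Inverse-frequency weighted binary cross-entropy
#'
#' The positive term of label k is weighted by `w_k = (N - n_k) / n_k`
#' (negatives per positive), so rare labels are up-weighted. With balanced
#' labels (`n_k = N/2`) this reduces to plain BCE.
#'
#' @inheritParams bce_loss
#' @param weights Optional per-label positive weights; defaults to inverse
#'   frequency computed from `labels`.
#' @return Scalar loss.
#' @export
weighted_bce_loss <- function(scores, labels, weights = NULL) {
  p <- .clamp_prob(as.matrix(unclass(scores)))
  y <- as.matrix(unclass(labels))
  stopifnot(all(dim(p) == dim(y)))
  if (is.null(weights)) weights <- inverse_frequency_weights(y)
  w <- matrix(weights, nrow(p), ncol(p), byrow = TRUE)
  -sum(w * y * log(p) + (1 - y) * log(1 - p)) / nrow(p)
}

#' Inverse-frequency positive-class weights
#'
#' @param labels 0/1 matrix.
#' @return `w_k = (N - n_k) / n_k` per label (capped at 100 for labels with
#'   very few positives; `Inf` avoided).
#' @export
inverse_frequency_weights <- function(labels) {
  y <- as.matrix(unclass(labels))
  n <- nrow(y); nk <- pmax(colSums(y), 1)
  pmin((n - nk) / nk, 100)
}

#' Focal loss for multi-label classification
#'
#' `L = -(1/N) sum_i sum_k alpha_k (1 - p_ik)^gamma log(p_ik)` where `p_ik`
#' is the model's confidence in the true class (the score if the label is 1,
#' one minus the score otherwise). `gamma` down-weights easy examples;
#' `alpha_k` rebalances labels. With `gamma = 0`, `alpha = 1` this is exactly
#' binary cross-entropy.
#'
#' @inheritParams bce_loss
#' @param alpha Scalar or per-label vector in (0,1], default 0.25.
#' @param gamma Focusing exponent, >= 0, default 2.
#' @return Scalar loss.
#' @examples
#' # single sample, true label, p = 0.9: 0.25 * 0.1^2 * -log(0.9)
#' focal_loss(matrix(0.9), matrix(1), alpha = 0.25, gamma = 2)
#' @export
focal_loss <- function(scores, labels, alpha = 0.25, gamma = 2) {
  p <- .clamp_prob(as.matrix(unclass(scores)))
  y <- as.matrix(unclass(labels))
  stopifnot(all(dim(p) == dim(y)), gamma >= 0, all(alpha > 0), all(alpha <= 1))
  a <- matrix(alpha, nrow(p), ncol(p), byrow = TRUE)
  u <- ifelse(y == 1, p, 1 - p)   # confidence in the true class
  sum(a * (1 - u)^gamma * (-log(u))) / nrow(p)
}

# loss + gradient wrt logits, used by the training loop.
# type: "bce" | "weighted_bce" | "focal"
.loss_grad <- function(type, logits, y, alpha = 0.25, gamma = 2, weights = NULL) {
  n <- nrow(logits)
  p <- .clamp_prob(1 / (1 + exp(-logits)))
  if (type == "bce") {
    loss <- -sum(y * log(p) + (1 - y) * log(1 - p)) / n
    dz <- (p - y) / n
  } else if (type == "weighted_bce") {
    w <- matrix(weights, n, ncol(p), byrow = TRUE)
    loss <- -sum(w * y * log(p) + (1 - y) * log(1 - p)) / n
    dz <- (w * y * (p - 1) + (1 - y) * p) / n
  } else if (type == "focal") {
    a <- matrix(alpha, n, ncol(p), byrow = TRUE)
    u <- ifelse(y == 1, p, 1 - p)
    loss <- sum(a * (1 - u)^gamma * (-log(u))) / n
    s <- ifelse(y == 1, 1, -1)
    dl_du <- a * (gamma * (1 - u)^pmax(gamma - 1, 0) * log(u) - (1 - u)^gamma / u)
    dz <- dl_du * s * u * (1 - u) / n
  } else stop("unknown loss type")
  list(loss = loss, dlogits = dz)
}
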