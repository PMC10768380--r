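## Inductive matrix completion head. Scores every drug-target pair as
## S = X Z1 Z2' Y' (rank at most k) and trains against a weighted
## reconstruction loss in which the unobserved class is down-weighted by
## mu = |Omega| / |Omega-bar| to counter the extreme positive/negative
## imbalance of interaction matrices.

#' Score all drug-target pairs
#'
#' `S = X Z1 Z2' Y'`; the rank of `S` is at most the factor rank `k`.
#'
#' @param X drug embeddings (`m x f_r`).
#' @param Y target embeddings (`n x f_t`).
#' @param Z1 drug-side projection factor (`f_r x k`).
#' @param Z2 target-side projection factor (`f_t x k`).
#' @return `m x n` score matrix.
#' @export
imcScoreMatrix <- function(X, Y, Z1, Z2) {
  if (ncol(X) != nrow(Z1))
    stop(sprintf("X width %d != Z1 rows %d", ncol(X), nrow(Z1)))
  if (ncol(Y) != nrow(Z2))
    stop(sprintf("Y width %d != Z2 rows %d", ncol(Y), nrow(Z2)))
  if (ncol(Z1) != ncol(Z2))
    stop("Z1 and Z2 must share the latent rank k")
  (X %*% Z1) %*% t(Y %*% Z2)
}

#' Class-imbalance weight
#'
#' `mu = |Omega| / |Omega-bar|`: the ratio of observed positive pairs to
#' unobserved pairs, computed from the training split only.
#'
#' @param T binary interaction matrix restricted to the training rows.
#' @param mask optional logical/0-1 matrix marking pairs that belong to the
#'   training split (held-out pairs excluded from both classes).
#' @return scalar weight in (0, Inf).
#' @export
imbalanceWeight <- function(T, mask = NULL) {
  if (is.null(mask)) mask <- array(1, dim = dim(T))
  nPos <- sum(T[mask > 0] == 1)
  nNeg <- sum(T[mask > 0] == 0)
  if (nPos == 0) stop("no observed positives: imbalance weight undefined")
  if (nNeg == 0) stop("no negatives: imbalance weight undefined")
  nPos / nNeg
}

#' Weighted inductive matrix completion loss
#'
#' `loss = (1 - alpha)/2 ||P_Omega(T - S)||_F^2
#'        + (alpha mu)/2 ||P_Omegabar(T - S)||_F^2`
#' where `P_Omega` keeps the observed positive pairs and `P_Omegabar` the
#' complement. Pairs excluded by `mask` (held-out drugs' rows during
#' cross-validation) contribute to neither term.
#'
#' @param T binary interaction matrix.
#' @param S score matrix of the same shape.
#' @param alpha bias term in (0, 1) trading the two classes.
#' @param mu class-imbalance weight (see [imbalanceWeight()]).
#' @param mask optional training-pair mask.
#' @return scalar loss.
#' @export
imcLoss <- function(T, S, alpha, mu, mask = NULL) {
  if (!all(dim(T) == dim(S))) stop("T and S must have the same shape")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  C <- .lossWeights(T, alpha, mu, mask)
  sum(C * (T - S)^2) / 2
}

## Per-pair quadratic weights: (1-alpha) on Omega, alpha*mu on the
## complement, 0 outside the training mask.
.lossWeights <- function(T, alpha, mu, mask = NULL) {
  C <- ifelse(T == 1, 1 - alpha, alpha * mu)
  if (!is.null(mask)) C <- C * (mask > 0)
  C
}

#' Analytic gradients of the IMC loss
#'
#' Returns the gradient of [imcLoss()] at `S = X Z1 Z2' Y'` with respect to
#' the projection factors and the embeddings.
#'
#' @inheritParams imcScoreMatrix
#' @inheritParams imcLoss
#' @return list with elements `S` (dL/dS), `Z1`, `Z2`, `X`, `Y`, plus the
#'   score matrix `Shat` and the `loss` value.
#' @export
imcGradients <- function(T, X, Y, Z1, Z2, alpha, mu, mask = NULL) {
  S <- imcScoreMatrix(X, Y, Z1, Z2)
  C <- .lossWeights(T, alpha, mu, mask)
  R <- C * (S - T)
  YZ2 <- Y %*% Z2
  XZ1 <- X %*% Z1
  RYZ2 <- R %*% YZ2
  RtXZ1 <- crossprod(R, XZ1)
  list(
    S = R,
    Z1 = crossprod(X, RYZ2),
    Z2 = crossprod(Y, RtXZ1),
    X = tcrossprod(RYZ2, Z1),
    Y = tcrossprod(RtXZ1, Z2),
    Shat = S,
    loss = sum(C * (T - S)^2) / 2
  )
}
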