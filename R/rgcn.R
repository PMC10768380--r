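## Per-metapath residual graph convolution channel.
##
## Layers propagate with the symmetrically normalized adjacency
## D^{-1/2} (A + I) D^{-1/2}; after a first projection layer, residual
## blocks add an identity shortcut around each convolution so depth does
## not wash out the signal.

#' Symmetric adjacency normalization
#'
#' Returns `D^{-1/2} (A + I) D^{-1/2}` where `D` is the diagonal degree
#' matrix of `A + I`. A row/column whose original degree is zero keeps a
#' lone unit self-loop entry. The normalization constant between nodes i
#' and j is `sqrt(d_i d_j)`.
#'
#' @param A square non-negative adjacency matrix (self-loops are added
#'   internally; an already-present diagonal is first removed).
#' @return normalized symmetric matrix with spectral radius at most 1.
#' @export
normalizeAdjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("adjacency must be a square matrix")
  if (any(A < 0)) stop("adjacency must be non-negative")
  At <- A
  diag(At) <- 0
  At <- At + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' One graph convolution layer
#'
#' `H_out = sigma(A_norm H W)`. The first layer of the channel consumes the
#' initial feature matrix; subsequent layers consume prior outputs.
#'
#' @param Anorm normalized adjacency from [normalizeAdjacency()].
#' @param H input embeddings.
#' @param W layer weight matrix (`ncol(H) x d_out`).
#' @param activation nonlinearity name.
#' @return activated embeddings.
#' @export
gcnLayer <- function(Anorm, H, W, activation = "tanh") {
  if (ncol(H) != nrow(W))
    stop(sprintf("H width %d does not match W rows %d", ncol(H), nrow(W)))
  out <- .activate(Anorm %*% H %*% W, activation)
  if (any(!is.finite(out)))
    stop("non-finite values in graph convolution layer output")
  out
}

#' Residual graph convolution block
#'
#' `G_out = F(G_in, W) + G_in` where `F` is one [gcnLayer()] application;
#' the identity shortcut requires equal input and output widths.
#'
#' @inheritParams gcnLayer
#' @param G input embeddings (width must equal `ncol(W)`).
#' @return embeddings of the same shape as `G`.
#' @export
residualBlock <- function(Anorm, G, W, activation = "tanh") {
  if (ncol(G) != ncol(W))
    stop(sprintf("residual undefined: input width %d != output width %d",
                 ncol(G), ncol(W)))
  gcnLayer(Anorm, G, W, activation) + G
}

#' Encode every metapath with a residual graph convolution stack
#'
#' Per metapath: one plain projection layer taking the initial features to
#' the hidden width, then `nResidual` residual blocks.
#'
#' @param graphs named list of [MetapathGraph-class].
#' @param features initial node features.
#' @param params named list (per metapath) of `list(W0, Wres)` where `Wres`
#'   is a list of residual-block weight matrices.
#' @param activation nonlinearity name.
#' @return named list of per-metapath embedding matrices.
#' @export
rgcnEncode <- function(graphs, features, params, activation = "tanh") {
  out <- list()
  for (nm in names(graphs)) {
    Anorm <- normalizeAdjacency(adjacency(graphs[[nm]]))
    H <- gcnLayer(Anorm, features, params[[nm]]$W0, activation)
    for (W in params[[nm]]$Wres)
      H <- residualBlock(Anorm, H, W, activation)
    out[[nm]] <- H
  }
  out
}

## Forward with cache for backprop. Anorm precomputed.
.rgcnForward <- function(Anorm, F0, par, activation) {
  pre0 <- Anorm %*% F0 %*% par$W0
  H <- .activate(pre0, activation)
  stages <- list()
  for (li in seq_along(par$Wres)) {
    Hin <- H
    pre <- Anorm %*% Hin %*% par$Wres[[li]]
    R <- .activate(pre, activation)
    H <- R + Hin
    stages[[li]] <- list(Hin = Hin, pre = pre, R = R)
  }
  list(H = H, cache = list(pre0 = pre0, H0 = .activate(pre0, activation),
                           stages = stages))
}

.rgcnBackward <- function(Anorm, F0, par, cache, dH, activation) {
  gWres <- vector("list", length(par$Wres))
  for (li in rev(seq_along(par$Wres))) {
    st <- cache$stages[[li]]
    dR <- dH                                   # residual branch
    dpre <- dR * .activateGrad(st$pre, st$R, activation)
    Adpre <- Anorm %*% dpre
    gWres[[li]] <- crossprod(st$Hin, Adpre)
    dH <- dH + tcrossprod(Adpre, par$Wres[[li]])  # shortcut + conv path
  }
  dpre0 <- dH * .activateGrad(cache$pre0, cache$H0, activation)
  gW0 <- crossprod(F0, Anorm %*% dpre0)
  list(W0 = gW0, Wres = gWres)
}

.initGCNParams <- function(metapathNames, dIn, width, nResidual) {
  glorot <- function(nr, nc) {
    a <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -a, a), nr, nc)
  }
  out <- list()
  for (nm in metapathNames) {
    out[[nm]] <- list(
      W0 = glorot(dIn, width),
      Wres = lapply(seq_len(nResidual), function(i) glorot(width, width))
    )
  }
  out
}
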