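## Metapath-level (semantic) attention: fuses the per-metapath embeddings
## of both channels into one embedding matrix per node type. One shared
## parameter set (Wf, b, q) scores every metapath of a node type so the
## scores are comparable.

#' Metapath-level attention score
#'
#' `s^rho = (1/n) sum_j q' tanh(Wf x_j + b)` averaged over the node set.
#'
#' @param Wf shared weight matrix (`width x attDim`).
#' @param b bias vector (length `attDim`).
#' @param q semantic-level attention vector (length `attDim`).
#' @param X one metapath's embedding matrix (nodes x width).
#' @param nodes optional integer subset of rows to average over (default all).
#' @return scalar score.
#' @export
metapathScore <- function(Wf, b, q, X, nodes = NULL) {
  if (!is.null(nodes)) X <- X[nodes, , drop = FALSE]
  if (nrow(X) == 0) stop("empty node set: metapath score undefined")
  H <- tanh(sweep(X %*% Wf, 2, b, `+`))
  mean(H %*% q)
}

#' Softmax weights over metapath scores
#'
#' @param scores named numeric vector of metapath-level attention scores.
#' @return named weights summing to 1.
#' @export
metapathWeights <- function(scores) {
  if (!length(scores)) stop("need at least one metapath")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Fuse per-metapath, per-channel embeddings
#'
#' `X = sum_rho a^rho (G_a^rho + G_c^rho) / 2`: the mean of the attention
#' channel and the convolution channel, weighted by the shared
#' metapath-level attention. Linear in each channel's embeddings for fixed
#' weights.
#'
#' @param weights named metapath weights from [metapathWeights()].
#' @param gatEmbs,gcnEmbs named lists of embedding matrices, one per
#'   metapath, equal widths across channels.
#' @return fused embedding matrix.
#' @export
fuseEmbeddings <- function(weights, gatEmbs, gcnEmbs) {
  stopifnot(all(names(weights) %in% names(gatEmbs)),
            all(names(weights) %in% names(gcnEmbs)))
  X <- NULL
  for (nm in names(weights)) {
    Ga <- gatEmbs[[nm]]; Gc <- gcnEmbs[[nm]]
    if (!all(dim(Ga) == dim(Gc)))
      stop(sprintf("channel width mismatch for metapath '%s': %dx%d vs %dx%d",
                   nm, nrow(Ga), ncol(Ga), nrow(Gc), ncol(Gc)))
    term <- weights[[nm]] * (Ga + Gc) / 2
    X <- if (is.null(X)) term else X + term
  }
  X
}

## Forward with cache. channels: "both", "gat", "gcn". Scores are computed
## on the attention-channel embeddings when present, else on the
## convolution channel.
.fusionForward <- function(par, gatEmbs, gcnEmbs, channels) {
  scoreEmbs <- if (channels == "gcn") gcnEmbs else gatEmbs
  nms <- names(scoreEmbs)
  scores <- numeric(length(nms)); names(scores) <- nms
  Hs <- list()
  for (nm in nms) {
    H <- tanh(sweep(scoreEmbs[[nm]] %*% par$Wf, 2, par$b, `+`))
    Hs[[nm]] <- H
    scores[nm] <- mean(H %*% par$q)
  }
  w <- metapathWeights(scores)
  X <- NULL
  for (nm in nms) {
    term <- switch(channels,
      both = w[[nm]] * (gatEmbs[[nm]] + gcnEmbs[[nm]]) / 2,
      gat  = w[[nm]] * gatEmbs[[nm]],
      gcn  = w[[nm]] * gcnEmbs[[nm]])
    X <- if (is.null(X)) term else X + term
  }
  list(X = X, weights = w, scores = scores, Hs = Hs)
}

## Backward: returns dGat/dGcn per metapath plus fusion parameter grads.
.fusionBackward <- function(par, gatEmbs, gcnEmbs, cache, dX, channels) {
  nms <- names(cache$scores)
  w <- cache$weights
  dGat <- list(); dGcn <- list()
  dscore <- numeric(length(nms)); names(dscore) <- nms
  for (nm in nms) {
    base <- switch(channels,
      both = (gatEmbs[[nm]] + gcnEmbs[[nm]]) / 2,
      gat  = gatEmbs[[nm]],
      gcn  = gcnEmbs[[nm]])
    dscore[nm] <- sum(dX * base)
    dBase <- w[[nm]] * dX
    if (channels == "both") {
      dGat[[nm]] <- dBase / 2
      dGcn[[nm]] <- dBase / 2
    } else if (channels == "gat") {
      dGat[[nm]] <- dBase
    } else {
      dGcn[[nm]] <- dBase
    }
  }
  ds <- w * (dscore - sum(w * dscore))        # softmax backward
  gWf <- matrix(0, nrow(par$Wf), ncol(par$Wf))
  gb <- numeric(length(par$b))
  gq <- numeric(length(par$q))
  scoreEmbs <- if (channels == "gcn") gcnEmbs else gatEmbs
  for (nm in nms) {
    H <- cache$Hs[[nm]]
    n <- nrow(H)
    gq <- gq + ds[[nm]] * colMeans(H)
    dH <- (ds[[nm]] / n) * matrix(par$q, n, length(par$q), byrow = TRUE)
    dPre <- dH * (1 - H^2)
    gWf <- gWf + t(scoreEmbs[[nm]]) %*% dPre
    gb <- gb + colSums(dPre)
    dEmb <- dPre %*% t(par$Wf)
    if (channels == "gcn") {
      dGcn[[nm]] <- dGcn[[nm]] + dEmb
    } else {
      dGat[[nm]] <- if (is.null(dGat[[nm]])) dEmb else dGat[[nm]] + dEmb
    }
  }
  list(dGat = dGat, dGcn = dGcn, Wf = gWf, b = gb, q = gq)
}

.initFusionParams <- function(width, attDim) {
  a <- sqrt(6 / (width + attDim))
  list(Wf = matrix(stats::runif(width * attDim, -a, a), width, attDim),
       b = rep(0, attDim),
       q = stats::runif(attDim, -a, a))
}
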