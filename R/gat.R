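## Per-metapath multi-head graph attention channel.
##
## A head is a list(W, g) with W the d_out x d_in linear map and g the
## attention vector of length 2*d_out. The attention logit of neighbour j
## on node i is leakyReLU(g' [W x_i || W x_j]); logits are softmax-normalized
## over the metapath neighbourhood (self-loops guarantee it is non-empty).

.leaky <- function(x, slope) pmax(x, slope * x)   # slope in (0, 1)

.activate <- function(x, activation) {
  switch(activation,
    tanh = tanh(x),
    relu = pmax(x, 0),
    identity = x,
    stop("unknown activation '", activation, "'"))
}

.activateGrad <- function(pre, post, activation) {
  switch(activation,
    tanh = 1 - post^2,
    relu = (pre > 0) * 1,
    identity = array(1, dim = dim(pre)),
    stop("unknown activation '", activation, "'"))
}

#' Attention logit of one neighbour on one node
#'
#' `w_ij = leakyReLU(g' [W x_i || W x_j])`. Asymmetric in general:
#' swapping i and j swaps which half of `g` multiplies which transformed
#' embedding.
#'
#' @param W head weight matrix (`d_out x d_in`).
#' @param g attention vector of length `2 * d_out`.
#' @param xi,xj embeddings of node i and neighbour j (length `d_in`).
#' @param leakySlope negative-part slope of the rectifier (default 0.2).
#' @return scalar logit.
#' @export
attentionLogits <- function(W, g, xi, xj, leakySlope = 0.2) {
  if (length(xi) != ncol(W) || length(xj) != ncol(W))
    stop(sprintf("embedding length %d does not match W input dimension %d",
                 length(xi), ncol(W)))
  if (length(g) != 2 * nrow(W))
    stop(sprintf("attention vector length %d != 2 x output dimension %d",
                 length(g), nrow(W)))
  z <- c(W %*% xi, W %*% xj)
  .leaky(sum(g * z), leakySlope)
}

#' Softmax attention coefficients over a neighbourhood
#'
#' Normalizes a node's logits over its metapath neighbours with the softmax,
#' using max-subtraction for overflow safety. The neighbourhood must be
#' non-empty (guaranteed by self-loops in metapath graphs).
#'
#' @param logits numeric vector of logits over `N^rho(i)`.
#' @return coefficients summing to 1.
#' @export
attentionCoefficients <- function(logits) {
  if (!length(logits))
    stop("empty neighbourhood: self-loop invariant violated")
  e <- exp(logits - max(logits))
  e / sum(e)
}

## Dense masked-softmax attention matrix for one head.
## Returns list(Z, Eraw, A) where A[i, j] is the coefficient of neighbour j
## on node i (zero off the adjacency support).
.headAttention <- function(adj, H, W, g, leakySlope) {
  d <- nrow(W)
  Z <- tcrossprod(H, W)                 # n x d
  g1 <- g[seq_len(d)]; g2 <- g[d + seq_len(d)]
  e <- drop(Z %*% g1); f <- drop(Z %*% g2)
  Eraw <- outer(e, rep(1, length(f))) + outer(rep(1, length(e)), f)
  L <- .leaky(Eraw, leakySlope)
  L[adj == 0] <- -Inf
  rm <- apply(L, 1, max)
  A <- exp(L - rm)
  A[adj == 0] <- 0
  A <- A / rowSums(A)
  list(Z = Z, Eraw = Eraw, A = A)
}

#' One multi-head graph attention layer
#'
#' Per head, each node's new embedding is the activation of the
#' attention-weighted sum of its neighbours' linearly transformed
#' embeddings; the head outputs are concatenated, giving width
#' `K * d_out`.
#'
#' @param graph a [MetapathGraph-class] (or a square binary adjacency).
#' @param H input embeddings, one row per node.
#' @param heads list of heads, each `list(W, g)`.
#' @param activation node-update nonlinearity (`"tanh"`, `"relu"`,
#'   `"identity"`).
#' @param leakySlope slope of the attention rectifier.
#' @param attDropout optional list of per-head dropout mask matrices applied
#'   to the attention coefficients (training only).
#' @return embeddings of dimension `n x (K * d_out)`.
#' @export
gatLayer <- function(graph, H, heads, activation = "tanh", leakySlope = 0.2,
                     attDropout = NULL) {
  adj <- if (is(graph, "MetapathGraph")) adjacency(graph) else graph
  if (nrow(H) != nrow(adj))
    stop(sprintf("embedding rows (%d) != graph nodes (%d)", nrow(H), nrow(adj)))
  out <- .gatLayerForward(adj, H, heads, activation, leakySlope, attDropout)
  if (any(!is.finite(out$H)))
    stop("non-finite values in graph attention layer output")
  out$H
}

.gatLayerForward <- function(adj, H, heads, activation, leakySlope,
                             attDropout = NULL) {
  caches <- vector("list", length(heads))
  pieces <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    hd <- heads[[k]]
    att <- .headAttention(adj, H, hd$W, hd$g, leakySlope)
    Ad <- if (is.null(attDropout)) att$A else att$A * attDropout[[k]]
    P <- Ad %*% att$Z
    Hk <- .activate(P, activation)
    caches[[k]] <- list(Z = att$Z, Eraw = att$Eraw, A = att$A, Ad = Ad,
                        P = P, Hk = Hk)
    pieces[[k]] <- Hk
  }
  list(H = do.call(cbind, pieces), caches = caches)
}

## Backward pass of one GAT layer. dOut is n x (K*d_out). Returns gradients
## for every head and the gradient w.r.t. the input embeddings.
.gatLayerBackward <- function(adj, H, heads, cache, dOut, activation,
                              leakySlope, attDropout = NULL) {
  n <- nrow(H)
  dH_in <- matrix(0, n, ncol(H))
  gradHeads <- vector("list", length(heads))
  col0 <- 0
  for (k in seq_along(heads)) {
    hd <- heads[[k]]
    ck <- cache[[k]]
    d <- nrow(hd$W)
    dHk <- dOut[, col0 + seq_len(d), drop = FALSE]
    col0 <- col0 + d
    dP <- dHk * .activateGrad(ck$P, ck$Hk, activation)
    dZ <- crossprod(ck$Ad, dP)
    dAd <- tcrossprod(dP, ck$Z)
    dA <- if (is.null(attDropout)) dAd else dAd * attDropout[[k]]
    rowdot <- rowSums(dA * ck$A)
    dL <- ck$A * (dA - rowdot)          # softmax backward, zero off-support
    dE <- dL * ((ck$Eraw > 0) + leakySlope * (ck$Eraw <= 0))
    de <- rowSums(dE); df <- colSums(dE)
    g1 <- hd$g[seq_len(d)]; g2 <- hd$g[d + seq_len(d)]
    dZ <- dZ + outer(de, g1) + outer(df, g2)
    dg <- c(drop(crossprod(ck$Z, de)), drop(crossprod(ck$Z, df)))
    dW <- crossprod(dZ, H)
    dH_in <- dH_in + dZ %*% hd$W
    gradHeads[[k]] <- list(W = dW, g = dg)
  }
  list(heads = gradHeads, dH = dH_in)
}

#' Encode every metapath with stacked graph attention layers
#'
#' Applies `length(params[[rho]])` attention layers per metapath, starting
#' from the supplied features; with zero layers the features pass through
#' unchanged.
#'
#' @param graphs named list of [MetapathGraph-class].
#' @param features initial node features (shared across metapaths).
#' @param params named list (per metapath) of lists of layers, each layer a
#'   list of heads `list(W, g)`.
#' @inheritParams gatLayer
#' @return named list of per-metapath embedding matrices.
#' @export
gatEncode <- function(graphs, features, params, activation = "tanh",
                      leakySlope = 0.2) {
  out <- list()
  for (nm in names(graphs)) {
    H <- features
    layers <- params[[nm]]
    for (li in seq_along(layers))
      H <- gatLayer(graphs[[nm]], H, layers[[li]], activation, leakySlope)
    out[[nm]] <- H
  }
  out
}

## Seeded Glorot-style initialization for one head.
.initHead <- function(dIn, dOut) {
  a <- sqrt(6 / (dIn + dOut))
  list(W = matrix(stats::runif(dOut * dIn, -a, a), dOut, dIn),
       g = stats::runif(2 * dOut, -a, a))
}

.initGATParams <- function(metapathNames, dIn, headDim, nHeads, nLayers) {
  out <- list()
  for (nm in metapathNames) {
    layers <- list()
    din <- dIn
    for (li in seq_len(nLayers)) {
      layers[[li]] <- lapply(seq_len(nHeads), function(k) .initHead(din, headDim))
      din <- nHeads * headDim
    }
    out[[nm]] <- layers
  }
  out
}
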