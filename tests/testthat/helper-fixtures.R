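# Shared fixtures and brute-force reference implementations (the oracles
# the vectorized code is checked against).

# A small fully hand-specified network: 4 drugs, 3 targets, 2 diseases,
# 2 side effects.
tinyNet <- function() {
  dd <- matrix(0, 4, 4); dd[1, 2] <- dd[2, 1] <- 1
  dt <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 0))
  ddis <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  dse <- rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 1))
  tt <- matrix(0, 3, 3); tt[2, 3] <- tt[3, 2] <- 1
  tdis <- rbind(c(1, 0), c(0, 1), c(1, 1))
  HeteroNetwork(list(drug_drug = dd, drug_target = dt, drug_disease = ddis,
                     drug_sideeffect = dse, target_target = tt,
                     target_disease = tdis))
}

# Random binary network with every relation and both similarity matrices.
randomNet <- function(seed, nd = 6, nt = 7, ndis = 5, nse = 4, p = 0.3) {
  set.seed(seed)
  sym <- function(n) {
    M <- matrix(rbinom(n * n, 1, p), n, n)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    diag(M) <- 0
    M
  }
  bip <- function(nr, nc) matrix(rbinom(nr * nc, 1, p), nr, nc)
  simm <- function(n) {
    S <- matrix(runif(n * n), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    S
  }
  HeteroNetwork(
    list(drug_drug = sym(nd), drug_target = bip(nd, nt),
         drug_disease = bip(nd, ndis), drug_sideeffect = bip(nd, nse),
         target_target = sym(nt), target_disease = bip(nt, ndis)),
    similarities = list(drug_sim = simm(nd), target_sim = simm(nt))
  )
}

# Exhaustive path enumeration: walks every sequence of intermediate nodes
# allowed by the (oriented) chain matrices and marks reachable pairs.
refComposeChain <- function(mats) {
  reach <- mats[[1]]
  for (M in mats[-1]) {
    n1 <- nrow(reach); n2 <- ncol(M)
    out <- matrix(0, n1, n2)
    for (i in seq_len(n1))
      for (j in seq_len(n2))
        for (k in seq_len(ncol(reach)))
          if (reach[i, k] > 0 && M[k, j] > 0) out[i, j] <- 1
    reach <- out
  }
  reach
}

# Scalar-loop GAT layer: per node, per head, literal evaluation of the
# attention formulas.
refGatLayer <- function(adj, H, heads, activation = "tanh",
                        leakySlope = 0.2) {
  act <- function(x) switch(activation, tanh = tanh(x),
                            identity = x, relu = pmax(x, 0))
  n <- nrow(adj)
  pieces <- list()
  for (hd in heads) {
    d <- nrow(hd$W)
    out <- matrix(0, n, d)
    for (i in seq_len(n)) {
      nbr <- which(adj[i, ] > 0)
      logits <- vapply(nbr, function(j)
        attentionLogits(hd$W, hd$g, H[i, ], H[j, ], leakySlope), numeric(1))
      a <- exp(logits - max(logits)); a <- a / sum(a)
      agg <- numeric(d)
      for (t in seq_along(nbr))
        agg <- agg + a[t] * drop(hd$W %*% H[nbr[t], ])
      out[i, ] <- act(agg)
    }
    pieces[[length(pieces) + 1]] <- out
  }
  do.call(cbind, pieces)
}

# Per-node convolution: h_i = act(sum_j A~_ij / sqrt(d_i d_j) h_j W).
refGcnLayer <- function(A, H, W, activation = "tanh") {
  act <- function(x) switch(activation, tanh = tanh(x), identity = x)
  At <- A; diag(At) <- 0; At <- At + diag(nrow(A))
  deg <- rowSums(At)
  n <- nrow(A)
  out <- matrix(0, n, ncol(W))
  for (i in seq_len(n)) {
    acc <- numeric(ncol(W))
    for (j in which(At[i, ] > 0))
      acc <- acc + drop(H[j, ] %*% W) / sqrt(deg[i] * deg[j])
    out[i, ] <- act(acc)
  }
  out
}

# AUROC as the fraction of concordant positive-negative pairs (ties 1/2).
refAuroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# AUPR as stepwise average precision over the pessimistic ranking,
# evaluated one rank at a time.
refAupr <- function(labels, scores) {
  ord <- order(-scores, labels)
  l <- labels[ord]
  tp <- 0; s <- 0
  for (i in seq_along(l)) {
    if (l[i] == 1) {
      tp <- tp + 1
      s <- s + tp / i
    }
  }
  s / sum(l)
}

# Standard error of an AUROC estimate (Hanley & McNeil).
aurocSE <- function(A, P, N) {
  Q1 <- A / (2 - A); Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (P - 1) * (Q1 - A^2) + (N - 1) * (Q2 - A^2)) / (P * N))
}

# Tiny training configuration used by pipeline smoke tests.
tinyTrainConfig <- function(seed = 1, epochs = 5, ...) {
  defaultRunConfig(seed = seed, epochs = epochs, nHeads = 2, headDim = 4,
                   attDim = 8, rank = 4, dropout = 0, ...)
}

randomHeads <- function(seed, nHeads, dIn, dOut) {
  set.seed(seed)
  lapply(seq_len(nHeads), function(k)
    list(W = matrix(rnorm(dOut * dIn), dOut, dIn), g = rnorm(2 * dOut)))
}
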