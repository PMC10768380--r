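test_that("attention logits follow the concatenated bilinear form", {
  set.seed(1)
  W <- matrix(rnorm(6), 2, 3)
  xi <- rnorm(3); xj <- rnorm(3)
  # zero attention vector: logit 0 everywhere
  expect_equal(attentionLogits(W, rep(0, 4), xi, xj), 0)
  # equal g-halves: the logit is symmetric under swapping i and j
  g <- c(0.3, -0.2, 0.3, -0.2)
  expect_equal(attentionLogits(W, g, xi, xj),
               attentionLogits(W, g, xj, xi))
  gAsym <- rnorm(4)
  expect_equal(attentionLogits(W, gAsym, xi, xj),
               {
                 z <- c(W %*% xi, W %*% xj)
                 v <- sum(gAsym * z)
                 if (v > 0) v else 0.2 * v
               })
  # scalar-loop re-implementation over coordinates on a 3-node instance
  H <- matrix(rnorm(9), 3, 3)
  for (i in 1:3) for (j in 1:3) {
    zi <- numeric(2); zj <- numeric(2)
    for (r in 1:2) for (c in 1:3) {
      zi[r] <- zi[r] + W[r, c] * H[i, c]
      zj[r] <- zj[r] + W[r, c] * H[j, c]
    }
    v <- sum(gAsym[1:2] * zi) + sum(gAsym[3:4] * zj)
    v <- ifelse(v > 0, v, 0.2 * v)
    expect_equal(attentionLogits(W, gAsym, H[i, ], H[j, ]), v)
  }
  expect_error(attentionLogits(W, gAsym, rnorm(2), xj), "dimension")
})

test_that("attention coefficients are a neighbourhood softmax", {
  expect_equal(attentionCoefficients(3.7), 1)            # singleton
  expect_equal(attentionCoefficients(c(2, 2)), c(0.5, 0.5))
  w <- c(1, 2, 3)
  expect_equal(attentionCoefficients(w), exp(w) / sum(exp(w)))
  # overflow safety
  expect_equal(attentionCoefficients(c(1000, 1000)), c(0.5, 0.5))
  expect_error(attentionCoefficients(numeric(0)), "self-loop")
})

test_that("gat layer reduces to identity and to mean aggregation in the closed-form cases", {
  n <- 4
  H <- matrix(rnorm(n * n, sd = 0.5), n, n)
  # identity adjacency, W = I, identity activation: output = input
  idHead <- list(list(W = diag(n), g = rep(0, 2 * n)))
  expect_equal(gatLayer(diag(n), H, idHead, activation = "identity"), H)
  # complete graph with zero attention vector: all-equal logits, so each
  # node's pre-activation is the mean of the transformed neighbours
  set.seed(2)
  W <- matrix(rnorm(2 * n), 2, n)
  out <- gatLayer(matrix(1, n, n), H, list(list(W = W, g = rep(0, 4))),
                  activation = "identity")
  ref <- matrix(colMeans(H %*% t(W)), n, 2, byrow = TRUE)
  expect_equal(out, ref)
})

test_that("gat layer matches the per-node scalar-loop reference", {
  set.seed(5)
  n <- 5
  adj <- matrix(rbinom(n * n, 1, 0.5), n, n)
  adj <- ((adj + t(adj)) > 0) * 1
  diag(adj) <- 1
  H <- matrix(rnorm(n * 4), n, 4)
  heads <- randomHeads(6, nHeads = 3, dIn = 4, dOut = 2)
  out <- gatLayer(adj, H, heads)
  ref <- refGatLayer(adj, H, heads)
  expect_equal(out, ref, tolerance = 1e-6)
})

test_that("attention rows normalize to one on every metapath graph", {
  net <- randomNet(3)
  H <- initialFeatures(net, "drug")
  heads <- randomHeads(4, 2, ncol(H), 3)
  for (g in metapathGraphs(net, "drug")) {
    adj <- adjacency(g)
    att <- hgdti:::.headAttention(adj, H, heads[[1]]$W, heads[[1]]$g, 0.2)
    expect_equal(rowSums(att$A), rep(1, nrow(adj)), tolerance = 1e-9)
    expect_true(all(att$A[adj == 0] == 0))
  }
})

test_that("gat layer is permutation equivariant", {
  set.seed(8)
  n <- 6
  adj <- matrix(rbinom(n * n, 1, 0.4), n, n)
  adj <- ((adj + t(adj)) > 0) * 1; diag(adj) <- 1
  H <- matrix(rnorm(n * 3), n, 3)
  heads <- randomHeads(9, 2, 3, 2)
  out <- gatLayer(adj, H, heads)
  perm <- sample(n)
  outPerm <- gatLayer(adj[perm, perm], H[perm, ], heads)
  expect_equal(outPerm[order(perm), ], out, tolerance = 1e-10)
})

test_that("stacked encoding composes single layers", {
  net <- randomNet(10)
  graphs <- metapathGraphs(net, "drug")
  Fd <- initialFeatures(net, "drug")
  # zero layers: features pass through
  params0 <- setNames(lapply(names(graphs), function(x) list()), names(graphs))
  enc0 <- gatEncode(graphs, Fd, params0)
  for (nm in names(graphs)) expect_equal(enc0[[nm]], Fd)
  # one layer equals a single gatLayer call; two layers equal the manual
  # composition
  set.seed(11)
  params <- list()
  for (nm in names(graphs)) {
    l1 <- randomHeads(sample.int(1000, 1), 2, ncol(Fd), 3)
    l2 <- randomHeads(sample.int(1000, 1), 2, 6, 3)
    params[[nm]] <- list(l1, l2)
  }
  enc2 <- gatEncode(graphs, Fd, params)
  for (nm in names(graphs)) {
    h1 <- gatLayer(graphs[[nm]], Fd, params[[nm]][[1]])
    h2 <- gatLayer(graphs[[nm]], h1, params[[nm]][[2]])
    expect_equal(enc2[[nm]], h2)
  }
})
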