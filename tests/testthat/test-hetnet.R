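test_that("HeteroNetwork validity enforces the relation invariants", {
  net <- tinyNet()
  expect_s4_class(net, "HeteroNetwork")
  expect_equal(nDrugs(net), 4L)
  expect_equal(nTargets(net), 3L)

  bad <- net
  bad@relations$drug_drug[1, 2] <- 0      # breaks symmetry
  expect_error(validObject(bad), "symmetric")
  bad <- net
  bad@relations$drug_target[1, 1] <- 2    # not binary
  expect_error(validObject(bad), "binary")
  expect_error(
    HeteroNetwork(list(drug_target = matrix(0, 2, 3),
                       drug_disease = matrix(0, 3, 2))),
    "inconsistent drug count")
})

test_that("shared-disease metapath connects exactly the drugs that share a disease", {
  # 4 drugs, 2 diseases; drugs 1&2 share disease 1, drugs 2&3 share disease 2
  ddis <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  net <- HeteroNetwork(list(drug_target = matrix(0, 4, 3),
                            drug_disease = ddis))
  g <- composeMetapath(net, Metapath("r-d-r", "drug",
                                     c("drug_disease", "drug_disease")))
  A <- adjacency(g)
  expect_equal(A[1, 2], 1)  # via shared disease
  expect_equal(A[2, 3], 1)
  expect_equal(A[1, 3], 0)  # no shared disease
  expect_equal(A[1, 4], 0)  # drug 4 is isolated apart from its self-loop
  expect_equal(diag(A), rep(1, 4))
  # matches exhaustive path enumeration off the diagonal
  ref <- refComposeChain(list(ddis, t(ddis)))
  diag(ref) <- 0; diag(ref) <- 1
  expect_equal(A, ref)
})

test_that("an empty symmetric relation composes to self-loops only", {
  net <- HeteroNetwork(list(drug_drug = matrix(0, 4, 4),
                            drug_target = matrix(0, 4, 2)))
  g <- composeMetapath(net, Metapath("r-r", "drug", "drug_drug"))
  expect_equal(adjacency(g), diag(4))
  g2 <- composeMetapath(net, Metapath("r-r", "drug", "drug_drug"),
                        selfLoops = FALSE)
  expect_equal(adjacency(g2), matrix(0, 4, 4))
})

test_that("composition agrees with exhaustive path enumeration on random networks", {
  for (seed in 1:5) {
    net <- randomNet(seed, nd = 8, nt = 9, ndis = 6, nse = 5)
    chains <- list(
      drug = list(c("drug_drug"), c("drug_disease", "drug_disease"),
                  c("drug_sideeffect", "drug_sideeffect"),
                  c("drug_target", "drug_target")),
      target = list(c("target_target"), c("target_disease", "target_disease"),
                    c("drug_target", "drug_target"))
    )
    rel <- function(nm, from) {
      ty <- hgdti:::.REL_TYPES[[nm]]
      if (ty[1] == from) relation(net, nm) else t(relation(net, nm))
    }
    for (anchor in names(chains)) {
      for (chain in chains[[anchor]]) {
        cur <- anchor
        mats <- list()
        for (nm in chain) {
          ty <- hgdti:::.REL_TYPES[[nm]]
          M <- rel(nm, cur)
          cur <- if (ty[1] == cur) ty[2] else ty[1]
          mats[[length(mats) + 1]] <- M
        }
        ref <- refComposeChain(mats)
        diag(ref) <- 0; diag(ref) <- 1
        g <- composeMetapath(net, Metapath("x", anchor, chain))
        expect_equal(adjacency(g), ref,
                     info = sprintf("seed %d %s %s", seed, anchor,
                                    paste(chain, collapse = "+")))
      }
    }
  }
})

test_that("palindromic chains yield symmetric adjacency", {
  net <- randomNet(42)
  for (mp in defaultMetapaths("drug")) {
    A <- adjacency(composeMetapath(net, mp))
    expect_equal(A, t(A), info = mp@name)
  }
})

test_that("broken chains are rejected with the offending relations named", {
  net <- tinyNet()
  expect_error(
    composeMetapath(net, Metapath("bad", "drug",
                                  c("drug_disease", "target_target"))),
    "drug_disease.*target_target")
  expect_error(
    composeMetapath(net, Metapath("bad", "target", "drug_disease")),
    "chain")
})

test_that("merging neighbour graphs is a boolean union", {
  mkGraph <- function(n, edges, anchor = "drug") {
    A <- matrix(0, n, n)
    for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
    new("MetapathGraph", metapath = Metapath("g", anchor, "drug_drug"),
        adjacency = A, selfLoops = FALSE)
  }
  g1 <- mkGraph(4, list(c(1, 2)))
  g2 <- mkGraph(4, list(c(2, 3)))
  merged <- mergeNeighborGraphs(list(g1, g2))
  A <- adjacency(merged)
  expect_equal(sum(A), 4)                   # both edges, symmetric
  expect_equal(A[1, 2] + A[2, 3], 2)
  # idempotence
  expect_equal(adjacency(mergeNeighborGraphs(list(g1, g1))), adjacency(g1))
  # mixed anchors rejected
  g3 <- mkGraph(4, list(), anchor = "target")
  expect_error(mergeNeighborGraphs(list(g1, g3)), "mixed anchor")
})

test_that("merged default metapath graphs equal the brute-force union", {
  net <- randomNet(7)
  graphs <- metapathGraphs(net, "drug")
  merged <- mergeNeighborGraphs(unname(graphs))
  ref <- (Reduce(`+`, lapply(graphs, adjacency)) > 0) * 1
  expect_equal(adjacency(merged), ref)
  # monotone: adding an edge to an input relation never removes a merged edge
  net2 <- net
  net2@relations$drug_drug[1, 4] <- net2@relations$drug_drug[4, 1] <- 1
  merged2 <- mergeNeighborGraphs(unname(metapathGraphs(net2, "drug")))
  expect_true(all(adjacency(merged2) >= adjacency(merged)))
})

test_that("initial features concatenate similarity and interaction blocks", {
  # identity fallback: no similarity matrix present
  dt <- rbind(c(1, 0, 1), c(0, 1, 0))
  net <- HeteroNetwork(list(drug_target = dt))
  Fd <- initialFeatures(net, "drug")
  expect_equal(dim(Fd), c(2L, 5L))
  expect_equal(Fd, cbind(diag(2), dt))
  # zero interactions: only the similarity block is nonzero
  net0 <- HeteroNetwork(list(drug_target = matrix(0, 2, 3)))
  expect_equal(initialFeatures(net0, "drug"), cbind(diag(2), matrix(0, 2, 3)))
  # row sums decompose into similarity row sums + interaction degree
  net2 <- randomNet(9)
  Fd2 <- initialFeatures(net2, "drug")
  expect_equal(rowSums(Fd2),
               rowSums(similarity(net2, "drug_sim")) +
                 rowSums(relation(net2, "drug_target")))
  Ft2 <- initialFeatures(net2, "target")
  expect_equal(rowSums(Ft2),
               rowSums(similarity(net2, "target_sim")) +
                 colSums(relation(net2, "drug_target")))
})

test_that("similarity metapaths threshold the similarity matrix", {
  net <- randomNet(13)
  mp <- Metapath("t-sim-t", "target", "target_sim", simThreshold = 0.5)
  A <- adjacency(composeMetapath(net, mp))
  S <- similarity(net, "target_sim")
  ref <- (S >= 0.5) * 1
  diag(ref) <- 1
  expect_equal(A, ref)
})
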