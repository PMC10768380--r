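## Metapath neighbour graphs over the heterogeneous network.

#' Default metapath sets
#'
#' Four metapaths per node type. For drugs: direct interaction (r-r), shared
#' disease (r-d-r), shared side effect (r-se-r), shared target (r-t-r). For
#' targets: direct interaction (t-t), shared disease (t-d-t), shared drug
#' (t-r-t), and high-similarity neighbourhood (t-sim-t, the target
#' similarity matrix thresholded at `simThreshold`). The sets are
#' configurable; any chain of canonical relation names that composes back to
#' the anchor type is accepted by [composeMetapath()].
#'
#' @param anchor `"drug"` or `"target"`.
#' @param simThreshold threshold for similarity pseudo-relations.
#' @return list of [Metapath-class] objects.
#' @export
defaultMetapaths <- function(anchor = c("drug", "target"), simThreshold = 0.5) {
  anchor <- match.arg(anchor)
  if (anchor == "drug") {
    list(
      Metapath("r-r",    "drug", "drug_drug"),
      Metapath("r-d-r",  "drug", c("drug_disease", "drug_disease")),
      Metapath("r-se-r", "drug", c("drug_sideeffect", "drug_sideeffect")),
      Metapath("r-t-r",  "drug", c("drug_target", "drug_target"))
    )
  } else {
    list(
      Metapath("t-t",     "target", "target_target"),
      Metapath("t-d-t",   "target", c("target_disease", "target_disease")),
      Metapath("t-r-t",   "target", c("drug_target", "drug_target")),
      Metapath("t-sim-t", "target", "target_sim", simThreshold = simThreshold)
    )
  }
}

## Resolve one chain step against the current node type, returning the
## (possibly transposed) binary matrix and the next node type.
.resolveStep <- function(net, relName, current, simThreshold, prevName) {
  if (relName %in% names(.SIM_TYPES)) {
    ty <- .SIM_TYPES[[relName]]
    if (ty != current)
      stop(sprintf(
        "metapath chain broken between '%s' and '%s': similarity is over %s nodes but chain is at %s",
        prevName, relName, ty, current))
    S <- net@similarities[[relName]]
    if (is.null(S))
      stop(sprintf("network has no similarity matrix '%s'", relName))
    M <- (S >= simThreshold) * 1
    diag(M) <- 0
    return(list(M = M, to = ty))
  }
  M <- relation(net, relName)
  ty <- .REL_TYPES[[relName]]
  if (ty[1] == current) {
    list(M = M, to = ty[2])
  } else if (ty[2] == current) {
    list(M = t(M), to = ty[1])
  } else {
    stop(sprintf(
      "metapath chain broken between '%s' and '%s': relation connects %s-%s but chain is at %s",
      prevName, relName, ty[1], ty[2], current))
  }
}

#' Compose a metapath into a neighbour graph
#'
#' Multiplies the chain's relation matrices (resolving the orientation of
#' each step automatically), booleanizes the product, zeroes the diagonal,
#' and optionally adds self-loops. Node i's metapath neighbours are the
#' nonzeros of row i; multiplicities (path counts) are discarded because the
#' neighbour set is a set.
#'
#' @param net a [HeteroNetwork-class].
#' @param mp a [Metapath-class].
#' @param selfLoops add the identity after zeroing the diagonal
#'   (default TRUE, so isolated nodes still aggregate their own features).
#' @return a [MetapathGraph-class].
#' @export
composeMetapath <- function(net, mp, selfLoops = TRUE) {
  stopifnot(is(net, "HeteroNetwork"), is(mp, "Metapath"))
  validObject(mp)
  current <- mp@anchor
  P <- NULL
  prevName <- sprintf("<%s anchor>", mp@anchor)
  for (relName in mp@chain) {
    step <- .resolveStep(net, relName, current, mp@simThreshold, prevName)
    P <- if (is.null(P)) step$M else P %*% step$M
    current <- step$to
    prevName <- relName
  }
  if (current != mp@anchor)
    stop(sprintf("metapath '%s' ends at %s, not its anchor type %s",
                 mp@name, current, mp@anchor))
  A <- (P > 0) * 1
  diag(A) <- 0
  if (selfLoops) diag(A) <- 1
  new("MetapathGraph", metapath = mp, adjacency = A, selfLoops = selfLoops)
}

#' Merge metapath neighbour graphs by boolean union
#'
#' Elementwise union of the adjacencies of several metapath graphs over the
#' same anchor node set, giving the combined neighbour graph.
#'
#' @param graphs list of [MetapathGraph-class] objects sharing anchor type
#'   and dimension.
#' @return a [MetapathGraph-class] named `"merged"`.
#' @export
mergeNeighborGraphs <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  anchors <- vapply(graphs, anchorType, character(1))
  if (length(unique(anchors)) != 1)
    stop("cannot merge graphs with mixed anchor types: ",
         paste(unique(anchors), collapse = ", "))
  dims <- vapply(graphs, function(g) nrow(g@adjacency), integer(1))
  if (length(unique(dims)) != 1)
    stop("cannot merge graphs of different dimension")
  A <- Reduce(`+`, lapply(graphs, adjacency))
  A <- (A > 0) * 1
  mp <- Metapath("merged", anchors[1], graphs[[1]]@metapath@chain)
  new("MetapathGraph", metapath = mp, adjacency = A,
      selfLoops = any(vapply(graphs, function(g) g@selfLoops, logical(1))))
}

#' Initial node features
#'
#' Each node's initial feature vector concatenates its similarity profile
#' and its interaction profile: for drugs, the drug-drug similarity row
#' (identity if no similarity matrix is present) followed by the drug-target
#' interaction row, giving an `n_drugs x (n_drugs + n_targets)` matrix;
#' symmetrically for targets.
#'
#' @param net a [HeteroNetwork-class].
#' @param nodeType `"drug"` or `"target"`.
#' @return numeric feature matrix, one row per node.
#' @export
initialFeatures <- function(net, nodeType = c("drug", "target")) {
  nodeType <- match.arg(nodeType)
  DT <- relation(net, "drug_target")
  if (nodeType == "drug") {
    S <- similarity(net, "drug_sim")
    if (is.null(S)) S <- diag(nDrugs(net))
    cbind(S, DT)
  } else {
    S <- similarity(net, "target_sim")
    if (is.null(S)) S <- diag(nTargets(net))
    cbind(S, t(DT))
  }
}

#' Build the per-metapath graphs for one node type
#'
#' Convenience wrapper: composes every metapath in a set against the
#' network. Metapaths whose required similarity matrix is absent are
#' dropped with a message (the remaining set must be non-empty).
#'
#' @inheritParams composeMetapath
#' @param metapaths list of [Metapath-class]; default [defaultMetapaths()].
#' @param anchor node type used when `metapaths` is NULL.
#' @return named list of [MetapathGraph-class].
#' @export
metapathGraphs <- function(net, anchor = c("drug", "target"),
                           metapaths = NULL, selfLoops = TRUE) {
  anchor <- match.arg(anchor)
  if (is.null(metapaths)) metapaths <- defaultMetapaths(anchor)
  out <- list()
  for (mp in metapaths) {
    needsSim <- intersect(mp@chain, names(.SIM_TYPES))
    if (length(needsSim) && any(vapply(needsSim, function(s)
      is.null(net@similarities[[s]]), logical(1)))) {
      message(sprintf("dropping metapath '%s': similarity matrix absent",
                      mp@name))
      next
    }
    out[[mp@name]] <- composeMetapath(net, mp, selfLoops = selfLoops)
  }
  if (!length(out)) stop("no usable metapaths for anchor type ", anchor)
  out
}
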