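#' @import methods
NULL

## Relation registry: row/column node type of every canonical relation.
.REL_TYPES <- list(
  drug_drug       = c("drug", "drug"),
  drug_target     = c("drug", "target"),
  drug_disease    = c("drug", "disease"),
  drug_sideeffect = c("drug", "sideeffect"),
  target_target   = c("target", "target"),
  target_disease  = c("target", "disease")
)

.SIM_TYPES <- list(drug_sim = "drug", target_sim = "target")

.NODE_TYPES <- c("drug", "target", "disease", "sideeffect")

#' HeteroNetwork: a typed heterogeneous biomedical network
#'
#' Container for the four node sets (drugs, target proteins, diseases,
#' side effects), their binary relation matrices and optional dense
#' similarity matrices. This object is the single source of truth for the
#' graph structure every downstream stage consumes.
#'
#' Relations are stored under canonical names: `drug_drug`, `drug_target`,
#' `drug_disease`, `drug_sideeffect`, `target_target`, `target_disease`.
#' Within-type relations must be symmetric with zero diagonal; all relation
#' matrices are binary 0/1. Similarities (`drug_sim`, `target_sim`) are
#' symmetric, valued in `[0, 1]`, with unit diagonal.
#'
#' @slot counts named integer vector with entries `drug`, `target`,
#'   `disease`, `sideeffect`.
#' @slot relations named list of binary matrices.
#' @slot similarities named list of similarity matrices (possibly empty).
#' @slot nodeIds named list of character vectors giving external node
#'   identifiers per node type (mapping by position).
#' @exportClass HeteroNetwork
setClass("HeteroNetwork",
  slots = c(
    counts = "integer",
    relations = "list",
    similarities = "list",
    nodeIds = "list"
  )
)

setValidity("HeteroNetwork", function(object) {
  msgs <- character(0)
  cnt <- object@counts
  if (!all(.NODE_TYPES %in% names(cnt)))
    return("counts must be named with drug, target, disease, sideeffect")
  if (any(cnt < 0L)) msgs <- c(msgs, "node counts must be non-negative")
  for (nm in names(object@relations)) {
    if (!nm %in% names(.REL_TYPES)) {
      msgs <- c(msgs, sprintf("unknown relation '%s'", nm)); next
    }
    M <- object@relations[[nm]]
    ty <- .REL_TYPES[[nm]]
    if (nrow(M) != cnt[[ty[1]]] || ncol(M) != cnt[[ty[2]]])
      msgs <- c(msgs, sprintf(
        "relation '%s' is %dx%d but node counts imply %dx%d",
        nm, nrow(M), ncol(M), cnt[[ty[1]]], cnt[[ty[2]]]))
    if (length(M) && !all(M %in% c(0, 1)))
      msgs <- c(msgs, sprintf("relation '%s' is not binary", nm))
    if (ty[1] == ty[2] && length(M)) {
      if (!isTRUE(all.equal(M, t(M))))
        msgs <- c(msgs, sprintf("within-type relation '%s' is not symmetric", nm))
      if (any(diag(M) != 0))
        msgs <- c(msgs, sprintf("within-type relation '%s' has nonzero diagonal", nm))
    }
  }
  for (nm in names(object@similarities)) {
    if (!nm %in% names(.SIM_TYPES)) {
      msgs <- c(msgs, sprintf("unknown similarity '%s'", nm)); next
    }
    S <- object@similarities[[nm]]
    n <- cnt[[.SIM_TYPES[[nm]]]]
    if (nrow(S) != n || ncol(S) != n)
      msgs <- c(msgs, sprintf("similarity '%s' has wrong dimension", nm))
    else {
      if (!isTRUE(all.equal(S, t(S))))
        msgs <- c(msgs, sprintf("similarity '%s' is not symmetric", nm))
      if (any(S < 0 | S > 1))
        msgs <- c(msgs, sprintf("similarity '%s' has values outside [0,1]", nm))
      if (!isTRUE(all.equal(unname(diag(S)), rep(1, n))))
        msgs <- c(msgs, sprintf("similarity '%s' diagonal is not 1", nm))
    }
  }
  for (ty in .NODE_TYPES) {
    ids <- object@nodeIds[[ty]]
    if (!is.null(ids) && length(ids) != cnt[[ty]])
      msgs <- c(msgs, sprintf("nodeIds for '%s' have wrong length", ty))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a HeteroNetwork
#'
#' @param relations named list of binary relation matrices (canonical names,
#'   see [HeteroNetwork-class]).
#' @param similarities optional named list with `drug_sim` and/or
#'   `target_sim`.
#' @param nodeIds optional named list of character identifiers per node type;
#'   defaults are generated (`DR...`, `TA...`, `DI...`, `SE...`).
#' @return a validated `HeteroNetwork`.
#' @export
HeteroNetwork <- function(relations, similarities = list(), nodeIds = NULL) {
  counts <- integer(length(.NODE_TYPES))
  names(counts) <- .NODE_TYPES
  seen <- setNames(rep(FALSE, length(.NODE_TYPES)), .NODE_TYPES)
  note <- function(ty, n) {
    if (!seen[[ty]]) {
      counts[[ty]] <<- as.integer(n); seen[[ty]] <<- TRUE
    } else if (counts[[ty]] != n) {
      stop(sprintf("inconsistent %s count: %d vs %d", ty, counts[[ty]], n))
    }
  }
  for (nm in names(relations)) {
    if (!nm %in% names(.REL_TYPES)) stop(sprintf("unknown relation '%s'", nm))
    ty <- .REL_TYPES[[nm]]
    relations[[nm]] <- unname(as.matrix(relations[[nm]])) * 1
    note(ty[1], nrow(relations[[nm]]))
    note(ty[2], ncol(relations[[nm]]))
  }
  for (nm in names(similarities)) {
    similarities[[nm]] <- unname(as.matrix(similarities[[nm]]))
    note(.SIM_TYPES[[nm]], nrow(similarities[[nm]]))
  }
  if (is.null(nodeIds)) nodeIds <- list()
  pfx <- c(drug = "DR", target = "TA", disease = "DI", sideeffect = "SE")
  for (ty in .NODE_TYPES) {
    if (is.null(nodeIds[[ty]]))
      nodeIds[[ty]] <- sprintf("%s%04d", pfx[[ty]], seq_len(counts[[ty]]))
  }
  new("HeteroNetwork", counts = counts, relations = relations,
      similarities = similarities, nodeIds = nodeIds[.NODE_TYPES])
}

#' Metapath: a composite relation over the heterogeneous network
#'
#' An ordered chain of canonical relation names whose composition starts and
#' ends at the anchor node type (drug or target). Each step may be traversed
#' forward or reversed; the orientation is resolved automatically from the
#' relation registry when the chain is composed against a network. The
#' pseudo-relations `drug_sim` / `target_sim` denote the corresponding
#' similarity matrix thresholded into a binary within-type relation.
#'
#' @slot name display name, e.g. `"r-d-r"`.
#' @slot anchor `"drug"` or `"target"`.
#' @slot chain character vector of relation names.
#' @slot simThreshold threshold applied when a similarity pseudo-relation
#'   appears in the chain.
#' @exportClass Metapath
setClass("Metapath",
  slots = c(name = "character", anchor = "character", chain = "character",
            simThreshold = "numeric"),
  prototype = prototype(simThreshold = 0.5)
)

setValidity("Metapath", function(object) {
  msgs <- character(0)
  if (!object@anchor %in% c("drug", "target"))
    msgs <- c(msgs, "anchor must be 'drug' or 'target'")
  known <- c(names(.REL_TYPES), names(.SIM_TYPES))
  bad <- setdiff(object@chain, known)
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown relation(s) in chain: %s",
                            paste(bad, collapse = ", ")))
  if (length(object@chain) < 1) msgs <- c(msgs, "chain must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' @rdname Metapath-class
#' @param name,anchor,chain,simThreshold see slots.
#' @export
Metapath <- function(name, anchor, chain, simThreshold = 0.5) {
  new("Metapath", name = name, anchor = anchor, chain = chain,
      simThreshold = simThreshold)
}

#' MetapathGraph: homogeneous neighbour graph induced by one metapath
#'
#' Binary adjacency over the anchor node set. Entry (i, j) is 1 iff at least
#' one instance of the metapath connects i and j (path multiplicities are
#' discarded; metapath neighbours form a set). Self-loops are added by
#' default so isolated nodes still aggregate their own features.
#'
#' @slot metapath the inducing [Metapath-class].
#' @slot adjacency binary square matrix.
#' @slot selfLoops whether self-loops were added.
#' @exportClass MetapathGraph
setClass("MetapathGraph",
  slots = c(metapath = "Metapath", adjacency = "matrix", selfLoops = "logical")
)

setValidity("MetapathGraph", function(object) {
  A <- object@adjacency
  msgs <- character(0)
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "adjacency must be square")
  if (length(A) && !all(A %in% c(0, 1)))
    msgs <- c(msgs, "adjacency must be binary")
  if (length(msgs)) msgs else TRUE
})

#' DTIModel: a trained drug-target interaction model
#'
#' Holds the learned parameters of every stage (per-metapath attention and
#' convolution encoders, fusion attention, low-rank projection factors), the
#' fused embeddings, the full score matrix and the training loss trajectory.
#'
#' @slot params nested list of parameter arrays for both node-type sides.
#' @slot config the run configuration used for training.
#' @slot lossTrajectory per-epoch training loss.
#' @slot metapathWeights named list (`drug`, `target`) of learned
#'   metapath-level attention weights.
#' @slot X fused drug embeddings (drugs x width).
#' @slot Y fused target embeddings (targets x width).
#' @slot S full drug x target score matrix.
#' @slot mu class-imbalance weight computed from the training split.
#' @slot heldoutDrugs integer indices of drugs whose interaction rows were
#'   hidden from training (empty if trained on everything).
#' @exportClass DTIModel
setClass("DTIModel",
  slots = c(params = "list", config = "list", lossTrajectory = "numeric",
            metapathWeights = "list", X = "matrix", Y = "matrix",
            S = "matrix", mu = "numeric", heldoutDrugs = "integer")
)

#' EvalReport: results of the cross-validated evaluation protocol
#'
#' @slot auroc pooled (micro-averaged) area under the ROC curve.
#' @slot aupr pooled area under the precision-recall curve.
#' @slot mcc Matthews correlation coefficient of the thresholded scores.
#' @slot macroAuroc mean of per-drug AUROCs.
#' @slot macroAupr mean of per-drug AUPRs.
#' @slot perDrug data.frame with one row per evaluable drug (drug id, index,
#'   number of positives, auroc, aupr, coverage, recall@k columns).
#' @slot recallAtK named numeric, mean per-drug recall among the top k\% of
#'   each drug's candidates.
#' @slot coverage mean per-drug coverage (candidates inspected until every
#'   known target is retrieved).
#' @slot thresholdTable data.frame of the fraction of drugs whose AUROC/AUPR
#'   exceeds each threshold delta.
#' @slot nDrugsSkipped drugs excluded from per-drug averages (no positives).
#' @slot labels pooled test labels (for curve export).
#' @slot scores pooled test scores.
#' @slot folds fold assignment used.
#' @exportClass EvalReport
setClass("EvalReport",
  slots = c(auroc = "numeric", aupr = "numeric", mcc = "numeric",
            macroAuroc = "numeric", macroAupr = "numeric",
            perDrug = "data.frame", recallAtK = "numeric",
            coverage = "numeric", thresholdTable = "data.frame",
            nDrugsSkipped = "integer", labels = "numeric",
            scores = "numeric", folds = "integer")
)

setMethod("show", "HeteroNetwork", function(object) {
  cnt <- object@counts
  cat(sprintf(
    "HeteroNetwork: %d drugs, %d targets, %d diseases, %d side effects\n",
    cnt[["drug"]], cnt[["target"]], cnt[["disease"]], cnt[["sideeffect"]]))
  for (nm in names(object@relations))
    cat(sprintf("  relation %-16s %6d edges\n", nm,
                as.integer(sum(object@relations[[nm]])) %/%
                  (if (.REL_TYPES[[nm]][1] == .REL_TYPES[[nm]][2]) 2L else 1L)))
  if (length(object@similarities))
    cat("  similarities:", paste(names(object@similarities), collapse = ", "),
        "\n")
})

setMethod("show", "MetapathGraph", function(object) {
  A <- object@adjacency
  offdiag <- sum(A) - sum(diag(A))
  cat(sprintf("MetapathGraph '%s' (%s anchor): %d nodes, %d edges%s\n",
              object@metapath@name, object@metapath@anchor, nrow(A),
              as.integer(offdiag / 2),
              if (object@selfLoops) " (+self-loops)" else ""))
})

setMethod("show", "DTIModel", function(object) {
  cat(sprintf("DTIModel: %d drugs x %d targets, rank %d, %d epochs\n",
              nrow(object@S), ncol(object@S), object@config$rank,
              length(object@lossTrajectory)))
  if (length(object@lossTrajectory))
    cat(sprintf("  final loss %.6g (initial %.6g)\n",
                utils::tail(object@lossTrajectory, 1),
                object@lossTrajectory[1]))
  for (side in c("drug", "target")) {
    w <- object@metapathWeights[[side]]
    if (is.null(w)) next
    cat(sprintf("  %s metapath attention: %s\n", side,
                paste(sprintf("%s=%.3f", names(w), w), collapse = " ")))
  }
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (drug-wise cross-validation)\n")
  cat(sprintf("  pooled AUROC %.4f  AUPR %.4f  MCC %.4f\n",
              object@auroc, object@aupr, object@mcc))
  cat(sprintf("  macro AUROC %.4f  AUPR %.4f  (over %d drugs, %d skipped)\n",
              object@macroAuroc, object@macroAupr, nrow(object@perDrug),
              object@nDrugsSkipped))
  cat(sprintf("  mean coverage %.1f\n", object@coverage))
  cat("  recall@k%:", paste(sprintf("%s=%.3f", names(object@recallAtK),
                                    object@recallAtK), collapse = " "), "\n")
})

## --- accessors ---------------------------------------------------------

#' @describeIn HeteroNetwork-class number of drugs
#' @param net a `HeteroNetwork`
#' @export
nDrugs <- function(net) net@counts[["drug"]]

#' @describeIn HeteroNetwork-class number of target proteins
#' @export
nTargets <- function(net) net@counts[["target"]]

#' @describeIn HeteroNetwork-class number of diseases
#' @export
nDiseases <- function(net) net@counts[["disease"]]

#' @describeIn HeteroNetwork-class number of side effects
#' @export
nSideEffects <- function(net) net@counts[["sideeffect"]]

#' @describeIn HeteroNetwork-class one relation matrix by canonical name
#' @param name canonical relation name
#' @export
relation <- function(net, name) {
  if (!name %in% names(net@relations))
    stop(sprintf("network has no relation '%s'", name))
  net@relations[[name]]
}

#' @describeIn HeteroNetwork-class one similarity matrix (or NULL)
#' @export
similarity <- function(net, name) net@similarities[[name]]

#' @describeIn HeteroNetwork-class node identifiers for one node type
#' @param type node type
#' @export
nodeIds <- function(net, type) net@nodeIds[[type]]

#' @describeIn MetapathGraph-class adjacency matrix of a metapath graph
#' @param graph a `MetapathGraph`
#' @export
adjacency <- function(graph) graph@adjacency

#' @describeIn MetapathGraph-class anchor node type of a metapath graph
#' @export
anchorType <- function(graph) graph@metapath@anchor

#' @describeIn DTIModel-class full drug x target score matrix
#' @param model a `DTIModel`
#' @export
scoreMatrix <- function(model) model@S

#' @describeIn DTIModel-class fused embeddings as a list(X, Y)
#' @export
embeddings <- function(model) list(X = model@X, Y = model@Y)

#' @describeIn DTIModel-class per-epoch training loss
#' @export
lossTrajectory <- function(model) model@lossTrajectory

#' @describeIn DTIModel-class learned metapath attention weights
#' @export
metapathAttention <- function(model) model@metapathWeights
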