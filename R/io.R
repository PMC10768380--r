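## File formats: TSV edge lists (source_id <TAB> target_id) or MatrixMarket
## sparse matrices per relation, dense TSV per similarity matrix, one ID
## file per node type. Node identifiers are arbitrary strings mapped to
## 0-based internal indices by first appearance; the mapping is persisted
## via the ID files.

.ID_FILES <- c(drug = "drug_ids.txt", target = "target_ids.txt",
               disease = "disease_ids.txt", sideeffect = "sideeffect_ids.txt")

#' Write a heterogeneous network to a directory
#'
#' One edge-list TSV (or MatrixMarket file) per relation, one dense TSV per
#' similarity matrix (ID header row and column), one ID file per node type,
#' and a small JSON manifest with the node counts.
#'
#' @param net a [HeteroNetwork-class].
#' @param dir output directory (created if missing).
#' @param format `"tsv"` edge lists or `"mtx"` MatrixMarket.
#' @return `dir`, invisibly.
#' @export
writeHeteroNetwork <- function(net, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ty in .NODE_TYPES)
    writeLines(nodeIds(net, ty), file.path(dir, .ID_FILES[[ty]]))
  for (nm in names(net@relations)) {
    M <- net@relations[[nm]]
    ty <- .REL_TYPES[[nm]]
    if (format == "tsv") {
      idx <- which(M == 1, arr.ind = TRUE)
      df <- data.frame(source = nodeIds(net, ty[1])[idx[, 1]],
                       target = nodeIds(net, ty[2])[idx[, 2]])
      utils::write.table(df, file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    } else {
      Matrix::writeMM(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                  "generalMatrix"),
                      file.path(dir, paste0(nm, ".mtx")))
    }
  }
  for (nm in names(net@similarities)) {
    S <- net@similarities[[nm]]
    ids <- nodeIds(net, .SIM_TYPES[[nm]])
    dimnames(S) <- list(ids, ids)
    utils::write.table(S, file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  manifest <- list(counts = as.list(net@counts), format = format,
                   relations = names(net@relations),
                   similarities = names(net@similarities))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a heterogeneous network from a directory
#'
#' Counterpart of [writeHeteroNetwork()]; relies on the ID files for node
#' counts and identifier-to-index mapping, so isolated nodes survive the
#' round trip.
#'
#' @param dir directory written by [writeHeteroNetwork()].
#' @return a [HeteroNetwork-class].
#' @export
readHeteroNetwork <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath))
    stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  ids <- list()
  for (ty in .NODE_TYPES) {
    p <- file.path(dir, .ID_FILES[[ty]])
    ids[[ty]] <- if (file.exists(p)) readLines(p) else character(0)
  }
  relations <- list()
  for (nm in manifest$relations) {
    ty <- .REL_TYPES[[nm]]
    nr <- length(ids[[ty[1]]]); nc <- length(ids[[ty[2]]])
    tsv <- file.path(dir, paste0(nm, ".tsv"))
    mtx <- file.path(dir, paste0(nm, ".mtx"))
    if (file.exists(tsv)) {
      M <- matrix(0, nr, nc)
      if (file.size(tsv) > 0) {
        df <- utils::read.table(tsv, sep = "\t", header = FALSE,
                                colClasses = "character")
        ri <- match(df[[1]], ids[[ty[1]]])
        ci <- match(df[[2]], ids[[ty[2]]])
        if (anyNA(ri) || anyNA(ci))
          stop(sprintf("relation '%s' references unknown node identifiers", nm))
        M[cbind(ri, ci)] <- 1
        if (ty[1] == ty[2]) M[cbind(ci, ri)] <- 1
      }
    } else if (file.exists(mtx)) {
      M <- as.matrix(Matrix::readMM(mtx)) * 1
      if (!all(dim(M) == c(nr, nc)))
        stop(sprintf("relation '%s' has dimensions %dx%d, expected %dx%d",
                     nm, nrow(M), ncol(M), nr, nc))
    } else {
      stop(sprintf("missing relation file for '%s' (looked for %s and %s)",
                   nm, basename(tsv), basename(mtx)))
    }
    if (ty[1] == ty[2]) diag(M) <- 0
    relations[[nm]] <- M
  }
  similarities <- list()
  for (nm in manifest$similarities) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(p)) stop("missing similarity file for '", nm, "'")
    S <- as.matrix(utils::read.table(p, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    ord <- match(ids[[.SIM_TYPES[[nm]]]], rownames(S))
    similarities[[nm]] <- unname(S[ord, ord])
  }
  HeteroNetwork(relations, similarities, nodeIds = ids)
}

#' Export a metapath graph as MatrixMarket + ID file
#'
#' @param graph a [MetapathGraph-class].
#' @param ids node identifiers for the anchor node set.
#' @param path output path stem; writes `<path>.mtx` and `<path>_ids.txt`.
#' @return `path`, invisibly.
#' @export
writeMetapathGraph <- function(graph, ids, path) {
  A <- adjacency(graph)
  stopifnot(length(ids) == nrow(A))
  Matrix::writeMM(methods::as(Matrix::Matrix(A, sparse = TRUE),
                              "generalMatrix"),
                  paste0(path, ".mtx"))
  writeLines(ids, paste0(path, "_ids.txt"))
  invisible(path)
}
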