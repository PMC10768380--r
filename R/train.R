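## End-to-end training: both encoder channels, fusion attention and the
## low-rank completion head are optimised jointly by reverse-mode gradients
## written out layer by layer, with adaptive moment estimation (Adam).

## --- parameter-tree utilities ------------------------------------------

.treeMap <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a))
      out[[i]] <- do.call(.treeMap, c(list(f), lapply(trees, `[[`, i)))
    out
  } else {
    do.call(f, trees)
  }
}

.zeroLike <- function(tree) .treeMap(function(x) x * 0, tree)

.adamInit <- function(params) list(m = .zeroLike(params), v = .zeroLike(params))

.adamStep <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  ## bias-corrected step folded into two scalars:
  ## p - lr (m/bc1) / (sqrt(v/bc2) + eps) = p - lr' m / (sqrt(v) + eps')
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  lr2 <- lr * sqrt(bc2) / bc1
  eps2 <- eps * sqrt(bc2)
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- step(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r[[1]]; m[[i]] <- r[[2]]; v[[i]] <- r[[3]]
      }
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr2 * m / (sqrt(v) + eps2)
    }
    list(p, m, v)
  }
  r <- step(params, grads, state$m, state$v)
  list(params = r[[1]], state = list(m = r[[2]], v = r[[3]]))
}

## --- one node-type side ------------------------------------------------

.initSideParams <- function(metapathNames, dIn, cfg) {
  width <- cfg$nHeads * cfg$headDim
  list(
    gat = .initGATParams(metapathNames, dIn, cfg$headDim, cfg$nHeads,
                         cfg$gatLayers),
    gcn = .initGCNParams(metapathNames, dIn, width, cfg$gcnResBlocks),
    fusion = .initFusionParams(width, cfg$attDim)
  )
}

.drawDropout <- function(adjs, dIn, n, cfg) {
  p <- cfg$dropout
  if (p <= 0) return(NULL)
  keep <- function(nr, nc)
    matrix(stats::rbinom(nr * nc, 1, 1 - p), nr, nc) / (1 - p)
  att <- NULL
  if (cfg$channels != "gcn") {
    att <- lapply(adjs, function(a)
      lapply(seq_len(cfg$gatLayers), function(li)
        lapply(seq_len(cfg$nHeads), function(k) keep(nrow(a), ncol(a)))))
  }
  list(input = keep(n, dIn), att = att)
}

.sideForward <- function(Fmat, adjs, Anorms, sp, cfg, drop = NULL) {
  Fuse <- if (is.null(drop)) Fmat else Fmat * drop$input
  gatEmbs <- NULL; gatCaches <- NULL
  if (cfg$channels != "gcn") {
    gatEmbs <- list(); gatCaches <- list()
    for (nm in names(adjs)) {
      H <- Fuse
      layerCaches <- list()
      for (li in seq_along(sp$gat[[nm]])) {
        masks <- if (is.null(drop)) NULL else drop$att[[nm]][[li]]
        fw <- .gatLayerForward(adjs[[nm]], H, sp$gat[[nm]][[li]],
                               cfg$activation, cfg$leakySlope, masks)
        layerCaches[[li]] <- list(Hin = H, cache = fw$caches)
        H <- fw$H
      }
      gatEmbs[[nm]] <- H
      gatCaches[[nm]] <- layerCaches
    }
  }
  gcnEmbs <- NULL; gcnCaches <- NULL
  if (cfg$channels != "gat") {
    gcnEmbs <- list(); gcnCaches <- list()
    for (nm in names(adjs)) {
      fw <- .rgcnForward(Anorms[[nm]], Fuse, sp$gcn[[nm]], cfg$activation)
      gcnEmbs[[nm]] <- fw$H
      gcnCaches[[nm]] <- fw$cache
    }
  }
  fus <- .fusionForward(sp$fusion, gatEmbs, gcnEmbs, cfg$channels)
  list(X = fus$X, weights = fus$weights, Fuse = Fuse,
       gatEmbs = gatEmbs, gatCaches = gatCaches,
       gcnEmbs = gcnEmbs, gcnCaches = gcnCaches, fusion = fus)
}

.sideBackward <- function(fwd, adjs, Anorms, sp, cfg, dX, drop = NULL) {
  fb <- .fusionBackward(sp$fusion, fwd$gatEmbs, fwd$gcnEmbs, fwd$fusion,
                        dX, cfg$channels)
  grads <- list(gat = .zeroLike(sp$gat), gcn = .zeroLike(sp$gcn),
                fusion = list(Wf = fb$Wf, b = fb$b, q = fb$q))
  if (cfg$channels != "gcn") {
    for (nm in names(adjs)) {
      dH <- fb$dGat[[nm]]
      for (li in rev(seq_along(sp$gat[[nm]]))) {
        lc <- fwd$gatCaches[[nm]][[li]]
        masks <- if (is.null(drop)) NULL else drop$att[[nm]][[li]]
        bk <- .gatLayerBackward(adjs[[nm]], lc$Hin, sp$gat[[nm]][[li]],
                                lc$cache, dH, cfg$activation, cfg$leakySlope,
                                masks)
        grads$gat[[nm]][[li]] <- bk$heads
        dH <- bk$dH
      }
    }
  }
  if (cfg$channels != "gat") {
    for (nm in names(adjs)) {
      grads$gcn[[nm]] <- .rgcnBackward(Anorms[[nm]], fwd$Fuse, sp$gcn[[nm]],
                                       fwd$gcnCaches[[nm]], fb$dGcn[[nm]],
                                       cfg$activation)
    }
  }
  grads
}

## --- the trainer -------------------------------------------------------

#' Train a drug-target interaction model
#'
#' Builds the per-metapath neighbour graphs and initial features from the
#' network (with the held-out drugs' interaction rows hidden), then trains
#' the attention channel, the residual convolution channel, the
#' metapath-level fusion and the projection factors end-to-end against the
#' imbalance-weighted completion loss. Deterministic given
#' `config$seed`.
#'
#' @param net a [HeteroNetwork-class].
#' @param config run configuration from [defaultRunConfig()].
#' @param heldoutDrugs integer drug indices whose interaction rows are
#'   excluded from the training loss, the imbalance weight and the graph /
#'   feature construction (drug-wise cross-validation).
#' @param heldoutPairs optional 2-column matrix of (drug, target) pairs to
#'   exclude from the loss instead of whole rows (pair-wise mode).
#' @param drugMetapaths,targetMetapaths optional metapath sets (default
#'   [defaultMetapaths()]).
#' @return a [DTIModel-class].
#' @export
trainDTIModel <- function(net, config = defaultRunConfig(),
                          heldoutDrugs = integer(0), heldoutPairs = NULL,
                          drugMetapaths = NULL, targetMetapaths = NULL) {
  .validateRunConfig(config)
  set.seed(config$seed)
  m <- nDrugs(net); n <- nTargets(net)
  Tfull <- relation(net, "drug_target")
  heldoutDrugs <- as.integer(heldoutDrugs)

  ## hide held-out drugs' interactions from everything the model sees
  netTrain <- net
  if (length(heldoutDrugs)) {
    DT <- netTrain@relations$drug_target
    DT[heldoutDrugs, ] <- 0
    netTrain@relations$drug_target <- DT
  }

  mask <- matrix(1, m, n)
  if (length(heldoutDrugs)) mask[heldoutDrugs, ] <- 0
  if (!is.null(heldoutPairs)) mask[heldoutPairs] <- 0
  mu <- imbalanceWeight(Tfull, mask)

  graphsD <- metapathGraphs(netTrain, "drug", drugMetapaths,
                            selfLoops = config$selfLoops)
  graphsT <- metapathGraphs(netTrain, "target", targetMetapaths,
                            selfLoops = config$selfLoops)
  adjsD <- lapply(graphsD, adjacency)
  adjsT <- lapply(graphsT, adjacency)
  AnD <- lapply(adjsD, normalizeAdjacency)
  AnT <- lapply(adjsT, normalizeAdjacency)
  FD <- initialFeatures(netTrain, "drug")
  FT <- initialFeatures(netTrain, "target")

  width <- config$nHeads * config$headDim
  params <- list(
    drug = .initSideParams(names(graphsD), ncol(FD), config),
    target = .initSideParams(names(graphsT), ncol(FT), config),
    Z1 = .glorotMat(width, config$rank),
    Z2 = .glorotMat(width, config$rank)
  )

  state <- .adamInit(params)
  losses <- numeric(config$epochs)
  attLog <- list(drug = NULL, target = NULL)

  for (epoch in seq_len(config$epochs)) {
    dropD <- .drawDropout(adjsD, ncol(FD), m, config)
    dropT <- .drawDropout(adjsT, ncol(FT), n, config)
    epochMask <- mask
    if (isTRUE(config$pairSampling)) {
      ## optional minibatch mode: the loss sees batchSize positives and a
      ## proportional draw of negatives each epoch
      trainable <- which(mask > 0)
      pos <- trainable[Tfull[trainable] == 1]
      neg <- trainable[Tfull[trainable] == 0]
      bp <- min(config$batchSize, length(pos))
      bn <- min(length(neg), ceiling(bp / mu))
      sel <- c(sample(pos, bp), sample(neg, bn))
      epochMask <- matrix(0, m, n)
      epochMask[sel] <- 1
    }

    fwdD <- .sideForward(FD, adjsD, AnD, params$drug, config, dropD)
    fwdT <- .sideForward(FT, adjsT, AnT, params$target, config, dropT)
    g <- imcGradients(Tfull, fwdD$X, fwdT$X, params$Z1, params$Z2,
                      config$alpha, mu, epochMask)
    losses[epoch] <- g$loss
    if (!is.finite(g$loss))
      stop(sprintf("training diverged: loss is not finite at epoch %d", epoch))

    grads <- list(
      drug = .sideBackward(fwdD, adjsD, AnD, params$drug, config, g$X, dropD),
      target = .sideBackward(fwdT, adjsT, AnT, params$target, config, g$Y,
                             dropT),
      Z1 = g$Z1, Z2 = g$Z2
    )
    upd <- .adamStep(params, grads, state, config$learningRate, epoch)
    params <- upd$params
    state <- upd$state
    attLog$drug <- rbind(attLog$drug, fwdD$weights)
    attLog$target <- rbind(attLog$target, fwdT$weights)
  }

  ## dropout-free evaluation pass with the final parameters
  fwdD <- .sideForward(FD, adjsD, AnD, params$drug, config)
  fwdT <- .sideForward(FT, adjsT, AnT, params$target, config)
  S <- imcScoreMatrix(fwdD$X, fwdT$X, params$Z1, params$Z2)

  new("DTIModel", params = params, config = config,
      lossTrajectory = losses,
      metapathWeights = list(drug = fwdD$weights, target = fwdT$weights,
                             trajectory = attLog),
      X = fwdD$X, Y = fwdT$X, S = S, mu = mu, heldoutDrugs = heldoutDrugs)
}

.glorotMat <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}
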