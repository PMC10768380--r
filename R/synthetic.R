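## Seeded generator of synthetic heterogeneous networks with a planted
## low-rank drug-target signal, emulating the structure of real DTI
## reference data (sparse binary relations, severe positive/negative
## imbalance, auxiliary associations correlated with the interaction
## signal) at desk scale.

#' Synthetic network configuration
#'
#' Defaults describe the package's standard study fixture: 60 drugs, 90
#' targets, rank-4 latent signal, ~1:100 positive-to-negative imbalance,
#' noiseless labels. Auxiliary relation densities are per-pair edge
#' probabilities; auxiliary edges are drawn with probability increasing in
#' latent similarity so the metapath encoders have genuine signal to learn
#' (set `auxSignal = FALSE` for the pure-noise ablation variant).
#'
#' @param nDrugs,nTargets,nDiseases,nSideEffects node counts.
#' @param latentRank rank of the planted signal.
#' @param positiveRate fraction of drug-target pairs made positive.
#' @param relationDensities named per-relation edge probabilities.
#' @param noiseFlipRate probability of flipping an interaction label.
#' @param auxSignal couple auxiliary relations to the latent factors.
#' @param seed integer seed.
#' @return named list.
#' @export
synthConfig <- function(nDrugs = 60, nTargets = 90, nDiseases = 30,
                        nSideEffects = 20, latentRank = 4,
                        positiveRate = 0.01,
                        relationDensities = c(drug_drug = 0.08,
                                              drug_disease = 0.06,
                                              drug_sideeffect = 0.06,
                                              target_target = 0.08,
                                              target_disease = 0.06),
                        noiseFlipRate = 0, auxSignal = TRUE, seed = 1) {
  cfg <- list(nDrugs = nDrugs, nTargets = nTargets, nDiseases = nDiseases,
              nSideEffects = nSideEffects, latentRank = latentRank,
              positiveRate = positiveRate,
              relationDensities = relationDensities,
              noiseFlipRate = noiseFlipRate, auxSignal = auxSignal,
              seed = as.integer(seed))
  probs <- c(positiveRate, noiseFlipRate, relationDensities)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (round(positiveRate * nDrugs * nTargets) < 1)
    stop("configuration yields zero positive interactions")
  cfg
}

.cosineRows <- function(A, B) {
  An <- A / sqrt(rowSums(A^2))
  Bn <- B / sqrt(rowSums(B^2))
  An %*% t(Bn)
}

## Bernoulli edges with probability density * (1 + gamma * cosine),
## clipped to [0, 1]; mean probability stays ~density because cosines of
## independent latent factors are centred at 0.
.drawBipartite <- function(U, V, density, gamma) {
  P <- pmin(pmax(density * (1 + gamma * .cosineRows(U, V)), 0), 1)
  M <- matrix(stats::rbinom(length(P), 1, as.numeric(P)), nrow(P), ncol(P))
  M
}

.drawWithinType <- function(U, density, gamma) {
  M <- .drawBipartite(U, U, density, gamma)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]     # symmetrize from upper triangle
  diag(M) <- 0
  M
}

#' Generate a synthetic heterogeneous network
#'
#' Draws rank-`latentRank` drug and target factors; the top
#' `positiveRate` fraction of latent inner products become the positive
#' interactions (an exactly low-rank planted signal, the sharpest possible
#' recovery test for the completion head), then labels are flipped at
#' `noiseFlipRate`. Diseases and side effects get their own latent factors
#' and auxiliary relations are drawn with probability increasing in latent
#' cosine similarity; similarity matrices are latent cosine similarity
#' rescaled to `[0, 1]` with unit diagonal.
#'
#' @param cfg configuration from [synthConfig()].
#' @return list with `net` (a [HeteroNetwork-class]) and `truth`
#'   (drug/target latent factors, the latent score matrix, and the
#'   noiseless interaction matrix).
#' @export
generateSyntheticNetwork <- function(cfg = synthConfig()) {
  set.seed(cfg$seed)
  gamma <- 0.9
  U <- matrix(stats::rnorm(cfg$nDrugs * cfg$latentRank), cfg$nDrugs)
  V <- matrix(stats::rnorm(cfg$nTargets * cfg$latentRank), cfg$nTargets)
  D <- matrix(stats::rnorm(cfg$nDiseases * cfg$latentRank), cfg$nDiseases)
  E <- matrix(stats::rnorm(cfg$nSideEffects * cfg$latentRank),
              cfg$nSideEffects)

  scores <- U %*% t(V)
  nPos <- max(1L, as.integer(round(cfg$positiveRate * length(scores))))
  thr <- sort(as.numeric(scores), decreasing = TRUE)[nPos]
  Tclean <- (scores >= thr) * 1
  T <- Tclean
  if (cfg$noiseFlipRate > 0) {
    flips <- matrix(stats::rbinom(length(T), 1, cfg$noiseFlipRate),
                    nrow(T), ncol(T))
    T <- abs(T - flips)
  }

  dens <- cfg$relationDensities
  g <- if (cfg$auxSignal) gamma else 0
  relations <- list(
    drug_drug = .drawWithinType(U, dens[["drug_drug"]], g),
    drug_target = T,
    drug_disease = .drawBipartite(U, D, dens[["drug_disease"]], g),
    drug_sideeffect = .drawBipartite(U, E, dens[["drug_sideeffect"]], g),
    target_target = .drawWithinType(V, dens[["target_target"]], g),
    target_disease = .drawBipartite(V, D, dens[["target_disease"]], g)
  )
  simD <- (.cosineRows(U, U) + 1) / 2
  simT <- (.cosineRows(V, V) + 1) / 2
  simD <- pmin(pmax(simD, 0), 1); diag(simD) <- 1
  simT <- pmin(pmax(simT, 0), 1); diag(simT) <- 1
  simD[lower.tri(simD)] <- t(simD)[lower.tri(simD)]
  simT[lower.tri(simT)] <- t(simT)[lower.tri(simT)]

  net <- HeteroNetwork(relations,
                       similarities = list(drug_sim = simD,
                                           target_sim = simT))
  list(net = net,
       truth = list(drugFactors = U, targetFactors = V,
                    diseaseFactors = D, sideEffectFactors = E,
                    scoreMatrix = scores, interactions = Tclean))
}

#' Negative-to-positive imbalance ratio
#'
#' `floor((m * n - p) / p)` for `m` drugs, `n` targets and `p` known
#' interactions.
#'
#' @param nDrugs,nTargets,nPositives integer counts.
#' @return integer ratio (the "1:ratio" imbalance).
#' @export
imbalanceRatio <- function(nDrugs, nTargets, nPositives) {
  if (nPositives <= 0) stop("imbalance ratio undefined without positives")
  total <- as.numeric(nDrugs) * as.numeric(nTargets)
  floor((total - nPositives) / nPositives)
}

#' Reference profile of the benchmark dataset scale
#'
#' The printed node and association counts of the standard heterogeneous
#' DTI benchmark (Luo's dataset), plus derived quantities: total
#' drug-target pairs, negatives, and the implied negative:positive
#' imbalance ratio. The synthetic generator's configuration mimics this
#' regime proportionally at reduced scale.
#'
#' @return named list of counts and derived ratios.
#' @export
luoScaleCounts <- function() {
  counts <- list(drugs = 708L, targets = 1512L, positives = 1923L,
                 diseases = 5603L, drugDiseaseAssociations = 199214L)
  counts$totalPairs <- counts$drugs * counts$targets
  counts$negatives <- counts$totalPairs - counts$positives
  counts$imbalanceRatio <- imbalanceRatio(counts$drugs, counts$targets,
                                          counts$positives)
  counts
}
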