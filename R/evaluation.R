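## Evaluation protocol: drug-wise cross-validation, ranking metrics with
## conservative (pessimistic) tie handling, confusion-matrix metrics, and
## paired Wilcoxon signed-rank tests.

#' Drug-wise cross-validation folds
#'
#' Seeded uniform permutation of the drugs chunked into `nFolds` near-equal
#' groups (sizes differ by at most 1).
#'
#' @param m number of drugs.
#' @param nFolds number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of length `m`: fold id per drug.
#' @export
makeFolds <- function(m, nFolds = 10, seed = 1) {
  if (nFolds <= 0) stop("nFolds must be positive")
  if (nFolds > m) stop("cannot make more folds than drugs")
  set.seed(seed)
  perm <- sample.int(m)
  sizes <- rep(m %/% nFolds, nFolds)
  extra <- m %% nFolds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(m)
  fold[perm] <- rep(seq_len(nFolds), times = sizes)
  fold
}

#' Confusion-matrix metrics at a threshold
#'
#' TPR, FPR, precision, recall and the Matthews correlation coefficient
#' from binary labels and binarized predictions. An MCC denominator of 0
#' yields MCC = 0 by convention.
#'
#' @param labels binary vector.
#' @param predictions binary vector of the same length.
#' @return named numeric vector `tpr`, `fpr`, `precision`, `recall`, `mcc`.
#' @export
confusionMetrics <- function(labels, predictions) {
  if (!length(labels)) stop("empty input")
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  tp <- sum(labels == 1 & predictions == 1)
  fp <- sum(labels == 0 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fn <- sum(labels == 1 & predictions == 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  c(tpr = tpr, fpr = fpr, precision = prec, recall = tpr, mcc = mcc)
}

## Pessimistic descending ranking: within a score tie, negatives come
## before positives, so ranking metrics that use it are conservative.
.pessimisticOrder <- function(labels, scores) order(-scores, labels)

#' Ranking curves: AUROC and AUPR
#'
#' AUROC via the rank-sum (Mann-Whitney) identity with midrank tie
#' handling; AUPR by step-wise precision-recall summation (average
#' precision, no interpolation) over the pessimistic-tie descending
#' ranking.
#'
#' @param labels binary vector with at least one positive and one negative.
#' @param scores numeric scores.
#' @return named numeric vector `auroc`, `aupr`.
#' @export
rankingCurves <- function(labels, scores) {
  .checkTwoClass(labels)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  r <- rank(scores)                           # midranks
  auroc <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
  ord <- .pessimisticOrder(labels, scores)
  l <- labels[ord]
  cumTP <- cumsum(l)
  prec <- cumTP / seq_along(l)
  aupr <- sum(prec[l == 1]) / P
  c(auroc = auroc, aupr = aupr)
}

.checkTwoClass <- function(labels) {
  if (!any(labels == 1) || !any(labels == 0))
    stop("ranking metrics need at least one positive and one negative label")
}

#' ROC and PR curve points
#'
#' Threshold-sweep curve coordinates over the pessimistic ranking, for
#' export and plotting.
#'
#' @inheritParams rankingCurves
#' @return list of two data.frames, `roc` (fpr, tpr) and `pr`
#'   (recall, precision).
#' @export
curvePoints <- function(labels, scores) {
  .checkTwoClass(labels)
  ord <- .pessimisticOrder(labels, scores)
  l <- labels[ord]
  P <- sum(l); N <- length(l) - P
  cumTP <- cumsum(l)
  cumFP <- seq_along(l) - cumTP
  list(
    roc = data.frame(fpr = c(0, cumFP / N), tpr = c(0, cumTP / P)),
    pr = data.frame(recall = cumTP / P, precision = cumTP / seq_along(l))
  )
}

#' Recall among the top k percent of candidates
#'
#' For each k, takes the `ceiling(k% * N)` top-scored candidates under the
#' pessimistic tie ordering and reports the fraction of positives
#' retrieved.
#'
#' @inheritParams rankingCurves
#' @param kPercents percentages (default 5, 10, 15, 20, 30).
#' @return named numeric vector of recalls, one per k.
#' @export
recallAtTopK <- function(labels, scores, kPercents = c(5, 10, 15, 20, 30)) {
  if (!any(labels == 1)) stop("recall undefined without positives")
  ord <- .pessimisticOrder(labels, scores)
  l <- labels[ord]
  P <- sum(l)
  N <- length(l)
  out <- vapply(kPercents, function(k) {
    top <- ceiling(k / 100 * N)
    sum(l[seq_len(top)]) / P
  }, numeric(1))
  names(out) <- as.character(kPercents)
  out
}

#' Coverage: candidates inspected until recall reaches 1
#'
#' The 1-based position of the last positive in the pessimistic descending
#' ranking; always between the number of positives and the number of
#' candidates.
#'
#' @inheritParams rankingCurves
#' @return integer count.
#' @export
coverage <- function(labels, scores) {
  if (!any(labels == 1)) stop("coverage undefined without positives")
  ord <- .pessimisticOrder(labels, scores)
  max(which(labels[ord] == 1))
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ties receive midranks. For 25 or fewer
#' informative pairs the exact null distribution is computed (dynamic
#' programming over doubled midranks); beyond that a normal approximation
#' with tie correction and continuity correction is used. If every
#' difference is zero the p-value is 1.
#'
#' @param a,b paired metric vectors (e.g. per-drug AUROC under two methods).
#' @return list with `p.value`, `statistic` (V, sum of positive-difference
#'   ranks) and `n` (informative pairs).
#' @export
wilcoxonPaired <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p.value = 1, statistic = NA_real_, n = 0L))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    ## exact: DP over doubled midranks (integers even with ties)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)      # counts[s+1] = #subsets with 2V = s
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    v2 <- as.integer(round(2 * V))
    pLe <- sum(probs[seq_len(v2 + 1)])
    pGe <- sum(probs[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(pLe, pGe))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p.value = p, statistic = V, n = as.integer(n))
}

#' Run the full cross-validated evaluation
#'
#' For each fold, the test drugs' interaction rows are hidden from
#' training (graphs, features, loss and imbalance weight all see the masked
#' network), the model is trained, and the hidden rows are scored. Reports
#' pooled (micro) and per-drug (macro) AUROC/AUPR, MCC at the configured
#' threshold, mean recall@k, mean coverage, and the fraction of drugs whose
#' per-drug AUROC/AUPR exceeds each threshold delta. Drugs with no positive
#' in their row are pooled into the micro metrics but skipped in per-drug
#' averages.
#'
#' @param net a [HeteroNetwork-class].
#' @param config run configuration; `config$nFolds` folds,
#'   `config$seed` drives fold assignment and every training run.
#' @return an [EvalReport-class].
#' @export
runCV <- function(net, config = defaultRunConfig()) {
  m <- nDrugs(net)
  Tfull <- relation(net, "drug_target")
  fold <- makeFolds(m, config$nFolds, config$seed)
  Spred <- matrix(NA_real_, m, ncol(Tfull))
  for (f in seq_len(config$nFolds)) {
    test <- which(fold == f)
    model <- trainDTIModel(net, config, heldoutDrugs = test)
    Spred[test, ] <- model@S[test, , drop = FALSE]
  }
  buildEvalReport(Tfull, Spred, config, folds = fold,
                  drugIds = nodeIds(net, "drug"))
}

#' Assemble an evaluation report from a score matrix
#'
#' Shared by [runCV()] and by callers that scored the interaction matrix by
#' other means (e.g. a single held-out split).
#'
#' @param T binary interaction matrix.
#' @param S score matrix (rows not scored may be NA; they are skipped).
#' @param config run configuration (thresholds, recall@k grid).
#' @param folds optional fold assignment to record.
#' @param drugIds optional drug identifiers.
#' @return an [EvalReport-class].
#' @export
buildEvalReport <- function(T, S, config = defaultRunConfig(),
                            folds = integer(0), drugIds = NULL) {
  m <- nrow(T)
  scored <- which(rowSums(is.na(S)) == 0)
  labels <- as.numeric(T[scored, , drop = FALSE])
  scores <- as.numeric(S[scored, , drop = FALSE])
  pooled <- rankingCurves(labels, scores)
  cm <- confusionMetrics(labels, as.numeric(scores >= config$mccThreshold))
  perDrug <- list()
  skipped <- 0L
  for (i in scored) {
    li <- T[i, ]; si <- S[i, ]
    if (!any(li == 1)) { skipped <- skipped + 1L; next }
    if (!any(li == 0)) { skipped <- skipped + 1L; next }
    rc <- rankingCurves(li, si)
    rk <- recallAtTopK(li, si, config$recallK)
    perDrug[[length(perDrug) + 1L]] <- data.frame(
      drug = if (is.null(drugIds)) as.character(i) else drugIds[i],
      index = i, nPositives = sum(li == 1),
      auroc = rc[["auroc"]], aupr = rc[["aupr"]],
      coverage = coverage(li, si),
      t(rk), check.names = FALSE
    )
  }
  pd <- if (length(perDrug)) do.call(rbind, perDrug) else
    data.frame(drug = character(0), index = integer(0),
               nPositives = integer(0), auroc = numeric(0),
               aupr = numeric(0), coverage = numeric(0))
  kCols <- as.character(config$recallK)
  recallMeans <- if (nrow(pd)) colMeans(pd[, kCols, drop = FALSE]) else
    setNames(rep(NA_real_, length(kCols)), kCols)
  thr <- rbind(
    data.frame(metric = "auroc", delta = config$aurocDeltas,
               fraction = vapply(config$aurocDeltas, function(d)
                 mean(pd$auroc > d), numeric(1))),
    data.frame(metric = "aupr", delta = config$auprDeltas,
               fraction = vapply(config$auprDeltas, function(d)
                 mean(pd$aupr > d), numeric(1)))
  )
  new("EvalReport",
      auroc = pooled[["auroc"]], aupr = pooled[["aupr"]], mcc = cm[["mcc"]],
      macroAuroc = mean(pd$auroc), macroAupr = mean(pd$aupr),
      perDrug = pd, recallAtK = recallMeans,
      coverage = mean(pd$coverage), thresholdTable = thr,
      nDrugsSkipped = skipped, labels = labels, scores = scores,
      folds = as.integer(folds))
}
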