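---
title: "Two-channel graph embeddings and inductive matrix completion for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-channel graph embeddings and inductive matrix completion for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgdti)
```

## The problem

Known drug-target interactions (DTIs) are extremely sparse: for a matrix of
hundreds of drugs against over a thousand proteins, typically fewer than one
pair in five hundred is a documented interaction. At the same time, drugs
and proteins come embedded in a rich heterogeneous network — drug-drug
interactions, drug-disease and drug-side-effect associations, protein-protein
interactions, protein-disease associations, chemical and sequence similarity
— all of which carry indirect evidence about which unobserved pairs are
plausible. `hgdti` predicts new DTIs by learning drug and target embeddings
from that heterogeneous network and completing the interaction matrix with a
low-rank bilinear head.

## The model

**Metapath neighbour graphs.** For each node type we fix a small set of
metapaths — composite relations such as drug-disease-drug ("two drugs
associated with a common disease") — and materialize each one as a
homogeneous binary graph over drugs (or targets): entry $(i,j)$ is 1 iff at
least one path instance connects $i$ and $j$. Multiplicities are discarded
because the metapath neighbourhood $N^\rho(i)$ is a set, and self-loops are
added so isolated nodes still aggregate their own features. The default
sets are four per side: drug interaction, shared disease, shared side
effect and shared target for drugs; protein interaction, shared disease,
shared drug and thresholded sequence-similarity neighbourhood for targets.
No metapath inventory is canonical for this model family; the default is
the natural reading of the four-subgraph construction, and the chain
mechanism accepts any composable relation sequence.

**Attention channel.** On each metapath graph a multi-head graph attention
layer computes, per head, the influence logit
$w_{ij} = \mathrm{LeakyReLU}\!\big(g^\top [W x_i \,\|\, W x_j]\big)$,
normalizes it over the neighbourhood with a softmax, and aggregates
$x_i' = \sigma\!\big(\sum_{j \in N^\rho(i)} a_{ij} W x_j\big)$; the $K$
head outputs are concatenated. This channel is sensitive to *which*
neighbours matter: the weights are learned per edge.

**Convolution channel.** In parallel, each metapath graph is encoded by a
residual graph convolution stack: one projection layer
$H = \sigma(\hat A X W_0)$ with
$\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$, followed by residual
blocks $G \leftarrow \sigma(\hat A G W) + G$. The identity shortcut keeps
gradients alive with depth; the symmetric normalization (constant
$\sqrt{\tilde d_i \tilde d_j}$ between nodes $i$ and $j$) keeps the
propagation operator's spectral radius at 1. We normalize in **every**
layer, including the first: the un-normalized first-layer form diverges on
high-degree nodes, and consistency with the stated propagation rule takes
precedence.

**Fusion.** Per node type, a shared semantic attention scores each
metapath, $s^\rho = \tfrac1n \sum_j q^\top \tanh(W_f x_j^\rho + b)$, the
scores are softmax-normalized into weights $a^\rho$, and the final
embedding is the weighted channel mean
$X = \sum_\rho a^\rho (G_a^\rho + G_c^\rho)/2$. The scores are computed on
the attention-channel embeddings and one weight per metapath reweights
both channels; giving each channel its own attention distribution is a
possible variant, but the single-weight form is what the fusion equation
states. Drugs and targets get separate fusion parameters.

**Completion head.** All pairs are scored as $S = X Z_1 Z_2^\top Y^\top$
with factors of rank $k \ll$ the embedding width, and everything is trained
end-to-end against

$$\mathcal{L} = \tfrac{1-\alpha}{2}\,\|P_\Omega(T - S)\|_F^2
             + \tfrac{\alpha\mu}{2}\,\|P_{\bar\Omega}(T - S)\|_F^2,
\qquad \mu = \tfrac{|\Omega|}{|\bar\Omega|},$$

where $\Omega$ is the observed-positive set. The tiny weight $\mu$
(recomputed from the *training* rows in cross-validation, so no test
leakage) keeps the million-fold majority of unobserved pairs from
swamping the positives.

We adopt the convention $X$ = drugs (rows of $T$), $Y$ = targets
(columns); descriptions of this model family are inconsistent about which
matrix is which, and this is the only reading under which the dimensions
of $S$ match $T$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nHeads`, `headDim` | 4, 64 | attention heads and per-head width; channel width is `nHeads * headDim` = 256 |
| `gatLayers` | 1 | attention-propagation layers per metapath; the metapath-level fusion acts as the second tier |
| `gcnResBlocks` | 2 | residual blocks after the projection layer |
| `attDim` | 128 | fusion attention dimension |
| `rank` (k) | 64 | rank of the completion factors |
| `alpha` | 0.5 | class trade-off in the loss, constrained to (0, 1); no canonical value exists, 0.5 treats the two terms symmetrically before `mu` scaling |
| `learningRate`, `epochs` | 0.001, 1000 | Adam, full-batch |
| `dropout` | 0.4 | on input features and attention coefficients, training only |
| `activation` | tanh | node update everywhere; attention logits use LeakyReLU slope 0.2 |

The published final configuration of this model family fixes Tanh,
learning rate 0.001, 1000 epochs, dropout 0.4 and a batch size of 64. A
batch size is incompatible with a full-matrix reconstruction loss, so
training is full-batch by default and `batchSize` only takes effect in the
optional `pairSampling` mode, which draws a minibatch of positive and
negative pairs each epoch.

The trainer computes reverse-mode gradients of every stage in closed form
(attention softmax, residual convolutions, fusion softmax, bilinear head)
and optimises with Adam; gradient correctness is pinned by
finite-difference tests through every parameter group.

## The synthetic study fixture

The generator plants an exactly low-rank signal: rank-`latentRank` drug
and target factors are drawn, and the top `positiveRate` fraction of
latent inner products become the positive interactions. Planting by
thresholding (rather than Bernoulli draws) keeps the signal exactly
low-rank, which makes recovery a sharp test of the completion head.
Auxiliary relations (drug-drug, drug-disease, drug-side-effect,
protein-protein, protein-disease) are drawn with edge probability
increasing in latent cosine similarity, so the metapath encoders carry
genuine information about the planted signal; similarity matrices are
rescaled latent cosine similarities. An `auxSignal = FALSE` switch
decouples the auxiliaries for ablation-style null experiments.

Defaults: 60 drugs x 90 targets, rank 4, `positiveRate = 0.01` (about
1:100 positive:negative), noiseless labels, auxiliary densities 6-8%.
These were fixed once as the package's standard desk-scale study
conditions: the 1:100 imbalance is severe enough to exercise the
$\mu$-weighted loss while leaving ~11 positives in a 20% held-out drug
fold, and the reference benchmark regime (708 drugs, 1512 proteins, 1923
interactions, 1:555) is represented exactly by `luoScaleCounts()`.
`noiseFlipRate` defaults to 0 because the planted-signal recovery
experiment is defined noiseless; noisy variants are one argument away.

What passing recovery tests does **not** show: real interaction data are
not exactly low-rank, their degree distributions are heavy-tailed where
the generator's are binomial, and real similarity matrices encode
chemistry and sequence rather than the planted factors. The synthetic
results validate the machinery (gradients, masking, protocol), not
real-data accuracy.

## Evaluation protocol

Drug-wise 10-fold cross-validation: drugs are permuted by seed and
chunked into near-equal folds; each fold's interaction **rows** are hidden
from the training loss, the imbalance weight *and* the graph/feature
construction, the model is retrained, and the hidden rows are scored. A
pair-wise CV mode exists but row-wise holdout is the default because it
matches how the protocol is described and is the harder, more honest
test. Reported metrics:

* pooled (micro) AUROC via the rank-sum identity with midranks, and AUPR
  as stepwise average precision — the headline numbers; macro (per-drug
  mean) variants are reported alongside because descriptions of pooled
  metrics are ambiguous between the two;
* MCC with scores binarized at 0.5 (configurable; the bilinear scores are
  trained toward the 0/1 targets so 0.5 is the natural midpoint);
* per-drug AUROC/AUPR plus the fraction of drugs exceeding thresholds
  $\delta$ (0.9/0.8/0.7 for AUROC, 0.8/0.5/0.3 for AUPR);
* mean recall within the top 5/10/15/20/30% of each drug's candidates,
  and mean coverage (rank of the last retrieved positive);
* paired two-sided Wilcoxon signed-rank tests on per-drug metric vectors
  (exact null for $\le 25$ informative pairs, normal approximation with
  tie and continuity corrections beyond).

Ties are handled pessimistically everywhere a ranking is materialized
(positives after negatives within a tie), so reported recall@k and
coverage are conservative; AUROC uses midranks, the standard resolution
of the rank-sum identity. Drugs with no positive (or no negative) in
their held-out row are pooled into the micro metrics but skipped in
per-drug averages, and the skip count is reported.

## Numerical choices and degenerate inputs

* Softmaxes (neighbourhood attention, metapath fusion) subtract the row
  maximum before exponentiation.
* Empty neighbourhoods cannot occur (self-loops are part of the metapath
  graph contract) and are rejected loudly if constructed by hand.
* An MCC denominator of zero yields MCC = 0.
* All-zero Wilcoxon difference vectors give p = 1.
* Non-finite losses or layer outputs abort with the epoch / layer named.
* Parameters are initialized from seeded symmetric-uniform distributions
  scaled by fan-in and fan-out; every stochastic component (init, dropout,
  fold assignment, pair sampling, the generator) flows from the single
  configuration seed, which is what makes runs reproducible byte for byte.

## Problem sizes used by the shipped experiments

The test-suite and acceptance experiments run the generator defaults
(60 x 90, one 20% drug fold held out, 300 epochs, three training seeds
per variant); unit tests use smaller instances (tiny hand-built networks,
25-30 drugs) with a reduced architecture. These sizes were chosen so the
full suite exercises every stage — including the two-channel vs
single-channel comparison and the shuffled-label null — at desk scale.

## Known limitations

* The metapath inventory is an inference from the four-subgraph
  construction; other inventories are configurable but unexplored.
* Dense matrix algebra throughout: appropriate to a few thousand nodes
  per type, not to genome-scale networks.
* Only gradient training of the factorized head is provided (no
  alternating least squares or nuclear-norm solver), matching the
  end-to-end formulation.
* Competitor methods are out of scope; cross-method Wilcoxon tables can
  be reproduced only if per-drug metric vectors for the other methods are
  supplied externally as TSV.
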