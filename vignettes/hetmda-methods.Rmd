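---
title: "Multi-module graph attention for miRNA–disease association prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-module graph attention for miRNA–disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Experimentally validated miRNA–disease associations (MDAs) are sparse:
curated databases record on the order of a few percent of all possible
miRNA–disease pairs, and wet-lab validation of the remainder is slow and
expensive. `hetmda` implements a link-prediction pipeline that scores
unobserved pairs by combining three sources of evidence in one
heterogeneous network: the bipartite association matrix itself, similarity
structure among miRNAs and among diseases, and protein-mediated relations
(miRNA–target-protein and disease–protein associations).

The pipeline has four stages:

1. **Integrated similarities.** miRNA functional similarity (best-match
   average of disease semantic similarities over the two miRNAs' disease
   sets) backed by a Gaussian interaction profile (GIP) kernel where the
   functional similarity is undefined; disease semantic similarity over a
   hierarchy DAG backed by a GIP kernel over association columns.
2. **Meta-path modules.** Three symmetric block matrices over the
   `n_m + n_d` nodes: `G1` holds the integrated similarities with the
   association matrix `A` in the off-diagonal block; `G2` replaces the
   similarity blocks by meta-path adjacencies mediated by the other entity
   type (miRNA–disease–miRNA, disease–miRNA–disease); `G3` uses
   protein-mediated meta-paths (miRNA–protein–miRNA,
   disease–protein–disease).
3. **Two-level attention encoder.** Per module, a multi-head graph
   attention layer: type-specific linear projections
   `h_i = W_c x_i`, additive attention
   `e_ij = LeakyReLU(omega · [h_i || h_j])` normalized by a softmax over
   each node's neighbor set, and logistic aggregation
   `z_i = sigma(sum_j alpha_ij h_j)`, heads concatenated. A second
   attention level scores each module by the mean of
   `lambda · tanh(W z + eps)` over nodes of one type and fuses the module
   representations with softmax weights (computed separately for miRNA and
   disease nodes). The encoder is pretrained by full-batch Adam on the mean
   binary cross-entropy between `A` and its inner-product reconstruction
   `sigma(Z_m Z_d')`.
4. **Classification.** A pair `(i, j)` is represented by the concatenation
   `[Z_m[i], Z_d[j]]` and classified by an RBF-kernel support vector
   machine with sigmoid-calibrated probability outputs.

## Model assumptions

The method assumes (i) *guilt by association*: functionally similar miRNAs
tend to associate with semantically similar diseases; (ii) the bipartite
association structure is approximately low-rank, so an inner-product
decoder can reconstruct it from node embeddings; and (iii) protein-mediated
relations carry signal about the same latent factors that drive the
associations. The synthetic generator (below) encodes exactly these
assumptions, which is what makes it a fair test bed and also bounds what
passing tests can show about real data.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `sigma` | 0.5 | decay of a disease's semantic contribution per hierarchy level (dimensionless, in (0,1)) |
| `head_dim`, `n_heads` | 32, 8 | per-head width and head count; embedding dimension `d = head_dim * n_heads = 256` |
| `module_attn_dim` | 128 | hidden width of the module-attention scorer |
| `epochs` | 2000 | full-batch Adam steps (a 4000-step setting is used for full-scale benchmark runs; both are supported) |
| `learning_rate` | 0.001 | Adam step size |
| `leaky_slope` | 0.2 | LeakyReLU negative slope in the attention score |
| `ratio` | 1 | sampled negatives per known positive (1:1 up to 1:5 studied) |
| `aed_frac` | off | reliable-negative threshold as a fraction of the average Euclidean distance to the positive centroid; grid 0.4–1.0 |
| `C` | 150 | SVM penalty (an alternative setting of 50 is also in circulation for this architecture; both selectable) |
| `gamma` | `1/(2d · var)` | RBF width, the data-driven reciprocal of feature dimension times mean feature variance, computed on standardized training features |

The GIP bandwidth is the reciprocal mean squared profile norm,
`delta = n / sum_i ||x_i||^2`, the convention of the kernel literature: it
makes the kernel of coinciding profiles equal 1 and keeps similarity
decaying (rather than growing) with profile norm. The miRNA and disease
sides each get their own bandwidth, computed over rows and columns of `A`
respectively. Specificity is `TN / (TN + FP)` and the Matthews coefficient
uses the standard four-factor denominator.

## Evaluation protocol

Cross-validation is stratified `k`-fold (default 5) over the labeled pair
set (all positives plus `ratio` sampled negatives), repeated with fresh
negatives and fold assignments. **Masking:** by default, each fold's
positive associations are zeroed out of `A` before anything downstream is
computed — similarities, meta-paths and the encoder's reconstruction target
all see only training associations. This prevents the test edges from
leaking into the features, at a real cost: a test positive's miRNA loses
part (sometimes all) of its interaction profile, so masked evaluation is
systematically harder than evaluation with similarities computed once on
the full matrix. Because published work in this area rarely states which
regime it used, `cross_validate(..., mask = FALSE)` provides the unmasked
variant for literal replication attempts; the package default is the
leakage-free regime.

Thresholded metrics use 0.5 on calibrated scores. AUC is the trapezoid over
the exact ROC step function (equal to the tie-corrected Mann–Whitney
statistic, which the tests verify); AUPR uses the average-precision
convention. Both are checked against independent oracles in the test suite.

For case-study ranking, every association of the query disease is erased
before any training; the erased disease's pairs are also excluded from the
negative-sampling pool so the ranking of its candidates is produced by a
model that has never seen the disease's links in any role.

## The synthetic generator

`generate_network()` plants the structure the method assumes: sparse
non-negative factor loadings `U` (miRNAs) and `V` (diseases) of rank `r`,
association probabilities `plogis(a0 + U V')` with the intercept `a0`
calibrated by root-finding so the expected density hits the target (default
3%, the regime of the curated human benchmark, which records 5,430
associations over 495 miRNAs × 383 diseases ≈ 2.9%), and protein layers
drawn from the same loadings against independent protein loadings, with
optional entry-flip noise. `obs_frac` hides a fraction of true
associations; the hidden ones are the recoverable ground truth. The
disease hierarchy is a random rooted tree over the disease labels.

What it does *not* emulate: the heavy-tailed degree distributions of real
curated databases, name-mapping noise between resources, correlated
curation biases, or a meaningful (MeSH-like) semantic hierarchy — the tree
is random, so semantic similarity is informative only about the generated
topology. Passing the recovery tests therefore demonstrates that the
implementation extracts planted low-rank signal through the full pipeline,
not that it attains any particular performance on real curated data.

### Desk-scale problem sizes

The package's own validation runs at sizes chosen to keep a complete test
cycle in minutes on one core: planted networks of 60 miRNAs × 40 diseases ×
80 proteins at rank 4 with 80% of true links observed; a 64-dimensional
embedding (4 heads × 16) trained for 300 epochs; 5-fold cross-validation
repeated 4 times (20 folds — folds at this scale hold only ~25 test pairs
each, so single-repeat AUC estimates are noisy and several repetitions are
needed for a stable mean, exactly as the full-scale protocol repeats its
cross-validation 10 times). The robustness sweep across generator seeds
uses a lighter encoder (32 dimensions, 150 epochs).

An interaction worth knowing about: with the full-matrix reconstruction
loss, held-out positives are zeros of the training target, so very long
pretraining actively encodes them as non-associations and degrades masked
evaluation. At desk scale the 300-epoch regime sits before this
memorization sets in; the same tension exists at full scale with long
training and is a known cost of inner-product decoders trained on the
complete zero-filled matrix.

## Numerical choices

* Attention softmax rows are shifted by the row maximum before
  exponentiation; masked (non-neighbor) entries are excluded exactly.
* Self-loops are inserted when modules are assembled, so every node has at
  least one neighbor and no softmax row is empty; meta-path adjacencies
  themselves keep a zero diagonal so that an all-zero row still identifies
  an entity with no mediated partner.
* Reconstruction probabilities are clamped to `[1e-7, 1 - 1e-7]` inside the
  loss; the gradient uses the exact unclamped sigmoid/cross-entropy form.
* Parameters are initialized Glorot-uniform from an explicit seed; the
  whole training loop is deterministic given the seed (verified bit-for-bit
  in the tests), and gradients of every parameter block are validated
  against central finite differences.
* The encoder's backward pass is written analytically (no autograd
  dependency); Adam uses the standard moment defaults (0.9, 0.999, 1e-8).
* Undefined metric ratios (empty denominator) are reported as 0; AED
  filtering retains distances exactly equal to the threshold; candidate
  ranking breaks score ties by miRNA index.
* Sub-seeds for folds, negative draws and calibration are derived
  arithmetically from the master seed and kept inside 32-bit integer range.

## Open design points, resolved

* *Semantic contribution on multi-parent hierarchies*: contributions are
  relaxed to a fixed point of `DC(a) = max over children on a path`, which
  matches explicit path enumeration (tested on random DAGs).
* *Functional-similarity definedness*: an miRNA pair has a defined
  functional similarity when both members have at least one associated
  disease inside the hierarchy; otherwise the GIP fallback fills the entry.
* *Module attention per node type*: module weights are computed separately
  for miRNA-type and disease-type nodes, since the two types may draw on
  different modules (empirically they do: the similarity module tends to
  dominate for miRNAs and the protein module for diseases on planted data).
* *AED recomputation*: the centroid and AED are computed once on the full
  candidate pool, then the filtered pool is re-sampled to the configured
  ratio.
* *Negative pool during pretraining*: the reconstruction loss uses the full
  zero-filled matrix rather than subsampled negatives.

## Known limitations

* Dense matrix algebra throughout: fine into the low thousands of nodes,
  not engineered for much larger networks.
* No dropout, weight decay or minibatching in the encoder; regularization
  comes only from early stopping via the epoch count.
* Identifier normalization (e.g. mapping database disease names onto a
  hierarchy) is deliberately out of scope: inputs must already use
  consistent names.
* Probability calibration of the SVM on small training sets is noisy;
  rankings (AUC/AUPR, candidate lists) are unaffected since calibration is
  monotone in the decision value.
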