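---
title: "Pathway-informed criss-cross attention for multi-omics classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-informed criss-cross attention for multi-omics classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathomix)
```

## The model

pathomix classifies samples (e.g. tumors, liquid-biopsy specimens) from
multi-modal omics measurements while keeping every learned quantity
attached to a biological unit — a gene, a pathway, or a pathway-pathway
interaction. The architecture has five stages.

**1. Compacted gene embedding.** Each modality arrives at its own
resolution: gene-level scores (RNA expression, gene-level CNV),
fragment-level fractions (methylation sites, several per gene), or
nucleotide-level events. A fixed menu of statistical indicators compacts
each modality to one or more gene-level features: the gene-level score
itself (`f1`), and for sub-gene features the count, minimum, maximum,
mean, Shannon entropy of the value distribution, and weighted means over
the whole gene or positional windows (`f2`–`f8`). Concatenating the
per-modality features gives each gene a short vector; stacking genes
gives the gene embedding `E_G` (`Ng x Dg`, per sample). By default
gene-level modalities contribute `f1` only and sub-gene modalities
contribute `{count, min, max, mean, entropy}`; the assignment is fully
configurable since the right menu depends on the assay. Every
(gene, indicator) column is z-scored across the *training* samples only;
genes with no mapped features receive 0, the standardized population
mean, which is neutral under the subsequent linear projection.

**2. Pathway-based sparse projection (PSNN).** A linear layer
`E_P = (M ∘ W)^T E_G + B` maps gene embeddings to pathway embeddings,
where `M` is the binary gene-pathway membership mask. Weights outside
the mask are structurally zero: they are zero at initialization, their
gradients vanish identically (verified by the test suite via the
autodiff engine), and the optimizer re-applies the mask after every
step, so membership is a hard constraint, not a regularizer. Weights on
the support are drawn uniformly in `±1/sqrt(k_p)` (`k_p` = pathway
size), with a seed, and learn the role each gene plays in each pathway.
The bias is one value per pathway per embedding dimension; a per-pathway
scalar is available where fewer parameters are wanted.

**3. Pathway knowledge.** Pathways come from GMT files and are filtered
by three clauses: size between 15 and 100 genes, or size above 15 with
an overlap ratio (fraction of the pathway's genes present in any other
pathway) strictly below 1, or size above 15 with strictly fewer than 5
contained sub-pathways. Overlap and subset statistics are computed
against the unfiltered collection, matching the one-pass curation order.
Crosstalk between every pathway pair is tested either by a binomial test
on inter-set edge counts against the background network's edge density
(when a gene–gene network is supplied) or by a shared-gene
hypergeometric test on the gene universe (when not). Entries are
`1 - BH-adjusted p` for pairs significant at `alpha = 0.05`, giving a
symmetric, zero-diagonal, significance-weighted matrix `P`. We weight by
significance rather than binarizing because the matrix enters the model
additively as attention bias, where graded evidence is meaningful.

**4. Criss-cross attention encoder.** Three blocks, eight heads each.
Column attention acts along the pathway axis with `P` added to the
logits, so information flows preferentially between pathways with prior
crosstalk. Heads are merged through sigmoid gates
(`U1 = Σ_h (σ(E_P W_g) ∘ A_h) W_U`), a residual, and a
LayerNorm→linear→GELU→linear feed-forward with its own residual. Row
attention then acts along the embedding-dimension axis of the transposed
output, exchanging information between modalities; its residual is
scaled by a constant `β` (a tuning parameter; default 1). After each
block the crosstalk matrix is updated from the batch-mean updated
embedding as the scaled Gram matrix `P' = Ē Ēᵀ / Dp`, symmetrized — the
updated network therefore mixes prior knowledge with task-driven
information and is the object later mined for hub modules. Two points in
the architecture admit more than one reading, and both are exposed as
options: the attention logit scale (`sqrt(d)` by default, the
numerically standard choice; plain `d` selectable) and the network
update (`embedding_correlation` by default, which uses the updated
embedding as the narrative describes; `printed_formula` computes
`P' = P Pᵀ / Np` from the network alone). Row-attention input is the
column sub-layer output, following the sub-layer order. Dropout (0.2 on
attention weights and feed-forwards) acts in training mode only; all
evaluation and interpretation run deterministic forward passes.

**5. Classifier head.** The final pathway embedding is pooled
(per-pathway mean over embedding dimensions by default; flatten and max
are available) and passed through fully connected layers of 300, 200 and
100 neurons with ReLU and dropout `dropout_c`, then a softmax over class
labels. Training minimizes class-weighted cross-entropy (inverse
frequency weights) with Adam, early-stopping on the macro-F1 of an
internal stratified validation split.

## Numerical engine

No deep-learning framework is assumed: the package carries a compact
reverse-mode automatic-differentiation tape over batched 3-D arrays
(`rows x cols x samples`), with the batched matrix products, softmax and
layer normalization implemented in C++ (RcppArmadillo) operating on the
arrays in place. The eight attention heads of a sub-layer are stored
column-stacked and evaluated in one batched product via a pure reshape,
which is what makes CPU training of the full model practical. Gradients
of every operation are checked against central finite differences in the
test suite, and the attention sub-layers are additionally checked against
an independently written, loop-based evaluation of the block equations.

## Evaluation protocol

`cross_validate()` implements stratified 5-fold cross-validation
repeated twice with reshuffling (10 fold-level metric sets). The
feature normalizer is fitted per training fold; test folds never inform
normalization or model selection (a deliberate-leakage switch exists
solely for regression-testing this contract). Metrics: macro-averaged F1
(primary, robust to class imbalance), support-weighted F1, AUC (binary:
Mann–Whitney rank statistic; multi-class: unweighted one-vs-rest mean),
and sensitivity at 99% specificity — the screening operating point,
defined by the smallest score threshold at which at least 99% of
negatives are rejected. Ablation modes strip the model down one
component at a time: `cc_attention` (no crosstalk bias), `transformer`
(no bias, no row attention), `psnn` (projection straight to the
classifier), `nn` (gene embedding straight to the classifier).

## Interpretation

*Modality contributions* average all row-attention maps element-wise
across blocks, heads and samples; the column means of that matrix sum to
one (rows are stochastic) and are summed per modality. *Pathway and gene
importance* use Shapley values with an interventional value function:
features absent from a coalition are replaced by background-sample
values and the model output is averaged over the background. Pathway
explanations act on the pooled classifier input; gene and gene-modality
explanations act on the gene embedding, optionally restricted to one
pathway's members. Pathway entities are, by default, the embedding rows
of a pathway's member genes masked at the model *input* — a pathway is
credited for the information its genes carry into the model, and genes
shared between pathways credit each of them. This matters because the
attention blocks deliberately mix information across pathways: masking
deeper representations (the encoder-input pathway embedding, or the
pooled classifier input — both available via the `at` argument) measures
which internal channels the trained network happens to route through,
and a network facing redundant pathways can satisfy the task through a
subset of them, leaving an equally informative pathway with zero
internal-channel credit. Input-level attribution reports the biology;
the deeper layers report the wiring. Exact enumeration is used up to 12
entities and a
seeded permutation-sampling approximation beyond; the exact mode is
verified against a permutation-enumeration oracle and satisfies the
additivity axiom by construction. A gene's *core modality* is the
modality with the best SHAP rank, ties broken by configured modality
order. *Pathway scores* are per-sample means of the final pathway
embedding over its dimensions. *Sub-network scores* mine the per-block
updated crosstalk networks in four steps: element-wise averaging across
blocks; pruning edges at or below a quantile of absolute edge weight
(default 0.9); greedy growth from top-SHAP seed pathways, adding the
neighbor joined by the strongest edge while the score improves, up to 20
members; scoring as the sum of member SHAP values weighted by
`1 + normalized within-subnetwork degree`. Sub-networks overlapping with
Jaccard above 0.5 are merged. The four-step structure is fixed; every
threshold is an exposed argument, since the concrete instantiation of
each step is a design choice of this package.

## The synthetic data generator

`generate_dataset()` produces studies with known ground truth: a latent
class `c ~ Bernoulli(0.5)` shifts the features of genes in a chosen set
of planted pathways — log-normal expression means by `effect_size`
standard deviations on the log scale, methylation-site Beta means by
`0.1 * effect_size` (precision 30, 3–10 sites per gene), and categorical
copy-number states (0–4) toward gains. Labels equal the latent class
flipped with probability `label_noise`; this is the steep limit of a
logistic link on the planted activity component, chosen so that at
`effect_size = 0` labels are independent coin flips — the property that
makes null-calibration checks meaningful. The truth object stores the
planted pathways, per-gene effects, and a linear rule (standardized
planted-gene mean against a threshold at half the effect) that
reconstructs the noise-free labels from the features; at the default
separations this reconstruction is exact. Default study conditions are
300 samples, 200 genes, 20 pathways of 15–25 genes with overlap rate
0.3, 3 planted pathways, effect size 2. The generator emulates the
*level structure* of real multi-omics data (gene-level, many-to-one
fragment-level, categorical states), not its full complexity: no batch
effects, no sequencing noise model, no gene–gene correlation beyond the
planted pathway structure, no survival times. Passing tests on it
demonstrate that the machinery recovers planted signal under the stated
conditions, not that any particular real dataset would classify well.

## Problem sizes and run times

The packaged experiments use the default study conditions above with
training capped at 20 epochs (early-stopping patience 5, Adam at 1e-3,
batch 32), 8 heads of dimension 8, feed-forward width 32, and 3 encoder
blocks — a configuration chosen so that the full battery (repeated CV,
five SHAP seeds, null calibration, three-seed ablation) completes on a
single CPU in minutes. On strongly separable planted data the early
stopping typically ends training well before the cap; the cap matters
mainly for null data where validation macro-F1 drifts.

## Degenerate inputs and tie-breaks

Empty feature sets yield the post-normalization fill (0); `count` on an
empty set is 0. Entropy requires non-negative values and treats
`0 log 0` as 0; an all-zero feature vector has entropy 0. Attention
softmax subtracts row maxima; argmax ties in max-pooling and predicted
classes resolve to the first index. Constant score vectors give
sensitivity 0 at 99% specificity (no threshold rejects 99% of
negatives). Pathways with identical gene sets count each other as
subsets. A zero-variance feature column gets unit scale rather than
dividing by zero. The crosstalk update is clamped to ±1e6 as a
safeguard; the clamp is inactive in all packaged experiments.

## Known limitations

Training is single-threaded CPU R/C++; it is practical at the hundreds
of samples and tens of pathways used here, not at thousands of pathways.
The indicator forms `f1`–`f8` follow their standard statistical readings;
assays whose conventions differ (e.g. M-values vs beta values) should
transform inputs upstream. SHAP sampling error decreases as `1/sqrt(n_perm)`;
ranking stability for closely tied pathways requires larger `n_perm`
than the default. The binomial crosstalk test treats edges as
independent, which real interaction networks violate; its p-values are
screening statistics, not calibrated error rates.
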