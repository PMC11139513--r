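# pathomix

Pathway-informed criss-cross attention for multi-omics sample
classification, with built-in interpretation.

## What problem it addresses

Integrating several omics layers (RNA expression, DNA methylation, copy
number, ...) for tasks like cancer risk stratification or liquid-biopsy
screening runs into two obstacles: the feature space (tens of thousands
of genes times several modalities) is far too long for a standard
transformer, and black-box integration discards the biology a clinician
or biologist needs back out of the model. pathomix addresses both by
keeping every learned quantity attached to a biological unit:

- **Compacted gene embedding**: statistical indicators (score, count,
  min, max, mean, entropy, weighted means) collapse each modality to
  gene level; concatenation gives each gene a short multi-modal vector,
  so the sequence length is the number of genes, not features.
- **Pathway-based sparse neural network (PSNN)**:
  `E_P = (M ∘ W)ᵀ E_G + B`, a linear layer whose weight support is the
  binary gene–pathway membership mask `M`. Weights off the mask are
  exactly zero before, during and after training.
- **Criss-cross attention with crosstalk bias**: 3 blocks × 8 heads.
  Pathway-axis attention uses the pathway crosstalk network `P` as an
  additive logit bias (`softmax(QKᵀ/√d + P)`); feature-axis attention
  exchanges information between modalities; gated head merging, GELU
  feed-forwards and a β-scaled residual complete each block; `P` is
  updated per block from the batch-mean embedding (`P' = Ē Ēᵀ / Dp`).
- **Classifier head**: pooled pathway embedding → 300/200/100-unit
  fully connected layers → class probabilities.
- **Interpretation**: attention-based modality contributions, Shapley
  values for pathways (top 15) and genes (top 5 per pathway), core
  modality per gene, per-sample pathway scores, and hub sub-networks of
  the updated crosstalk network.

Everything runs on a hand-written reverse-mode autodiff engine over
batched arrays (RcppArmadillo kernels) — no Python or GPU dependency —
and a synthetic multi-omics generator with planted pathway effects makes
every stage testable without downloads.

## Worked example

```r
library(pathomix)

# a synthetic study: 120 samples, 3 modalities, 10 pathways, 2 planted
sim  <- generate_dataset(sim_config(n_samples = 120, n_genes = 100,
                                    n_pathways = 10, n_planted = 2,
                                    effect_size = 2, seed = 7))
coll <- sim$collection
mask <- build_mask(coll)                     # genes x pathways, binary
ct   <- build_crosstalk(coll)                # hypergeometric crosstalk
eg   <- prepare_embedding(sim$modalities, coll$gene_universe)
dim(eg)                                      # genes x indicators x samples

cv <- cross_validate(eg, sim$labels$label, mask, ct$matrix,
                     cv_plan(k = 5, repeats = 2, seed = 1),
                     train_config(epochs = 15, patience = 4, seed = 1))
glance(cv)

fit <- train_model(eg, sim$labels$label, mask, ct$matrix,
                   train_config(epochs = 15, patience = 4, seed = 1))
imp <- shap_importance(fit, eg[, , 1:40], eg[, , 41:120],
                       level = "pathway", n_perm = 24, seed = 1)
head(imp, 6)
sim$truth$planted_pathways
```

Output from this exact script:

```
#> [1] 100   7 120
#> # A tibble: 1 × 9
#>   n_folds mean_macro_f1 sd_macro_f1 mean_weighted_f1 sd_weighted_f1 mean_auc
#>     <int>         <dbl>       <dbl>            <dbl>          <dbl>    <dbl>
#> 1      10             1           0                1              0        1
#> # ℹ 3 more variables: sd_auc <dbl>, mean_sens99 <dbl>, sd_sens99 <dbl>
#> # A tibble: 6 × 5
#>   entity kind      shap direction  rank
#>   <chr>  <chr>    <dbl>     <dbl> <int>
#> 1 pw07   pathway 0.178    0.0189      1
#> 2 pw03   pathway 0.108    0.0242      2
#> 3 pw01   pathway 0.0647  -0.00438     3
#> 4 pw10   pathway 0.0505   0.0156      4
#> 5 pw05   pathway 0.0333   0.00531     5
#> 6 pw04   pathway 0.0321   0.00135     6
#> [1] "pw04" "pw07"
```

The gene embedding has 7 dimensions (expression `f1`; methylation
count/min/max/mean/entropy; CNV `f1`). Cross-validated macro-F1 of 1.0
shows the planted two-pathway effect is recovered perfectly. Both
planted pathways (`pw04`, `pw07`) sit in the SHAP top 6 of 10, with
`pw07` first; the generator builds pathways with ~30% gene overlap, so
pathways sharing planted genes (`pw03`, `pw01`, `pw10` here) also carry
real signal and legitimately pick up part of the credit — importance is
attributed to the input information a pathway's genes carry, not to
pathway labels.

A command-line wrapper covers the same pipeline stage by stage:

```sh
Rscript inst/cli/pathomix.R simulate  --config run.yaml --seed 7
Rscript inst/cli/pathomix.R pathways  --config run.yaml
Rscript inst/cli/pathomix.R train     --config run.yaml
Rscript inst/cli/pathomix.R interpret --config run.yaml
```

See `vignettes/pathway-crosstalk-transformer.Rmd` for the model,
its assumptions, and every tuning knob.

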