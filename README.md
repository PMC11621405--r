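# nichecov

Niche interactions and latent-factor covariation for single-cell-resolution
spatial transcriptomics.

Imaging-based spatial transcriptomics (seqFISH, MERFISH/MERSCOPE, Xenium)
resolves individual cells in their tissue context but measures only a panel
of genes. `nichecov` integrates such data with an annotated scRNA-seq
reference and then asks what the tissue context *does*:

1. **Annotation** — label transfer through soft mutual-nearest-neighbor
   anchors in a joint PC space of NB-Pearson residuals, with Leiden guide
   clusters pruning dispersed anchors and gating an iterative majority-vote
   propagation (`annotate_spatial()`).
2. **Interaction** — for each "central" cell type, an L2-penalized
   multinomial classifier predicts the cell's type from its niche
   composition, featurized as enrichment ratios
   `X_ij = Λ_ij / (f_j Σ_k Λ_ik)` over Delaunay or fixed-radius
   neighborhoods. Averaged cross-fold coefficients β rank the niche cell
   types that are predictive of (i.e. preferentially co-localized with) each
   central type, and feed a directed cell-type interaction graph
   (`fit_niche_classifier()`, `build_interaction_graph()`).
3. **Covariation** — per cell type, non-negative latent gene programs are
   learned across modalities (iNMF with an alignment-score-selected penalty
   λ, or KL-NMF on the reference with fixed-basis transfer), ordered by
   entropy, and each central-cell factor is ridge-regressed on the
   neighborhood-averaged factors of its niche partners
   (min_α ‖Σ_m Σ_l α_{l,m} ⟨H_m⟩_niche − H_k[,i]‖² + η‖α‖²), with η chosen
   by leave-one-out CV and two-tailed t-statistic p-values
   (`fit_inmf()`, `fit_onmf_transfer()`, `regress_covariation()`).
   Gene-level readouts associate factors with the full transcriptome and
   nominate ligand–receptor pairs (`associate_genes()`,
   `select_lr_pairs()`).

Because real benchmark tissues require large downloads, the package ships a
**tissue simulator**: 2D Langevin dynamics under pairwise Lennard-Jones
potentials whose well depths ε encode planted cell-type affinities
(`simulate_tissue()`, `scenario_config()`), plus a negative-binomial
expression generator with planted cross-type factor coupling
(`synth_expression()`). Every stage of the pipeline is validated against
these ground truths.

## Worked example

```r
library(nichecov)
set.seed(1)

# simulate the harder affinity layout: eps(T0,T2)=3, eps(T3,T5)=5,
# eps(T2,T3)=10, eps(T1,T3)=8, all other pairs 1
snap  <- simulate_tissue(scenario_config("scenario2"))
graph <- build_neighborhoods(snap$coords, "delaunay_R0", max_dist = 100)
feat  <- enrichment_features(graph, snap$type_labels)
model <- fit_niche_classifier(feat, seed = 1)
rank_niche_predictors(model, "T3")
```

```
  niche     beta    beta_sd
3    T2 1.118290 0.02483512
2    T1 1.027750 0.05789549
6    T5 0.327589 0.03583268
```

The classifier's positive coefficients for central type T3 rank its niche
partners T2 > T1 > T5 — exactly the order of the planted attraction
strengths ε = 10 > 8 > 5. Label transfer closes the loop on synthetic
expression:

```r
dat <- synth_expression(snap, synthetic_expression_config())
ann <- annotate_spatial(dat$sp, dat$ref)
evaluate_annotation(ann$sp$labels, dat$truth$labels)
```

```
$ARI
[1] 1

$Jaccard
[1] 1

$weighted_precision
[1] 1
```

With the generator's default 5 markers per type at depth 1000, every cell
recovers its generating label.

A thin command-line wrapper over these functions lives in
`inst/cli/nichecov.R` (subcommands `simulate`, `annotate`, `interact`,
`covary`, `lrpairs`); the methods vignette
(`vignettes/niche-covariation.Rmd`) documents the models, defaults, and
numerical choices.

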