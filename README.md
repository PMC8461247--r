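# tensoromics

Gene-centric multi-omics integration by non-negative tensor decomposition,
for cohorts with matched gene-expression, promoter-methylation and
miRNA-expression profiles per patient (e.g. tumor collections with subtype
or clinical labels). The package is aimed at analysts who want
phenotype-associated latent features — and the genes and omics layers that
carry them — rather than a black-box classifier.

## What it computes

Each omics layer is encoded per gene so all layers share gene × sample axes
(promoter probes averaged over the strand-aware 2 kb window upstream of the
TSS; miRNAs bundled per target gene by geometric mean), normalized
(log2 + quantile for expression-scale layers, quantile for betas), min-max
scaled, and stacked into a non-negative tensor `T` (genes × samples ×
omics). `T` is decomposed by non-negative PARAFAC/CP:

    T[i,j,k] = Σ_f  C_g[i,f] · C_p[j,f] · C_o[k,f]  +  e[i,j,k],   f = 1..R

fit by HALS (alternating non-negative least squares) from algebraic
(generalized-eigenvalue) multi-starts with collapsed-column revival.
Label-specific
features are selected from the patient factor `C_p` by one-vs-rest lasso

    min_w Σ_i (y_i − Σ_f z_if w_f)² + α Σ_f |w_f|

(top 20% of nonzero weights by |w|), genes map to features by row-argmax of
`C_g`, features to omics layers by column-argmax of `C_o`, and the selected
feature genes are scored by stratified 10-fold cross-validated MLP
classification (macro F1), either transductively or with a strict
split-before-normalization protocol. Rank can be estimated by NMF
consensus-dispersion elbow. A synthetic-cohort generator with planted CP
structure makes the whole pipeline testable end to end.

## Worked example

```r
library(tensoromics)

# a matched 3-omics cohort: 300 genes x 80 samples, 4 subtypes, true rank 8
cohort <- generate_cohort(seed = 7)

dec <- parafac_nn(cohort$tensor, rank = 8, seed = 1)
dec
#> Non-negative CP decomposition: rank 8, 300 genes x 80 samples x 3 omics
#> relative error 0.110609 after 500 sweeps (max_iter reached), seed 1

sel <- select_all_labels(dec$C_p, cohort$labels, alpha = 0.01)
lapply(sel$selections, function(s) s$selected)
#> $L1: 1 4    $L2: 5 8    $L3: 3 7    $L4: 2 6

asg <- assign_genes(dec$C_g, sel)
lengths(asg$label_genes)
#>  L1  L2  L3  L4
#> 145  67  42  46

genes <- sort(unique(unlist(asg$label_genes)))
X <- build_classifier_input(cohort$tensor, genes)
cross_validate(X, cohort$labels, eval_config(mode = "transductive", seed = 1))
#> transductive cross-validation over 10 folds: mean macro F1 = 1.0000 (pooled 1.0000)
```

The relative error (~0.11) is the noise floor of the generated cohort; each
subtype's two selected features are exactly its two planted ones, and the
selected genes separate the four subtypes perfectly. `run_pipeline()` runs
the same chain from raw TSV/BED inputs and writes factor matrices, per-label
weights, gene assignments and evaluation results as TSV/JSON artifacts;
`cv_strict()` / `omics_ablation()` give the leakage-free protocol and the
per-omics-subset comparison.

There is also a command line (`inst/scripts/tensoromics`):

```sh
tensoromics simulate --out cohort/ --seed 7
tensoromics run --config run.txt
tensoromics alpha-sweep --config run.txt --alphas 0,0.001,0.01,0.05
```

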