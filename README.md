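# mcfa — multicellular factor analysis of cross-condition single-cell data

`mcfa` asks a tissue-level question of patient-resolved single-cell
atlases: which combinations of cell types change their gene expression
*together* across samples and conditions? Instead of testing cells, it
treats each **sample** as the unit: cells are summed into
per-(sample, cell type) pseudobulk profiles, each cell type becomes one
**view** of the samples, and an unsupervised group factor analysis
recovers **multicellular programs** — latent factors with per-cell-type
gene weights and per-sample scores.

The model, for view (cell type) $m$, group (study) $g$, sample $n$ and
gene $d$:

$$y^{m,g}_{nd} = \sum_{k=1}^{K} z^g_{nk} w^m_{dk} + \varepsilon, \qquad
\varepsilon \sim N(0, 1/\tau^{m,g}_d),$$

with automatic relevance determination priors
$w^m_{dk} \sim N(0,1/\alpha^m_k)$ and $z^g_{nk} \sim N(0,1/\beta^g_k)$:
$\alpha$ switches factors off per view (programs engaging only some cell
types), $\beta$ per study (shared versus study-specific variability).
Inference is deterministic mean-field variational Bayes (seeded
initialization, monotone ELBO, NA-masked missing views — no imputation).

Around the model, the package implements the full workflow:

* **views** — pseudobulking (min 25 cells), gene QC (100 counts in a
  sample, detected in ≥ 25% of samples), TMM + log-CPM normalization,
  highly variable genes, ambient **background-gene exclusion**,
  per-group centering/scaling; CLR composition views and
  spatial-dependency views (top 21 most variable interactions).
* **programs** — Kruskal–Wallis / linear-model factor–covariate
  association with BH correction; cell-type factor signatures
  (|loading| ≥ 0.1, split by sign); permutation-normalized weighted-mean
  scoring; hypergeometric cell-state enrichment; condition-vs-state
  variance partitioning (eta-squared, log2 ratios).
* **spatial** — signature scores per spot (cell type proportion ≥ 0.1),
  relative activation areas (z > 2), Wilcoxon condition comparisons.
* **transfer** — Moore–Penrose projection of new cohorts into a
  reference latent space; signature scoring of bulk studies; silhouette
  evaluation.
* **synthetic** — seeded generators with planted ground truth for every
  stage (multi-view, single-cell atlas with ambient contamination,
  spatial slides, bulk cohorts).

## Worked example

```r
library(mcfa)

sim <- simulate_single_cell(seed = 11)   # planted condition program
sim$cells
#> cell_profiles: 3600 cells x 300 genes; 20 samples, 3 cell types

res <- run_pipeline(sim$cells, pipeline_config(seed = 11), out_dir = "demo")
res$model
#> gfa_model: K=6, 3 views, 1 groups, 193 iterations (converged)
#>   total explained variance: 98.1%

head(res$associations[order(res$associations$padj), ], 3)
#>  factor covariate  statistic            p         padj
#> Factor1 condition 14.2857143 0.0001570523 0.0009423137
#> Factor2 condition  0.1428571 0.7054569861 0.7623688185
#> Factor3 condition  0.1428571 0.7054569861 0.7623688185

res$signatures[["CT1.positive"]]
#> factor_signature: CT1, factor 1, positive, 12 genes

round(res$model$r2$per_factor[, 1, 1:3], 3)
#>     Factor1 Factor2 Factor3
#> CT1   0.982   0.001   0.000
#> CT2   0.969   0.001   0.001
#> CT3   0.983   0.001   0.001
```

Factor 1 is the planted multicellular program: it is the only factor
associated with the condition (Kruskal–Wallis BH-adjusted p ≈ 9e-4), it
explains ~97–98% of every cell type's pseudobulk variance in this
noise-free-by-design simulation, and its thresholded positive signature
for cell type CT1 contains exactly the 12 planted up-regulated genes.
The remaining factors are shrunk to noise level by ARD. `demo/` then
holds the model bundle, factor scores, associations and signature TSVs.

A thin CLI wraps the same functions:

```sh
Rscript inst/exec/mcfa simulate --out atlas --seed 5
Rscript inst/exec/mcfa run --counts atlas --out results_dir --seed 5
```

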