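---
title: "Multicellular factor analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicellular factor analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcfa)
```

## The problem

Cross-condition single-cell atlases profile many patients, each
contributing cells of several types. Questions about *tissue-level*
disease processes — which combinations of cell types change their
expression together across patients — are awkward to answer cell by
cell. `mcfa` takes the sample as the statistical unit: cells are summed
into per-(sample, cell type) pseudobulk profiles, each cell type becomes
one *view* of the samples, and an unsupervised multi-view factor model
recovers *multicellular programs*: latent sample scores whose
cell-type-specific gene weights describe a coordinated expression change
across the tissue.

## From cells to views

1. **Pseudobulking.** UMI counts of all cells of a type in a sample are
   summed. Profiles built from fewer than 25 cells are discarded — they
   are dominated by sampling noise and ambient contamination.
2. **Gene QC.** Within a view, a gene is kept if its maximum count
   reaches 100 in at least one sample and it is detected in at least 25%
   of samples (boundary kept).
3. **Normalization.** Trimmed-mean-of-M-values size factors
   (reference sample by the 75th-percentile rule, 30%/5% two-sided trims
   on M and A, inverse delta-method-variance weights, factors rescaled to
   geometric mean 1), then `log2(CPM + 1)`. The implementation follows
   the published algorithm and agrees with `edgeR::calcNormFactors` to
   1e-10, which the test suite asserts on random count matrices.
4. **Highly variable genes.** A loess trend (span 0.3; quadratic
   polynomial below 30 genes) of per-gene variance against mean;
   `normvar` keeps genes with variance/trend > 1.5, `biovar` keeps genes
   with variance − trend > 0.
5. **Background exclusion.** Droplet data carries cell-free mRNA, so
   highly expressed markers of one cell type contaminate every other
   type's pseudobulk. For each view we remove highly variable genes that
   are markers of *another* cell type (own markers exempt). Markers are
   one-vs-rest Welch t-tests on log-CPM pseudobulks (lfc > 1,
   BH-adjusted p < 0.01). The published workflow uses edgeR
   quasi-likelihood models here; a Welch test is sufficient because the
   filter only needs high-confidence markers, and it keeps the negative
   binomial machinery out of scope. Marker contrasts run on the
   *unfiltered* pseudobulks: per-view gene QC removes precisely the other
   types' markers from a view, which would blind the contrast.
6. **Assembly.** Views are aligned on the union of sample ids; samples
   absent from a view are recorded missing (never zero-filled). Every
   feature is centered per group; with more than one group (multi-study
   integration) each feature is additionally scaled to unit variance per
   group, and features constant within a group are masked for that group.
   Unit variance is our reading of the per-study feature scaling; the
   source workflow does not pin the scheme down.
7. **Structural views** (optional). Cell-type compositions enter as
   centered log-ratios (zeros replaced by half the smallest positive
   part, then re-closed); spatial-dependency importances from a
   spatially contextualized model enter as the 21 most variable
   interactions per context.

## The factor model

For view $m$, group (study) $g$, sample $n$ and feature $d$:

$$y^{m,g}_{nd} = \sum_{k=1}^{K} z^g_{nk}\, w^m_{dk} + \varepsilon^{m,g}_{nd},
\qquad \varepsilon \sim N(0, 1/\tau^{m,g}_d)$$

with automatic relevance determination (ARD) priors
$w^m_{dk} \sim N(0, 1/\alpha^m_k)$, $z^g_{nk} \sim N(0, 1/\beta^g_k)$ and
Gamma(1e-3, 1e-3) hyperpriors on all precisions. $\alpha^m_k$ lets
factor $k$ switch off in view $m$ (a program involving only some cell
types); $\beta^g_k$ lets a factor be study-specific. For single-group
data $\beta \equiv 1$ so scores keep a standard-normal prior. Noise
precision is per feature per (view, group) because per-study noise
differs in meta-analysis settings. There is no spike-and-slab sparsity
and no non-Gaussian likelihood.

Inference is mean-field coordinate ascent with the posterior fully
factorized over the scalar scores and weights, updated factor by factor
against a running residual. We initially implemented joint row updates
with full $K \times K$ posterior covariances; both variants maximize a
valid ELBO monotonically, but the joint family admits rotated optima —
the likelihood is invariant under rotations of $(Z, W)$ and only the
axis-aligned ARD priors break the tie, too weakly once views go missing.
The fully factorized family cannot represent posterior correlations
between factors, which steers coordinate ascent to axis-aligned
solutions; on synthetic data with 30% missing views it recovers planted
factors at $|r| \ge 0.98$ where the joint variant stalled near 0.6–0.9.

Details that matter for reproducibility:

* Scores are initialized from a seeded standard normal, weights at zero.
  The first iteration therefore begins with the weight update (updating
  scores first from zero weights would collapse them to the prior mean —
  a degenerate fixed point); afterwards the order is
  Z, W, $\alpha$, $\beta$, $\tau$, ELBO.
* Entries recorded NA — including wholly missing (sample, view) pairs —
  are masked out of every sufficient statistic; no imputation anywhere.
* Iteration stops when the relative ELBO change drops below `tol`
  (default 1e-6) or after `max_iter` (default 1000). Identical data and
  seed give bitwise identical traces.
* $K$ is fixed by the user (default 6); ARD shrinks surplus factors
  instead of dropping them during training, and `postprocess_factors`
  flags factors under 0.5% total explained variance as inactive —
  reproducibility over heuristics.
* `postprocess_factors` orders factors by total explained variance and
  flips each factor's sign so the cubed-weight sum is positive in its
  top view; the reconstruction is invariant (asserted to 1e-10).

Explained variance is $1 - \sum (y - \hat y)^2 / \sum y^2$ over observed
entries, per (view, group, factor) with single-factor reconstructions
and per (view, group) with the full one. Raw values may be negative and
are reported as computed.

## Downstream procedures

* **Association**: per covariate, tie-corrected Kruskal–Wallis tests
  (categorical) or simple-regression F-tests (continuous) of each
  factor's scores, BH-adjusted across factors within the covariate.
* **Signatures**: per cell type, loadings of the chosen factor with
  $|w| < 0.1$ zeroed; survivors split by sign. Interpretation of the
  signs follows the factor–covariate direction.
* **Weighted-mean scoring**: $s = \sum_g x_g w_g / \sum_g |w_g|$; the
  null reassigns the weights to genes drawn uniformly without
  replacement from the measured universe (gene identity is permuted, not
  sample labels, matching the cited scoring tool), and
  $z = (s - \mu_{null})/\sigma_{null}$ per sample. 1000 permutations for
  functional scoring, 100 for spatial and bulk use. A degenerate null
  (sd 0, e.g. an empty spot) yields $z = 0$ with a flag rather than an
  error, because constant-expression spots do occur in sparse spatial
  data.
* **Cell-state enrichment**: upper-tail hypergeometric tests of state
  markers in signature genes, BH across states within a cell type,
  positive and negative signatures separately.
* **State independence**: per signature gene, one-way ANOVA
  $\eta^2$ by condition (sample pseudobulks) and by cell state
  (state pseudobulks from ≥ 25 cells); $r = \log_2(\eta^2_{cond} /
  \eta^2_{state})$ for genes with both positive (others counted and
  excluded — the log is undefined); a one-sample t-test of $r$ against 0
  summarizes each cell type, with a Shapiro–Wilk check reported
  alongside. Both are reported; neither gates results.
* **Spatial mapping**: spots are scored with the slide's own gene
  universe; spots where the signature's cell type is below proportion
  0.1 are masked (NA, never 0 — 0 is a meaningful score). The effective
  area is the number of spots at or above the proportion threshold; a
  spot is active when $z$ strictly exceeds 2 (boundary inactive); the
  relative activation area is their ratio. Condition comparisons use
  two-sided Wilcoxon rank-sum tests with BH families per condition pair.
* **Projection**: new cohorts, processed by the same pipeline and
  centered on their *own* feature means (this changes score offsets and
  is deliberate — each study is processed independently), are projected
  by the Moore–Penrose pseudoinverse of the concatenated reference
  weights, restricted to shared (view, gene) pairs (row restriction, not
  zero-filling). Rank-deficient weight matrices return the minimal-norm
  solution with a flag.
* **Bulk transfer**: within each study, genes are z-scored across
  samples (never pooling studies), then scored per sample; silhouette
  widths on Euclidean distances compare how well signature scores versus
  CLR compositions separate conditions.

## The synthetic data generators

The generators are first-class, tested code; they emulate the structure
of deposited cross-condition atlases so that every stage can be tested
against planted truth without downloads.

* `simulate_multiview`: $Z \sim N(0,1)$, $W \sim N(0,1)$ masked by a
  (view, factor) activity pattern, $Y = ZW^\top +$ noise, optional
  missing views, centered per group. The default activity pattern gives
  each factor a *distinct* active-view subset (all views; each view left
  out; pairs left out), mirroring programs that engage subsets of cell
  types — and making the planted factors identifiable beyond a rotation,
  which full-activity patterns are not.
* `simulate_single_cell`: multinomial cells with log-normal depth
  (median ≈ 2500); 3 cell types × 2 states × 2 conditions × 10 samples
  each, 300 genes, 60 cells per (sample, type) by default — sized so a
  full pipeline run takes seconds on one CPU. Planted per type: 10
  markers (structural zeros outside the type at $\lambda = 0$), 8
  markers per state, and a condition program (12 up / 8 down genes,
  3-fold). Ambient contamination mixes every cell's probabilities with
  the pooled mean profile at rate $\lambda$ (default 0.1) — a single
  pooled ambient profile, the simplest mechanism that makes marker genes
  leak across cell types and exercises the background filter.
* `simulate_slides`: 12×12 spot grids, niche-banded Dirichlet
  proportions, and program genes shifted by ±2.5 in a contiguous 40% of
  the target type's effective spots on case slides. Spot expression is
  emitted per-gene centered within each slide: without centering, the
  planted relative area is not identifiable by the weighted-mean z-rule
  even in principle, because a signature inherits the baseline offset of
  whichever genes it contains.
* `simulate_bulk_cohort`: bulk = composition-weighted mixture of
  cell-type profiles, program genes shifted 3-fold in cases, log-normal
  noise; default compositions are condition-independent so that
  signature scores, not composition, carry the condition signal.

What passing these tests does *not* show about real data: no doublets or
dropout curves beyond multinomial sampling, a single pooled ambient
profile, spatially uniform gene baselines on slides, and no
cross-platform batch structure in bulk cohorts.

## Numerical choices and degenerate inputs

* TMM: samples with zero library size are errors; under two samples the
  filters and factors are undefined and raise errors. Identical or
  depth-scaled libraries give factors exactly 1.
* Centering checks: the model constructor rejects data whose observed
  per-group column means exceed 1e-4 and points to `assemble_views`.
* CLR of a zero part uses multiplicative replacement (half the smallest
  positive part) because the transform is undefined at zero.
* Welch tests on zero-variance contrasts fall back to comparing means
  (p 0 or 1); classes with fewer than 2 replicates (pseudobulk) or 3
  cells (cell level) are skipped with warnings.
* Model persistence writes full-precision (`%.17g`) CSV plus JSON — a
  plain-text bundle that round-trips exactly and is byte-stable on
  re-save; a version tag guards format drift.
* Pipeline stage seeds are derived from the single config seed by fixed
  offsets, and every randomized function takes an explicit seed without
  touching the caller's RNG state.

## Problem sizes used in the checks

The test suite and acceptance script run entirely on the generators
above: 50 small random datasets for ELBO monotonicity; the factor
recovery checks at 3 views × 300 features and 2 groups × 50 samples
(with and without 30% missing views); the pipeline check at the
single-cell defaults (3,600 cells); spatial checks on six 144-spot
slides; bulk checks on 30 samples. These sizes were chosen so each stage
is informative yet the whole battery completes in minutes on one CPU.

## Known limitations

* Parity with other multi-view factor tools is at the subspace level,
  not parameter-by-parameter; hyperpriors and convergence schedules
  differ between implementations.
* The `normvar` highly-variable-gene rule is a faithful variance/trend
  ratio; exact parity with external adaptations of that rule is not
  guaranteed.
* Factor recovery relies on factors differing in their active-view
  patterns (or strengths); a latent space whose factors are active
  everywhere with equal strength is identifiable only up to rotation —
  for any method of this family.
* The weighted-mean z-score on uncentered expression carries the
  baseline offset of the signature's genes; on real slides the relative
  activation area should be read comparatively (across slides and
  conditions), not as an absolute calibrated rate.
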