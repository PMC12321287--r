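---
title: "Chunked single-cell analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chunked single-cell analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunkcell)
```

## Why chunks

Sparse matrix libraries that index stored values with 32-bit integers cap out
at 2^31 − 1 non-zero entries. `chunkcell` partitions the cell×gene matrix
into contiguous **row chunks** (cells), each below a configurable non-zero
cap (default exactly 2^31 − 1, kept even though a CPU build has no hard
limit, so the planner remains testable against the real constraint). Packing
is greedy first-fit in row order: a row opens a new chunk exactly when adding
it would overflow the cap. Greedy packing was chosen over balanced
partitioning because it preserves row order, which keeps every downstream
result reproducible; a single row above the cap is an unsatisfiable plan and
an error. Coordinates are 0-based half-open intervals; rows are cells.

Three storage backends share one iteration contract — `resident` and `host`
keep the chunk blocks in memory (`resident` is an alias with an injectable
array backend left as the acceleration extension point), `stream` writes each
chunk to disk and re-reads it lazily on every pass. All statistics in the
package are written against the iteration contract only, so the backends are
observationally equivalent and every deterministic stage is invariant to the
chunk plan (exactly for integer accumulations, ≤1e-10 relative for floating
stages; the suite checks plans of 1, 4, 17 and 64 chunks).

HDF5-backed input is not provided in this build: no R HDF5 binding is
declared among the package's dependencies, so the on-disk interchange format
is the 10x-style MatrixMarket triplet directory (genes × barcodes on disk,
1-based indices converted on read).

## Quality control and normalization

Per-cell statistics (expressed genes, total counts) are complete within a
chunk; the per-gene expressing-cell count is the one cross-chunk array,
updated incrementally so one pass finalizes both filters. The gene filter is
evaluated on expressing-cell counts over *all* cells — i.e. before the cell
filter — matching the single-pass streaming design; a stricter two-pass
variant can be had by re-running QC on the filtered store. Default
thresholds (min 200 genes/cell, min 3 cells/gene) are the field's
conventional placeholders and are exposed in the config.

Normalization scales each cell to a fixed total (default 10⁴) and applies
log(1+x). The plain log1p of raw counts is available by setting
`target_sum = NULL`, but the scaled default is what makes per-gene variances
comparable for feature selection. Both are chunk-local per cell, hence
bit-identical across chunk plans; zero counts map to zero so sparsity is
preserved.

## Highly variable genes (Seurat v3 flavor)

Two streaming passes over raw counts:

1. Running sums s and s² per gene give μᵢ = sᵢ/N and the **sample** variance
   σᵢ² = N/(N−1)(s²ᵢ/N − μᵢ²). The N−1 divisor matters: substituting the
   population variance shifts the variance estimates and, with them, the
   selected gene set, so a regression test pins the N−1 path.
2. A LOESS fit (degree 2, span 0.3 — the Seurat-v3 convention; computed with
   the exact "direct" surface so the fit is a pure local weighted quadratic
   regression, reproducible to machine precision against an independent
   implementation) of log₁₀σ² on log₁₀μ yields a fitted standard deviation
   σ′ᵢ per gene. Counts are standardized as x′ = min((x−μ)/σ′, c) and the
   sample variance of x′ over **all** N cells is the ranking statistic. The
   N−nnz implicit zeros of a gene all standardize to min(−μ/σ′, c), so their
   sum and sum of squares are added in closed form — pass 2 touches only
   stored values.

The clip bound c defaults to √N (the convention of the ecosystems this
reproduces); `clip = "n"` clips at N instead, and both paths are tested.
There is no lower clip. Genes with zero mean or zero variance get σ′ = 0 and
are excluded from selection. Ties at the top-K boundary break toward the
lower gene index.

## PCA by Gram accumulation

With M ≈ a few thousand HVGs, the M×M centered scatter is far cheaper to
decompose than X is to factor. One pass accumulates XᵀX = Σₖ XₖᵀXₖ and the
column sums s; the identity

(X−m)ᵀ(X−m) = XᵀX − mᵀs − sᵀm + N mᵀm

then gives the centered scatter without ever centering the sparse data
(centering would densify it). Eigendecomposition of the symmetrized scatter
yields components and variances; a second pass projects chunks, applying the
centering as a rank-one offset after the sparse product.

Eigenvector signs are arbitrary, so each component is flipped to make its
largest-magnitude loading positive (ties to the lowest index). This makes
repeated fits bit-identical and protects everything downstream — batch
correction takes the embedding as input, so a sign flip would otherwise
change final clusters. Default 50 components. Optional per-gene
standardization Z = (X−μ)/(σ+ε), ε = 1e-8, folds into the scatter as
D⁻¹SD⁻¹ and into the loadings at projection time; it is off by default
because the chunked derivation centers only, and unit-variance scaling gives
every noise gene the same weight as a marker.

## Harmony with sparse designs

Harmony alternates two steps on the d×N embedding:

- **Soft k-means with a diversity penalty.** Cells and centroids are
  L2-normalized (cosine geometry); assignments are
  R ∝ exp(−2(1−YᵀZ)/σ) · ((E+1)/(O+1))^θ Φ, where O = RΦᵀ is the observed
  cluster×batch co-occurrence and E its expectation under batch independence.
  R is updated in randomly ordered blocks of 5% of cells with E and O
  maintained incrementally — the block-coordinate scheme the objective's
  convergence relies on; a full-batch update (`block_size = 1`, available
  for analysis) can oscillate. Defaults: σ = 0.1, θ = 2, K = min(100, N/30),
  10 outer iterations, objective tolerance 1e-4.
- **Mixture-of-experts ridge correction.** Per cluster k,
  W_k = (Φ_Rk Φ_moeᵀ + Λ)⁻¹ (Φ_Rk Z_origᵀ) with Λ = diag(0, λ, …, λ): the
  intercept row is never penalized and never used for correction; λ = 1 on
  batch rows. Φ (B×N one-hot), Φ_moe (intercept row prepended) and Φ_Rk
  (Φ_moe scaled by cluster responsibilities) are sparse with ≈N and ≈2N
  stored values, and the right-hand product Φ_Rk Z_origᵀ — a (B+1)×d
  matrix — is computed *first*, so the (B+1)×N dense intermediate of the
  left-to-right order never exists. Peak additional memory is
  O(N(K+d) + B(K+d)). A cluster with vanishing total responsibility
  contributes W_k = 0.

Centroid initialization is k-means++ from a sequential RNG stream: the same
seed gives bit-identical seeds on any platform. `one_step` refines with the
package's own Lloyd loop; `two_step` (default) hands refinement to a
pluggable backend — the hook for accelerated k-means implementations — which
defaults to the same Lloyd loop, so the two modes coincide in this build.

With one batch the design is collinear with the intercept and the penalized
batch coefficient is exactly zero, so the embedding passes through unchanged
— a useful identity check.

## Neighbors, Leiden, UMAP

Neighbor search is **exact**: blockwise brute-force Euclidean distances
(default 4096 query rows per block, O(block×N) memory), ties broken by the
lower cell index, self excluded. Approximate search trades graph determinism
for speed and is deliberately not offered. Connectivities use the UMAP-style
adaptive kernel — per cell, bandwidth σᵢ solved by bisection so the kernel
mass equals log₂k above the nearest-neighbor distance ρᵢ — symmetrized by
the fuzzy union A + Aᵀ − A∘Aᵀ. This choice is conventional rather than
derived: the kernel is what the surrounding ecosystems compute.

Leiden (igraph, modularity objective, resolution 1) and UMAP (uwot) are
delegated, not re-implemented; both record their seed. Leiden labels are
relabeled 0..k−1 by decreasing size. UMAP layouts reproduce only under
pinned library versions.

## Markers and cluster merging

Per cluster, a one-vs-rest binary gradient-boosted tree ensemble (100 trees,
depth 6, η = 0.3, single thread, sparse input) ranks genes by total gain.
Candidates (top 30) are filtered by a binary specificity score —
(fraction of cluster cells expressing) × (1 − median expressing fraction of
the other clusters), "expressing" meaning a positive log-normalized value —
with threshold 0.1, and the **final top-m (default 5) are ordered by the
product of gain importance and binary score**. The composite is a deliberate
design choice with a failure mode behind each factor: gain alone admits noise
genes the booster used to split a cluster from its sister subcluster of the
same cell type (high gain, chance-level specificity), while specificity alone
drops a strong marker whose nonzero baseline expression dilutes its binary
score below that of random genes. Requiring both keeps marker sets stable
across re-clusterings of the same population, which the overlap-based merging
below depends on. No HVG pre-filter is applied by
default, so marker search sees the full gene universe.

Each cluster's set G_i is graded by a decision-tree F score: per gene, a
depth-1 tree fitted on cluster membership supplies a split threshold (falling
back to "expressed at all" when no split improves purity); a cell is
predicted positive when **every** gene in G_i exceeds its threshold, and
S_i is the F_β of that rule (β = 0.5, precision-weighted). Conjunction rules
under dropout noise give modest absolute scores — five genes at ~50%
per-gene recall compound — so S_i is best read as a relative quality signal:
clusters that genuinely own their markers score several-fold higher than
subclusters sharing markers with a sibling.

Merging: clusters are high quality iff S_i ≥ t_C (default 0.5, boundary
counts as high). For every pair, the overlap fraction |G_i ∩ G_j| / |G_i| is
computed in both directions; the pair is a candidate iff either direction
reaches t_G (default 1 — only identical marker sets merge; the threshold is
deliberately stringent). Pairs with two high-quality members never merge;
the rest merge transitively via union-find (a chain A–B–C with only B low
quality collapses all three), and each component takes the id of its largest
member. Lowering t_G can only grow the candidate set, so the number of
output clusters is monotone in t_G. The either-direction rule and the
transitive closure are design choices: the asymmetric count has no canonical
direction, and pairwise-only merging cannot express the observed collapse of
several subclusters into one type.

## Synthetic data: what it emulates, what it does not

The generator draws negative-binomial counts (dispersion 0.5, i.e.
variance μ + 0.5μ²) with per-gene baseline means log-normal across genes
(median 0.1, sdlog 1.2 — ≈90% zeros overall, the sparsity regime of real
UMI data). Each of K planted clusters owns `markers_per_cluster` exclusive
marker genes whose mean is multiplied by `marker_fold_change` (default 8)
inside the cluster. Marker baselines are drawn log-normal with median 1
(sdlog 0.25): an in-cluster mean of ~8 counts with ~4% dropout, the
"strongly expressed canonical marker" regime — markers so weakly expressed
that even a supervised classifier on the true marker sets cannot separate
the clusters would make recovery experiments meaningless, and real canonical
markers are precisely the well-detected genes. Batch effects are per-gene
multiplicative log-normal factors on the NB means (sdlog 0.1 by default) —
simple, controllable, and sufficient to exercise the correction step.

What the generator does **not** emulate: library-size heterogeneity beyond
NB sampling, ambient RNA, doublets, gene-gene correlation within programs,
or continuous trajectories. Passing the recovery tests therefore shows the
pipeline's machinery is correct on well-posed planted structure, not that it
resolves every real tissue. A replication scheme (`expand_dataset`) refits
per-cluster NB moments and resamples cells, growing a dataset by an integer
factor at fixed structure, mirroring how large-scale benchmarks are
synthesized from a seed dataset.

## Problem sizes and numerical choices

The test and acceptance workloads run at desk scale, chosen so the full
suite stays interactive: oracle comparisons on 500×200 fixtures, chunk-plan
invariance at 300×80 over {1, 4, 17, 64} chunks, Harmony oracle equality at
B = 5, N = 400, d = 10 and batch-scaling probes at N = 5000,
B ∈ {10, 100, 1000}, and the end-to-end recovery study on the generator's
default 10,000 cells × 2,000 genes (K = 7 clusters, B = 4 batches, 5 markers
each at fold 8). The recovery pipeline uses 500 HVGs and 20 principal
components: with 2,000 total genes and 35 informative ones, 20 components
retain the cluster subspace while halving the noise dimensions a 50-component
embedding would carry.

Numerical conventions, gathered in one place: sample (N−1) variances
throughout; LOESS on log₁₀ scale with the exact direct surface; eigenvalue
ties ordered by the eigensolver and documented as unstable beyond tolerance;
standardization ε = 1e-8; soft k-means renormalizes assignment columns after
every block; ridge systems are solved, never inverted explicitly; kNN ties
break to the lower index; union-find uses no rank heuristic (cluster counts
are tiny). Degenerate inputs fail loudly: empty QC masks, N < 2 for
variances, fewer than 3 positive-mean genes for the trend fit, k ≥ N
neighbors, single-class marker labels.

## Known limitations

- The stream backend materializes chunks once at conversion time (writing
  per-chunk files), so opening a store costs one full read; iteration after
  that is lazy.
- Exact kNN is O(N²d) time; it is the price of graph determinism and is
  practical to ~10⁵ cells on one CPU.
- Harmony here follows the reference update equations with full-precision
  arithmetic; it does not reproduce any particular implementation
  bug-for-bug, and objective traces are comparable only in trend.
- Absolute F scores of conjunction rules are not calibrated across datasets;
  t_C should be chosen relative to the observed score distribution.
- UMAP layouts are version-pinned; only the graph stages are contractually
  reproducible.
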