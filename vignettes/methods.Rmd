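---
title: "Topological stratification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological stratification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
computes, which parameters matter and why their defaults are what they are,
what the built-in simulator does and does not emulate, and where the design
was genuinely open.

## The problem

Large cohorts carry population structure — excess relatedness within
subgroups — that confounds association studies and limits polygenic-score
transfer. Structure is routinely *visualized* (PCA, neighbourhood
embeddings) but hard to *stratify*: centroid methods presume populations
have a centre, need the number of groups in advance, and either discard
"unassignable" individuals or force them into the nearest archetype.
`topostrat` instead treats structure topologically: individuals are
clustered when a chain of locally dense neighbourhoods connects them, so a
recently admixed group occupying a line in PC space is one stratum, not a
fragment of its sources.

## Density clustering with the ε̂ merge rule

The clustering core (`cluster()`, decomposable into `core_distances()`,
`mutual_reachability_mst()`, `build_condensed_tree()`,
`extract_clusters()`) is authored in full in this package:

1. **Core distance**: distance from a point to its `min_samples`-th nearest
   neighbour, *counting the point itself as the first*. This convention
   matches the dominant reference implementation, which keeps the package's
   ε̂ = 0 oracle test meaningful. `min_samples` defaults to
   `min_cluster_size`, likewise the reference convention.
2. **Mutual reachability**: `d_mr(a,b) = max(core(a), core(b), d(a,b))`.
   Sparse regions are pushed apart, so single-linkage on this metric is
   robust to noise chaining.
3. **MST / single linkage**: Prim's algorithm on the dense `d_mr` matrix
   (O(n²) memory; intended for cohorts that fit a dense distance matrix,
   i.e. up to a few tens of thousands of points). Edges are processed in
   ascending (weight, index) order, which fixes tie-breaks and makes the
   whole pipeline deterministic and permutation-equivariant *in general
   position*. Mutual-reachability matrices are saturated with exact ties
   (many pairs share a core-distance bound), so different valid MSTs exist;
   on data with tied edges two correct implementations can disagree on a
   few boundary points. The oracle-equivalence tests use well-separated
   fixtures where the extracted clustering is invariant to the choice of
   tied MST.
4. **Condensed tree**: walking the hierarchy from the root, a split side
   with fewer than `min_cluster_size` points "falls out" at that level
   (recorded per point at λ = 1/distance); a large side becomes a child
   cluster. Stability(C) = Σ_points (min(λ_leave, λ_death) − λ_birth).
5. **Extraction**: excess-of-mass — bottom-up, a cluster is selected when
   its stability is at least the summed stability of its selected
   descendants; the root is never selected, so an unstructured cloud is all
   noise rather than one big cluster. Then the ε̂ rule: a selected cluster
   born at distance < ε̂ is replaced by its lowest ancestor born at ≥ ε̂
   (or the child of the root when no such ancestor exists), merging the
   selected siblings beneath it. Points that left the hierarchy above every
   selected cluster are noise (−1). Labels are renumbered by decreasing
   cluster size for stable reporting.

ε̂ = 0 reproduces classic HDBSCAN, which on biobank-like data fragments
into micro-clusters and discards many points; ε̂ around 0.3–0.5 (in raw
embedded-space distance units — deliberately *not* normalized, so the
threshold composes with the embedding's fixed ~10-unit coordinate scale)
merges micro-structure and brings noise counts close to zero. The package's
three-scale fixture makes the regimes concrete: 9 clusters + 18 noise
points at ε̂ = 0 versus 3 clusters + 0 noise at ε̂ = 0.5.

The boundary semantics follow the selection rule "stability ≥ sum of
descendants" and the merge rule "ancestor born at distance ≥ ε̂"; both
comparisons are measure-zero decisions and only visible on artificially
tied inputs.

## The embedding

`embed()` reduces the leading `input_dims` PCs (default 40, or all
available) with the standard fuzzy-topology recipe: exact k-NN (brute
force; approximate search is out of scope at the package's target sizes), a
locally adaptive kernel (per-point bandwidth σ_i solving
Σ_j exp(−(d_ij − ρ_i)/σ_i) = log₂ k, with ρ_i the nearest-neighbour
distance), probabilistic-union symmetrization, and a layout optimized under
the output kernel 1/(1 + a d^(2b)) with (a, b) fitted from `min_dist`.
Optimization is batch gradient descent with per-pair gradient clipping,
per-point edge-mass normalization, five sampled repulsors per point per
epoch, and a linearly decaying step; initialization is the scaled leading
PCs plus a seeded 1e−4 jitter, so results are deterministic given the seed
and no two inputs embed to exactly coincident points (which would otherwise
produce infinite densities downstream).

Defaults encode the two-doctrine rule. Clustering: `n_components = 5`,
`n_neighbors = 50`, `min_dist = 0`. Visualization (`embed_params_viz()`):
2 components, `min_dist = 0.3`. Raising dimensions above 2 preserves input
neighbourhoods better; `min_dist ≈ 0` lets dense clumps stay dense for the
density clusterer.

Quality is quantified, not assumed: `neighborhood_preservation()` is the
mean Jaccard overlap of k-NN sets before and after embedding (1 for an
identity map, ≈ k/(n−1) for a random one). On the package's 3-blob fixture
the embedding scores ≈ 0.33 at k = 10; the regression floor frozen in the
tests is 0.25. Batch (rather than asynchronous per-edge) updates trade some
within-cluster neighbourhood fidelity for vectorized speed; between-cluster
topology — what the clustering consumes — is preserved much more strongly
(nearest-centroid separability 1.0 on separated blobs).

## PCA and filters

Standardization is the drift-variance convention: centre at 2p̂, scale by
√(2p̂(1−p̂)); missing calls are mean-imputed (equivalently zero after
centring), preserving sample size. The top-k factorization uses LAPACK
directly for small problems and randomized subspace iteration (10
oversamples, 4 power iterations, fixed internal seed) above 512×512. The
randomized path is exactly deterministic and row-permutation-equivariant
because its test matrix depends only on the column count; its leading
(signal) components agree with the dense SVD to ~1e−11 while directions
inside the noise bulk — where eigenvalues are nearly degenerate — may
rotate, which is immaterial for structure discovery and leaves score
orthogonality exact by construction. Sign convention: each component's
largest-magnitude loading is positive.

Filters mirror standard biobank preprocessing (MAF 0.05, missingness 0.1
per sample and per variant, HWE exact mid-p 1e−6, LD pruning in
1000-variant windows stepping by 50 at r² > 0.1, optional exclusion regions
such as the extended HLA block on chromosome 6, 25–33.5 Mb). LD pruning
keeps the earlier variant in genome order (determinism) and repeats its
sliding-window pass to a fixed point, which makes `apply_filters()`
idempotent — a property a single pass does not have, because removals
change window contents.

## The simulator

The generator produces desk-scale cohorts with the statistical signatures
the pipeline is meant to detect; it deliberately substitutes the
Balding–Nichols family for coalescent machinery:

- **Discrete populations**: per SNP an ancestral frequency p̃ ~
  U(0.05, 0.95) (the lower bound mirrors the MAF filter; near-monomorphic
  SNPs carry no structure), population frequencies
  Beta(p̃(1−F)/F, (1−p̃)(1−F)/F) — mean p̃, variance F·p̃(1−p̃) — and
  genotypes Binomial(2, p_j). F = 0 short-circuits to p_j = p̃ exactly.
  Calibration is tested, not asserted: across 50 seeds the mean squared
  sample-frequency difference matches E[p̃(1−p̃)]·(2F + (1−F)/n) within 3%,
  and two-population Hudson F_ST averages to F within 5%.
- **Admixture**: each of an individual's two allele copies picks a source
  with probability Q[i, s], then is Bernoulli(p_s). The demonstration
  design (`admixed_demo_spec()`) draws each admixed individual's ancestry
  from 0.6 + 0.3·Beta(2, 2) (mean 0.75): the admixed cloud is *elongated*
  along the inter-source axis, which makes a spherical k-means always
  reassign part of it to a source, while the bounded support keeps a
  density gap so the topological pipeline can hold it together. Its default
  of 3000 SNPs is the point where that gap clears genotype sampling noise
  at 1000 individuals per population; at 1000 SNPs the clouds genuinely
  touch and *any* density method merges them — an instructive boundary, but
  not the demonstration condition.
- **Stepping stone**: demes on a grid; each deme's frequency is
  (1−m)·own Balding–Nichols draw + m·mean of rook neighbours' draws. One
  parameter m ∈ [0, 0.5] produces the discrete-plus-continuous signature
  (pairwise F_ST rising with grid distance); m = 0 reduces bit-exactly to
  the discrete generator. This frequency-smoothing realization was chosen
  over generation-by-generation migration to keep the design
  single-parameter and analytic.
- **Phenotypes**: shift[label] + N(0, noise_sd) — cluster-structured
  residuals that principal components need not span, the situation ensemble
  smoothing exists to reveal.

One global seed expands into fixed per-stage substreams (frequencies,
genotypes, phenotypes, ancestry), so each stage is independently
reproducible. What the simulator does **not** emulate: linkage
disequilibrium between SNPs, recombination, selection, relatedness or IBD
segments, genotyping batch effects, and realistic site-frequency spectra.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative geometry (discrete, admixed, spatial), not performance on real
biobank data.

## Ensemble smoothing and model comparison

`smooth_phenotype()` implements μ_{p,i} = mean of m over s_p(i), μ_i =
Σ_p μ_{p,i}/|P|. A noise point contributes its own value (singleton
cluster) rather than being dropped, keeping μ_i defined for every
individual — consistent with the near-total cluster coverage the ε̂ regime
produces. The default `param_grid()` crosses dims {3,4,5} × neighbours
{10,15,25,50} × min_dist {0, 0.01} × ε̂ {0.3,0.4,0.5} × minimum size
{25,100} × 2 seeds = 288 parametrizations, all overridable.

`cv_compare()` contrasts a PC-only OLS model with one that adds μ_i (the
smoothed estimate *in addition to* the PCs — the additive formulation is
the stronger and better-specified of the two natural choices). Whether
smoothing inside cross-validation should see test-fold phenotypes is a
genuine leakage question; the default recomputes residuals and cluster
means on training folds only, with a test individual receiving its cluster
mates' training-fold mean (0 — the centre of the training residual scale —
when it has none), and `naive_smoothing = TRUE` reproduces the leaky
variant for comparison.

Two caveats are deliberately engineered in: cluster labels are computed
once on all data (only phenotype information is fold-restricted), and no
p-values are ever attached to cluster-derived statistics — F_ST between
clusters defined from the same genotypes is inflated by the clustering
process itself, so `hudson_fst()` reports the estimate and its caveat, and
nothing else.

## Evaluation choices

- ARI from pair counts under the permutation model; both noise policies
  (noise as own label, or excluded) are available because published
  practice is ambiguous — defaults to `own_cluster`, which penalizes a
  method for discarding points. Degenerate identical partitions return 1.
- k-means++ seeding with 10 restarts behind `stats::kmeans`, seeded and
  deterministic, as the typological baseline.
- Hudson's ratio-of-sums F_ST with finite-sample numerator corrections and
  allele-count denominators: low bias under the very unbalanced cluster
  sizes this method produces.
- Incremental R² as the in-sample difference of nested OLS fits, which is
  non-negative by construction.
- The per-SNP regression of cluster-level R² on cluster-level MAF uses
  cluster-specific allele counts (computed from the cluster's own
  genotypes), the natural reading when clusters are the analysis unit.

## Numerical choices and degenerate inputs

λ = 1/distance maps zero distances to +Inf; coincident-point pathologies
are avoided upstream by the embedding jitter, and a cohort whose points are
*all* identical merges at weight 0 into a single infinite-density cluster.
Distance ties break lexicographically by index. `n = 1` is a single noise
point; `n ≤ min_cluster_size` is all noise (the root is never selectable).
Zero-variance variants are dropped with a warning before PCA;
rank-deficient regression designs drop collinear columns with a warning.
The problem sizes the package targets by default — and the ones its tests
and acceptance study use — are 10³–10⁴ individuals and 10³ SNPs
simulations, where every stage runs in seconds on one core.

## Known limitations

Dense O(n²) distance handling bounds the clustering core at a few tens of
thousands of points; the embedding's batch optimizer trades within-cluster
neighbourhood fidelity for speed; the simulator's independence across SNPs
means LD-driven phenomena (e.g. pruning's real-world effect sizes, local
ancestry) cannot be studied with it; and clusters remain constructs of the
data and parameters — different parametrizations legitimately produce
different strata, which is precisely why the ensemble-smoothing machinery
averages over them rather than electing one.
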