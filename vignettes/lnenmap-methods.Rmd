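---
title: "Building and validating molecular maps of lung neuroendocrine neoplasms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating molecular maps of lung neuroendocrine neoplasms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnenmap)
```

## The problem

Lung neuroendocrine neoplasms (LNEN) span a clinical and molecular continuum
from indolent carcinoids to the aggressive neuroendocrine carcinomas (small-cell
lung cancer, SCLC, and large-cell neuroendocrine carcinoma, LCNEC). Bulk
RNA-seq of a few hundred tumors can be summarized as a two-dimensional
"molecular map" on which each point is a tumor and proximity means molecular
similarity. Such a map is only useful if it can be trusted: a 2D embedding of
a ~5-dimensional group structure (six molecular groups) necessarily discards
information, and different embedding algorithms discard different things.

`lnenmap` implements the full path from a gene-by-sample count matrix to a
quality-controlled map:

1. **Preprocessing** — median-of-ratios size factors, a variance-stabilizing
   log transform, removal of sex-chromosome and mitochondrial genes, and
   selection of the most variable genes (those explaining a chosen fraction,
   by default 50%, of the total variance).
2. **Embedding** — UMAP with all backend defaults except `n_neighbors`, plus
   PCA projections in 2 and 5 dimensions as references.
3. **Neighborhood QC** — the rank-weighted sequence-difference statistic
   $\overline{SD}_k$ and its anchor scaling.
4. **Autocorrelation QC** — per-gene Moran indices across spatial scales and
   the concordance of top-gene rankings between spaces.
5. **Subtype tests** — centroid-proximity Wilcoxon tests for groups whose
   histological and molecular classifications disagree.
6. **Export** — TumorMap-compatible layout and attribute files.

## The neighborhood-preservation statistic

For a sample $i$, let $N_k^{\mathrm{orig}}(i)$ and $N_k^{\mathrm{proj}}(i)$ be
its $k$ nearest neighbors (Euclidean) in the original gene space and in the
embedding. The sequence-difference statistic charges a rank weight for every
neighbor present in one neighborhood but not the other:

$$
SD_k(i) = \tfrac12 \sum_{j \in N_k^{\mathrm{orig}}(i) \setminus N_k^{\mathrm{proj}}(i)} w\!\left(r_i^{\mathrm{orig}}(j)\right)
        + \tfrac12 \sum_{j \in N_k^{\mathrm{proj}}(i) \setminus N_k^{\mathrm{orig}}(i)} w\!\left(r_i^{\mathrm{proj}}(j)\right),
$$

with $w(r) = k - r + 1$ by default: losing one's nearest neighbor costs $k$,
losing the $k$-th neighbor costs 1, so preserving close neighbors matters
more than preserving distant ones. $SD_k(i) = 0$ iff the two neighbor sets
coincide; the maximum, for disjoint sets, is $k(k+1)/2$. The literature
leaves the exact weight unstated in places; `w(r) = k - r` is available via
the `weight` flag, and the test suite's brute-force oracle honours the same
flag. $\overline{SD}_k$ is the mean over samples; small $k$ probes local,
large $k$ global structure.

Because raw $\overline{SD}_k$ values have no absolute meaning, they are
scaled between two PCA anchors:

$$
\overline{SD}'_{k,X} = \frac{\overline{SD}_{k,X} - \overline{SD}_{k,\mathrm{PCA5}}}{\overline{SD}_{k,\mathrm{PCA2}} - \overline{SD}_{k,\mathrm{PCA5}}},
$$

so PCA-5D maps to 0 and PCA-2D to 1 at every $k$ by construction (this
identity is what `scripts/acceptance.R` recomputes). A method at 0 preserves
$k$-neighborhoods as well as a 5-component PCA; above 1, worse than a
2-component PCA; below 0, better than PCA-5D. Since UMAP's optimization is
stochastic, its profile is replicated over independent seeds
(`replicate_umap_sd()`) and summarized as mean ± sd per $k$.

**Numerical choices.** Distance ties are broken by ascending sample index, so
profiles are deterministic even on degenerate data. The default $k$ grid is
every integer in $[2, n-2]$, thinned to at most 100 evenly spaced values:
$k = n - 1$ is excluded because there every method's $k$-neighborhood is the
whole cohort, making $\overline{SD}_{n-1} \equiv 0$ and the anchor scaling
undefined. At any other $k$ where the two anchors happen to coincide the
scaling is likewise undefined; `scaled_sd()` raises an error naming the $k$,
and `run_pipeline()` drops such levels with a warning. Summary means are
split at $k = 30$ ("local" below, "global" above), the approximate size of
the smallest molecular group in the motivating cohort. A paired t-test
across $k$ levels compares two methods' scaled profiles; when the per-$k$
differences have zero variance the t statistic is undefined and the result
is flagged degenerate (identical profiles report a tie with $p = 1$).

## Spatial autocorrelation QC

The Moran index of a gene's expression $x$ over a binary kNN weight matrix
$W$ is

$$
I = \frac{n}{S_0} \cdot \frac{\sum_{ij} W_{ij} (x_i - \bar x)(x_j - \bar x)}{\sum_i (x_i - \bar x)^2},
$$

computed in the original gene space, the PCA-5D projection and the UMAP map,
averaged over $k \in \{5, 10, \dots, 50\}$ (the spatial scale is controlled
by $k$). The weight matrix is left row-wise asymmetric by default — each row
flags exactly its $k$ nearest neighbors, matching what the commonly cited
implementation computes when handed a kNN indicator (for row-constant
weights the two conventions coincide exactly) — with symmetrization behind a
flag. Genes constant across samples have an undefined index and are excluded
with a message. Under random permutation of $x$ the expectation of $I$ is
$-1/(n-1)$, which the test suite verifies by simulation.

Concordance between spaces is measured by ranking genes on mean MI within
each space and intersecting the top-$N$ lists: the observed overlap
proportion is compared with the hypergeometric null mean $N/G$ (and
$(N/G)^2$ for the triple intersection). `euler_counts()` emits the
three-set region cardinalities for an Euler-diagram display, and
`concordance_test()` runs the one-sided paired t-test on per-gene mean MI
between two spaces.

## Subtype placement tests

Given a focal group and two reference groups, each focal sample contributes
its Euclidean distances to the two reference centroids (computed in the 2D
map, after removing any focal samples from the references to avoid
self-attraction). The paired differences enter a one-sided Wilcoxon
signed-rank test. The signed-rank (paired) form is the default because the
two distances of one sample are intrinsically paired; the data being exact
and tie-free at small $n$, five uniform-sign samples give the exact tail
$p = 2^{-5} = 0.03125$. Zero differences are dropped per the standard
signed-rank convention; an all-zero case reports a tie with $p = 1$.
Distances can instead be computed in the pre-embedding gene space by passing
the expression matrix's sample coordinates as the "embedding".

## The synthetic cohort generator

The generator (`generate_cohort()`) provides ground truth for every stage.
Counts are negative-binomial with $\mathrm{Var} = \mu + \phi\mu^2$
(`dispersion` $\phi$; 0 gives Poisson), per-sample library factors are
log-normal with expectation 1, and a configurable minority of "discordant"
samples have mean expression
$(1-w)\,\mu(\text{histology group}) + w\,\mu(\text{molecular group})$.

Group structure is controlled by a similarity matrix $S$ (unit diagonal,
entries in $[0,1]$): an informative gene assigned to group $g$ has mean
$\mu_{gh} = \text{baseline} \cdot 2^{\beta S[g,h]}$ in samples of group $h$,
with $\beta$ the `log2_effect_size`. The identity matrix yields fully
group-private programs, under which the groups sit at the vertices of a
regular simplex — equidistant clusters with no between-group geometry. Real
tumor cohorts are not like that: the published pan-LNEN analyses place the
two LCNEC types between SCLC and the carcinoids (Type II nearest SCLC), the
three carcinoid clusters in their own block, and carcinoid B nearest the
LCNECs (the supra-carcinoid side). The default similarity matrix
(`default_group_similarity()`) encodes exactly those ordinal relations, so
the simulated cohort has global geometry worth preserving — which is the
property the neighborhood QC is designed to measure. With an equidistant
simplex, which neighborhoods a sample has at large $k$ is pure noise and no
embedding can preserve it; the comparison between `n_neighbors` settings is
then meaningless, so the identity matrix is kept available but is not the
default.

Default conditions emulate the motivating cohort: 238 samples split
51/32/37/45/40/33 over SCLC, LCNEC Type I/II and Carcinoid A1/A2/B (the
smallest group ≈ 30 samples); 1,000 genes at desk scale with 300 informative
ones assigned round-robin; baseline mean 100 counts; `log2_effect_size` 1.2
(≈ 2.3-fold subtype programs, enough to separate groups after variable-gene
selection while keeping the UMAP neighbor graph connected, as overlapping
real cohorts are); dispersion 0.3 (typical for heterogeneous bulk tumor
RNA-seq); library-size sigma 0.2; 5% sex-chromosome and 1% mitochondrial
genes (ordinary background genes that exist to exercise the chromosome
filter); and 14 discordant samples (6 SCLC with an LCNEC-II profile, 5
LCNEC-II with an SCLC profile, 3 carcinoid-B supra-carcinoid analogues,
mixing weight 0.8).

One global seed drives a separate RNG stream per stage and per gene, so
enlarging the gene panel never reshuffles existing genes, and identical
configurations are bit-reproducible.

**What the generator does not emulate:** cross-study batch effects, gene–gene
correlation beyond the group programs, gene-specific baselines and
dispersions, continuous within-group gradients, and any read-level
artifacts. Passing the package's tests therefore demonstrates the
correctness and calibration of the statistics on data with planted
structure, not that any particular real dataset will show the same effect
sizes.

## Preprocessing choices

The variance-stabilizing transform is the documented closed form
$\log_2(x/s + 1)$ with median-of-ratios size factors $s$ — it shares the
essential properties (depth correction, count-scale compression) of
dispersion-fit transforms while being exactly reproducible; the
`transform_tag` field records it, and an externally transformed matrix can
be supplied through `lnen_expr()` without touching the rest of the
pipeline. Per-gene variances use the unbiased $n-1$ denominator.
Variable-gene selection takes the shortest variance-sorted prefix reaching
the threshold, with ties broken by input order; total variance is computed
after chromosome filtering, on the transformed scale. PCA centers and
unit-scales genes by default (the convention of the correlation-matrix PCA
used for such maps; scaling can be disabled), and each axis is oriented so
its largest-magnitude loading is positive, making outputs sign-deterministic.
New samples are integrated by **re-running** the whole pipeline on the
combined count matrix, never by projecting onto a frozen map — coordinates
of a UMAP map are meaningful only for the cohort they were optimized on.

## Problem sizes in the test suite

The packaged checks run at desk scale: the full 238-sample default cohort
with 50 UMAP replicates per `n_neighbors` setting and a 20-seed-pair vote
for the neighborhood trend; 50 seeds of a 46-sample cohort for discordant
sample recovery; 10,000 permutations for the Moran null at $n = 50$; 200
shuffles at $G = 5000$ for the overlap null; and 50 random instances at
$n \le 30$ for the brute-force oracle equivalences. The replicate count (50)
is a deliberate reduction of the 1,000-replicate protocol used at full
scale; the mean ± sd summaries are unchanged in form.

## Known limitations

* The SD rank weight follows the verbal description of the metric; if a
  different weighting of the same family is wanted, only `sd_weight()` and
  its flag need extending.
* `scaled_sd()` is undefined wherever the two PCA anchors agree exactly;
  dense, strongly clustered toy data can trigger this at many $k$. The
  pipeline drops such levels loudly rather than imputing.
* Moran indices are computed on the variable-gene subset by default (the
  features that define the map); pass `gene_set = NULL` explicitly with a
  wider expression matrix to widen the universe.
* The centroid tests interpret the 2D map. They inherit the map's
  distortions by design — that is what is being validated.
* p-values from the subtype suite are reported raw, one test per configured
  contrast, matching the way such validation tests are usually read;
  multiple-testing correction is the caller's decision.
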