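---
title: "Spatial coherence analysis of chromatin states: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial coherence analysis of chromatin states: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`spatchrom` analyses spatially resolved histone-modification profiles of the
kind produced by spot-grid CUT&Tag assays: per-spot genome-wide fragment
files plus the physical coordinates of the spots on the tissue. The package
covers six analysis stages — gene-activity scoring, spot clustering,
spatially coherent gene detection with co-localization modules, module-to-
cluster enrichment, broad-domain segmentation, serial-slice integration, and
domain-width transitions along a spatial pseudo-distance — together with a
synthetic-data generator that plants a known truth for every stage. This
vignette explains the models, the tunable parameters, and the design
decisions; it states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

# From fragments to activity scores

A fragment record `(chrom, start, end, barcode, count)` uses 0-based
half-open coordinates and represents `count` identical transposition events.
Each fragment is counted as two Tn5 insertions, at `start` and at `end - 1`.
This insertion convention (rather than whole-fragment coverage) makes the
tile-matrix mass exactly `2 * sum(count)`, an invariant the tests exploit;
whether the original preprocessing counted fragments or insertions into
tiles is not documented anywhere we could rely on, so insertion counting is
adopted and flagged here.

The **gene score** of gene *g* in spot *s* is a distance-weighted insertion
count. The gene window is the transcript body extended 5 kb upstream of the
strand-aware TSS. Insertions inside the window weigh 1; outside, the weight
decays as `exp(-d / 5000)` with `d` the distance in bp to the window, and is
zero beyond 100 kb. This is a deliberately simple, pluggable stand-in for
the more elaborate tile-based exponential models used by chromatin toolkits:
downstream analyses consume the scores only as a genes-by-spots activity
matrix, so any monotone local weighting serves, and the simple form has a
closed-form value for every insertion that the tests verify directly.
Promoters are `TSS ± 2000` bp; the half-width is one argument of
`gene_model()`.

# Normalization, embedding, clustering

`lsi_embed()` applies TF-IDF (per-spot term frequencies times
`log1p(n_spots / n_spots_with_tile)`) to the 5 kb tile matrix, restricted to
the `var_features = 25000` most variable tiles, followed by a truncated SVD
computed from the spot-space Gram matrix. A single pass replaces iterated
re-embedding: the embedding's only downstream role here is to group spots
into pseudobulk clusters, and the decomposition is exact for whatever
rank structure the matrix has (the tests check lossless rank-2 recovery).
Component signs follow a largest-magnitude-loading-positive convention so
results are machine-reproducible.

`cluster_spots()` builds a k-nearest-neighbor graph in embedding space,
reweights edges by the Jaccard overlap of the two endpoint neighborhoods
(shared nearest neighbors, self included), prunes weights below 1/15, and
runs Louvain modularity optimization at `resolution = 1`. The neighborhood
size defaults to `k = 40` rather than the more common 20: modularity at
resolution 1 fragments a contiguous cluster whose kNN graph is sparse
relative to its size, whereas clique-like communities do not split; with
k = 40 a planted pair of well-separated 100-spot groups is recovered as
exactly two clusters. Labels are `0..K-1` ordered by cluster size. When a
known partition should be used instead (synthetic truth, an external
annotation), `as_cluster_assignment()` bypasses clustering entirely so that
domain and transition analyses do not inherit clustering stochasticity.

# Spatially coherent genes

The spatial substrate is a kNN network over physical spot coordinates
(`k = 10`, `max_dist = 40` µm, union-symmetrized). The distance filter is
strict (`<`): on a 20 µm grid the 40 µm bound then links interior spots to
their 8 immediate neighbors, not to the second rook ring at exactly 40 µm.

Each gene is binarized by rank: the top 30% of spots by score become 1,
with exactly `ceiling(0.3 n)` ones and ties broken by spot order. Rank
binarization is deterministic and scale-free; a constant gene cannot be
binarized and is flagged instead of tested. Every network edge is then
classified by its endpoint pattern, counting both orientations of each
undirected edge, into the 2x2 table `[[2*HH, M], [M, 2*LL]]` (`HH` both
ends high, `LL` both low, `M` mixed). A one-sided Fisher exact test for
enrichment of high-high edges yields the p-value; the sample odds ratio of
the table is reported alongside. The tests validate the p-value against an
independent hypergeometric enumeration over all labelings of all small
networks. Benjamini-Hochberg adjustment runs over all tested genes, and
ranking is by adjusted p with deterministic tie-breaking (raw p, then
descending odds ratio, then name).

Co-localization modules smooth each spatial gene's profile over the network
(mean over the closed neighborhood), correlate smoothed profiles (Pearson),
and cluster genes by Ward linkage (`ward.D2`) on `1 - r`, cut at
`k_modules = 8`. Smoothing-then-correlation is our concrete reading of a
"network-based" spatial correlation; it is stated here because other
readings exist. A module's **metagene** is the per-spot mean of its member
genes' z-scored activities.

# Module-to-cluster enrichment (PAGE)

For each cluster, per-gene log2 fold changes compare the mean score inside
the cluster against the rest (pseudocount 1e-9). The PAGE statistic of a
module of size *m* is `Z = (S_m - mu) * sqrt(m) / delta` with `mu`,
`delta` the mean and standard deviation of fold changes over all genes and
`S_m` the module mean. Scores are z-normalized across clusters within each
module (the axis is configurable), and the discretized map keeps cells with
`z >= 0.7` **and** raw `Z >= 0.7`. The raw-score guard exists because
row-wise z-normalization rescales every row to unit variance: a module
enriched nowhere would otherwise always map to whichever cluster tops its
noise. Raw PAGE is itself approximately standard normal under the null, so
the same cutoff is meaningful on both scales.

# Broad-domain segmentation

Pseudobulk tracks per cluster sum insertions into 100 bp bins and binarize
at `count >= 5` (the cutoff is inclusive; "cutoff n = 5" is read as >= 5).
A two-state Bernoulli hidden Markov model, fitted by Baum-Welch jointly
across tracks (forward-backward in compiled code; deterministic
data-independent initialization, states ordered so state 2 is "enriched"),
yields bin-level states by Viterbi decoding. Domain-level states aggregate
bins into 5-bin (500 bp) blocks — a block is enriched iff at least 3 of its
5 bins are — and runs of enriched blocks separated by at most one
background block merge into a single domain whose width includes the
bridged gap and whose height is the maximal raw signal inside. This
two-level procedure is a stand-in for hierarchical chromatin-state models:
the scientific quantity downstream is domain width at the 5 kb broad/narrow
cutoff, which the block aggregation preserves (planted widths of 2, 8 and
20 kb are recovered exactly on clean tracks and within 10% under Poisson
noise at 10 insertions per enriched bin, as the acceptance suite computes).
Both levels tile the track, so background widths are well-defined; a gene
whose promoter (TSS ± 2 kb) overlaps no enriched domain has width 0. Genes
take the widest overlapping domain, ties broken by midpoint proximity to
the TSS.

Gene-set comparisons (spatial vs active vs all genes) report medians and
two-sided rank-sum p-values. For small sets the p-value is computed by
exact enumeration of group assignments, because the asymptotic
approximation that `wilcox.test` falls back to under ties is unreliable at
those sizes; identical sets then give p = 1 up to discreteness.

# Serial-slice integration

`kabsch()` solves the paired least-squares rigid alignment via SVD of the
cross-covariance, constrained to a proper rotation unless reflections are
explicitly allowed (serial sections share chirality). `icp_align()`
alternates nearest-neighbor correspondence with Kabsch fits until the RMSD
stops improving. Plain ICP from a single identity start is unreliable on
regular spot grids: lattice coincidences create local minima with a basin
of attraction of only a few degrees. The default therefore screens a
5-degree grid of initial rotations on deterministically thinned clouds and
refines the best three starts; non-convergence is reported in attributes,
never as an exception. Note that a rotationally symmetric cloud makes the
angle unidentifiable up to that symmetry — real tissue outlines are
asymmetric, and the synthetic layouts deliberately are too.

`transfer_scores()` maps source spots through the fitted transform and
gives each target spot the inverse-distance-weighted mean of its at most
`k = 4` nearest transformed sources within one target grid pitch
(estimated as the median nearest-neighbor distance); a coincident source
dominates exactly, and targets with no in-radius source are excluded as
non-overlapping. Per-gene relationships between two marks are summarized by
Pearson correlation over matched spots with a loess curve for plotting, and
classified as complementary (r < -0.3), independent, or co-occurring
(r > 0.3).

# Spatial pseudo-distance and width transitions

`diffusion_map()` embeds spots from their gene-score profiles: a Gaussian
kernel with a single bandwidth set to the median distance to the 10th
neighbor, density normalization (alpha = 1), and the top non-trivial
eigenvectors of the normalized operator as DC1/DC2, with the same sign
convention as the LSI embedding. The **pseudo-distance** of a spot to a
tissue is the sum of its min-max-normalized physical distance and its
min-max-normalized diffusion-space distance to the tissue centroid
(normalization mode configurable; min-max keeps both terms in [0, 1] so
neither dominates by units). Spots are cut into 20 equal-width distance
bins ("equidistance" is read as equal bin width, not equal occupancy;
a quantile mode is provided), half-open with the maximum closed into the
last bin.

For a declared locus window, each group's pseudobulk is the per-spot mean
insertion count scaled to a common reference group size and binarized at
the same cutoff as the cluster tracks; the domain width is 100 bp times the
number of significant bins, and the transition trend is the Spearman rank
correlation of width against group index. The depth scaling is the key
normalization: without it, group-size differences masquerade as width
changes. Groups with fewer than `min_spots = 5` spots are recorded as
missing and excluded from the trend, an extension of the empty-group rule:
below that size the scaled cutoff degenerates until a single background
insertion can mark a bin significant.

# The synthetic generator

`make_tissue_layout()` builds a regular pitch-20 µm grid with disk-shaped
regions; `make_synthetic_genes()` lays genes on two synthetic chromosomes
at 60 kb spacing. Spatial genes carry a promoter-anchored activating domain
whose width shrinks linearly with distance *d* from their region's center,
`w(d) = w_max * max(0, 1 - d/d0)` with `w_max = 20` kb, and a complementary
repressive domain growing as `10 kb * min(1, d/d0)`; housekeeping genes
carry a fixed 1.5 kb activating peak everywhere. Fragment counts are
Poisson (2 fragments per kb of domain per spot; 2 per housekeeping peak;
background 0.3 per 50 kb locus neighborhood), with a global `depth`
multiplier and an optional linear-vs-sigmoid width profile left to the
caller. Two geometry choices matter and were fixed once: `d0 = 1.5`
region radii by default, so a gene's activity vanishes before the nearest
neighboring region center (at 2 radii, neighboring tissues inherit real
secondary enrichment and the planted module-to-region map is no longer the
unique no-false-positive answer); and 60 kb gene spacing, so the
exponential tail of neighboring loci gives every spot a continuous score —
real gene scores are continuous, and heavily tied scores would make rank
binarization's deterministic tie-breaking spatially structured on a
row-major grid. The transition preset instead sets `d0` so the planted
activating width spans 20 kb at the tissue center to about 2 kb at the far
edge of the slide.

`make_second_slice()` rotates the grid about its centroid, translates,
jitters, and thins it, returning the exact planted transform for oracle
comparisons. Everything is reproducible bit-for-bit from (parameters,
seed); `planted_truth()` exports the planted widths, gene-region map and
spatial-gene identities.

What the generator does *not* emulate: real genome sequence and mappability
structure, fragment-length distributions, overdispersed (negative-binomial)
counts, doublets or segmentation errors in spot calling, irregular tissue
morphology beyond unions of disks, and any transcriptional readout. Tests
passing on this generator therefore demonstrate correctness of the
algorithms under the stated statistical model, not performance on real
tissue.

# Problem sizes and determinism

The test and acceptance workloads use a 45 x 45-spot benchmark (2025
spots, 300 genes, 30 planted spatial genes in four ~14%-of-slide regions),
a 32 x 32 "embryo-mini" preset with 8 regions and 3 spatial genes each,
and a 40 x 40 single-tissue transition preset — sizes chosen so every
planted effect is overwhelmingly detectable while the whole suite runs in
minutes on one core. All stochastic steps take explicit seeds; eigenvector
signs and tie-breaks are fixed by convention; the HMM initialization is
data-independent. Two runs with the same inputs and seeds are identical.

# Known limitations

- The Fisher statistic treats network edges as independent draws with
  fixed margins; edges sharing a node are not independent, so the p-value
  is a well-calibrated *ranking* statistic rather than an exact
  node-permutation p-value (the permutation property is tested separately).
- The two-level domain decoder snaps boundaries to 500 bp blocks; widths
  of domains not aligned to block boundaries carry up to one block of
  quantization error.
- ICP assumes partial overlap and similar point densities; with disjoint
  clouds it converges to a flagged high-RMSD solution rather than failing.
- The pseudo-distance mixes physical and chromatin distance with equal
  weight after min-max normalization; no claim is made that this is the
  optimal mixture, only that it is the documented, configurable default.
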