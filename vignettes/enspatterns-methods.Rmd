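---
title: "Models and methods behind enspatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind enspatterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`enspatterns` packages the transcriptomic workflow used to identify and
track mesoderm-derived enteric neurons (MENs) — a non-neural-crest
neuronal lineage of the gut wall — alongside the canonical
neural-crest-derived enteric neurons (NENs). The pipeline runs from raw
droplet count matrices to transferable gene-expression programs: droplet
QC, log normalization, batch-corrected clustering with marker
statistics, non-negative matrix factorization (NMF) of expression into
patterns, non-negative least-squares (NNLS) projection of external data
into those patterns with differential-usage tests, and continuous
cell-cycle position inference. Every stage is exercised against a
synthetic-data generator whose ground truth is known, so the package's
claims are tested properties, not anecdotes.

## The synthetic cohort model

The generator draws gene-by-cell UMI counts from a negative binomial
around a low-rank, non-negative expectation:

* **Programs.** A `genes x k_true` amplitude matrix `A_true` holds
  `k_true = 6` programs by default. Each program owns a block of marker
  genes with Gamma(25, 5) amplitudes on top of a Gamma(0.2, 10)
  baseline shared by all genes. The near-zero baseline and the moderate
  within-block amplitude variance are deliberate: log-scale
  normalization compresses dynamic range, and programs with heavy
  baselines or very skewed marker amplitudes stop being identifiable
  from log-normalized data even in principle. The generator therefore
  plants programs that a log-scale factorization *can* recover, which
  is what the recovery tests measure.
* **Cell types.** Six types, one per program (mixture weight 0.85 on
  the own program, the rest spread evenly), spanning four lineages: two
  MEN-like, two NEN-like, one glia-like, one other. Mixture vectors are
  exact per type, so `p_true` columns are the configured mixtures.
* **Counts.** Per-cell library sizes are log-normal
  (`meanlog = log(2000)`, `sdlog = 0.35`); the expected profile is
  normalized to sum to one and scaled by the library size; counts are
  NB with dispersion `phi = 10` (variance `mu + mu^2/phi`). One knob,
  the standard overdispersion form.
* **Mitochondria.** The last 37 genes are flagged mitochondrial (the
  size of the murine mitochondrial annotation). Each cell's
  mitochondrial fraction is Beta(2, 18) (mean 10%); a 5% "damaged"
  subpopulation draws from Beta(8, 12) so the 20% QC filter has
  something to remove.
* **Batch and age structure.** Gene-wise log-scale multiplicative batch
  shifts (SD 0.15) are applied per batch; samples cycle through two
  batches. Each sample carries an age, and a cell is MEN-like with
  probability `composition_curve(age)`.
* **Seeds.** One master seed; every stochastic operation derives a
  child stream keyed by its name, so stages can be re-run in isolation
  without perturbing each other.

### The composition curve

The measured MEN proportions at postnatal days 11, 22, 60, 180 and 510
are 4.12%, 29.63%, 46.38%, 57.29% and 95.99%. A four-parameter logistic
in log-age was the first candidate for interpolating them, but its best
fit misses the series badly (worst residual ~0.12): the late-life rise
between P180 and P510 is far steeper than the juvenile rise, which no
single logistic can accommodate. `composition_curve()` therefore uses a
monotone Hermite spline in log-age through the five measured points,
clamped to [0, 1] with constant extrapolation. It reproduces the
measurements exactly and stays monotone, which is all the downstream
age-trend machinery needs.

### What the generator does not emulate

Ambient RNA contamination inside cells, doublets, UMI collisions,
spliced/unspliced channels, gene-length effects and cell-type-specific
dispersion are all absent. Passing tests therefore demonstrate the
*statistical machinery* — identifiability of programs, calibration of
tests, correctness of estimators — not robustness to every artifact of
real droplet data.

## QC and normalization

Cells pass QC iff `total_umi >= min_umi` **and** `mito_ratio <
max_mito`. The minimum is inclusive (it is a "minimum threshold") and
the mitochondrial bound strict ("less than 20%"); a cell at exactly
0.20 fails. Presets: `min_umi = 200` for the adult (P180) cohort and
`600` for the P21 cohort, both with `max_mito = 0.20`. An all-zero
barcode gets `mito_ratio = 0` plus a degenerate flag; it can never pass
the UMI filter anyway.

Size factors are library size over the geometric mean, so `log(sf)`
averages to zero; the convention is documented and swappable because
replication against deposited data may prefer pooled deconvolution
factors, which this package deliberately does not implement.
Normalization is `log_base(count/sf + 1)` with base 10 the default for
single-cell matrices and base 2 the convention for single-nucleus
data; zeros map to exact zeros so sparsity survives.

### Barcode-rank landmarks

The knee/inflection estimator is an operational definition (the
landmarks are named in the field, the estimator rarely is): totals are
sorted descending, ties collapsed to unique (rank, total) points at
their mean rank, a smoothing spline fitted to log10(total) vs
log10(rank), and the inflection taken as the minimum first derivative
to the right of the upper plateau (points within 5% of the top of the
curve's range), the knee as the minimum signed curvature left of the
inflection. A near-constant slope (first-derivative range < 0.25)
flags a low-confidence, single-population curve. Filtering keeps
barcodes with totals strictly above the inflection total.

## Embedding, batch correction, clustering

PCA runs on the top 2,000 most variable normalized genes by default
(configurable to all genes; the embedding needs features even though
downstream marker statistics use every non-zero gene), with `d = 50`
components for a full dataset and `d = 20` for the MEN-subset
re-embedding. Mutual-nearest-neighbor (MNN) batch correction merges
batches sequentially: mutual k-NN pairs across the batch boundary
define correction vectors — one per paired incoming cell, to its
nearest mutual partner, so coinciding batches yield exactly zero
correction — and each incoming cell moves by a Gaussian-kernel-weighted
average of those vectors (bandwidth = median pair distance,
`k_mnn = 20`). Like every mutual-neighbor scheme it assumes the batch
displacement is small against the separation between cell populations;
the tests exercise exactly that regime.

Clustering builds a shared-nearest-neighbor graph (edge iff two cells
share a neighbor among their k-NN lists, weight = Jaccard of the two
neighbor sets) and runs Leiden (constant Potts objective) or Louvain
(modularity) through igraph, both deterministic under the exposed seed.
The MEN-subset preset is `knn_k = 10`, `resolution = 5e-4`.

Marker detection uses an all-pairs scheme: per gene and cluster, one-sided Welch t-tests against every
other cluster; Simes combination across the pairwise set ("upregulated
compared to any other", with max-combination available for "compared to
all others"); Benjamini–Hochberg across genes within a cluster; the
summary log fold change taken from the pairwise comparison with the
smallest p; the top 30 genes flagged. Zero-variance comparisons get
p = 1 by convention, so constant genes can never become markers. The
pseudo-R² ranking score is McFadden's measure from a one-vs-rest
logistic regression with a small (1e-4) ridge on the slope — the ridge
keeps perfectly separating genes finite while leaving the score within
1e-4 of the unpenalized optimum elsewhere.

Cluster annotation scores each signature's mean z-scored expression per
cluster and assigns the best label only when it leads the runner-up by
0.25 z-units; the bundled signatures are *Ret* for NENs,
*Sox10*/*Ncam1* for neuroglia and *Calcb*/*Met*/*Cdh3* co-expression
for MENs.

## NMF pattern discovery

`nmf_fit()` minimizes `0.5 * ||V - AP||_F^2` under non-negativity by
hierarchical alternating least squares (HALS): each column of `A` and
row of `P` has a closed-form non-negative update, which makes the
objective provably non-increasing per sweep (asserted on the stored
trace). Random uniform initialization, three restarts keeping the best
objective (NMF is non-convex and restarts are the cheapest insurance),
`tol = 1e-6` relative change, `k = 50` for the reference analysis.
After fitting, columns of `A` are rescaled to unit L2 norm with the
scale absorbed into `P` — no convention is standard, so the package
fixes one.

Pattern specificity is the AUROC of a pattern's cell-weight row as a
classifier of cluster membership; selecting lineage-specific patterns from a
heatmap by eye is common practice, and the AUROC rule is its
reproducible analog (`m = 4` patterns, floor 0.9, both configurable).
Specificity is computed against fine clusters and the best cluster then
translated to its annotation label, because each MEN program marks one
MEN subcluster rather than the merged lineage. With surplus components
(`k > k_true`) the true programs are still recovered; on noiseless data
the extras carry near-zero weight or duplicate a recovered pattern,
while on overdispersed counts they absorb sampling noise — a known,
benign behavior of overcomplete NMF worth remembering when choosing k.

## Projection and differential usage

Projection solves, per target column, `argmin_{p >= 0} ||y - A p||^2`
with a Lawson–Hanson active-set NNLS (tested against exhaustive
support enumeration); ordinary least squares is available for parity
checks since projection tools differ in whether they constrain signs. The
non-negative default respects the cone geometry of NMF and is
positively scale-equivariant. Feature matching is case-insensitive
exact symbol matching, optionally through a strictly 1:1 ortholog map
(ambiguous rows dropped — determinism beats coverage); it errors when
fewer than half the reference genes match.

Per-cell weights are averaged to per-sample means before any group
test: samples, not cells, are the experimental unit, and cell-level
testing would pseudoreplicate. Two groups get an equal-variance Student
t-test (Welch switchable), three or more a one-way ANOVA with (DFn,
DFd) reported; BH q-values across patterns are emitted alongside raw
p-values. Human atlas samples map to Juvenile (4–12 y), Adult (20–50 y)
and Aged (60–75 y) inclusive age groups; out-of-range ages are
"unassigned" rather than silently nearest-matched.

## Cell-cycle position

The 2-D cell-cycle reference is the first two PCs of the centered
cell-cycle-gene submatrix (500 genes by default); theta is the angle
`atan2(e2, e1) mod 2pi` of a cell's projection, and cells with theta in
the half-open arc `[0.5pi, 1.5pi)` are called cycling — the boundary
value goes to "cycling" since interval notation alone does not
decide it. A PCA plane has two gauge freedoms, rotation and
handedness, that no data can fix; `align_theta()` estimates them
against any reference angles (circular mean of differences, reflection
if it improves the circular correlation), and evaluation against
planted truth is always done after alignment. The package builds its
reference from user-supplied data rather than shipping a pretrained
species reference.

Periodic smoothing is local-linear regression with tricube weights on
the wrapped angular distance and a span-sized window — a loess that
respects the topology of the circle, without iterative robustness
steps. Circular association is the Fisher–Lee correlation, computed via
its O(n) expansion and tested against the O(n²) pairwise definition.

## Problem sizes and numerical choices

The bundled property checks run on desk-scale cohorts chosen to keep
the whole suite in the low minutes while leaving clear margins: 2,000
cells x 500 genes for pattern recovery (five seeds), 200 random
problems for the NNLS oracle, 200 replicates for the null calibration
of the age-trend ANOVA (11 samples in a 5/3/3 grouping, matching the
reference design's degrees of freedom (2, 8)), 100 simulations of the
n = 3/group bulk design, and a 600-cell planted-theta cohort with 500
cell-cycle genes. Degenerate inputs are handled explicitly rather than
by accident: zero-variance Welch comparisons give p = 1, all-zero
barcodes are flagged, constant barcode-rank curves raise a typed error,
single-population rank curves are flagged low-confidence, HALS columns
with zero norm are zeroed, and rank-deficient OLS projection falls back
to the minimum-norm solution with a warning.

## Known limitations

Library-size factors stand in for pooled deconvolution factors; no
ambient-RNA or doublet modeling; UMAP visualization is out of scope;
the MNN estimator is single-pass and, like its relatives, cannot
separate a batch shift from biology when the two are comparable in
magnitude; NMF restarts mitigate but do not eliminate local optima;
and the exact cluster count obtained on real data depends on tuning
(resolution, HVG policy) that reasonable analysts set differently.
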