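# enspatterns

Pattern discovery and transfer projection for enteric nervous system
single-cell transcriptomics.

The enteric nervous system contains, besides the canonical
neural-crest-derived enteric neurons (NENs, marked by *Ret*), a second
neuronal lineage of mesodermal origin (MENs, marked by co-expression of
*Calcb*, *Met* and *Cdh3*) whose share of the myenteric ganglia grows
from a few percent in juveniles to nearly all neurons in aged gut.
`enspatterns` implements the computational workflow that identifies this
lineage from droplet scRNA-seq and tracks its transcriptomic signature
across datasets, species and modalities:

* **Droplet QC** — barcode-rank knee/inflection statistics, UMI and
  mitochondrial-ratio filters (presets: 200 or 600 UMI minimum,
  mito < 20%), library-size factors, log10/log2(x/sf + 1) normalization.
* **Clustering** — PCA, mutual-nearest-neighbor batch correction,
  shared-nearest-neighbor graph with Leiden/Louvain communities,
  pairwise one-sided Welch marker tests with Simes combination and BH
  correction, ridge-logistic pseudo-R² marker scores, signature-based
  annotation.
* **Pattern discovery** — non-negative matrix factorization
  `V ≈ A·P` by HALS (default k = 50), AUROC-based selection of the
  patterns most specific to a target lineage (default: the four most
  MEN-specific).
* **Transfer projection** — non-negative least squares of new
  single-cell, single-nucleus or bulk profiles onto fixed amplitudes
  `A`, per-sample aggregation, and Student-t / one-way-ANOVA tests of
  differential pattern usage (e.g. Juvenile/Adult/Aged human age
  groups, or disease vs control bulk cohorts).
* **Cell-cycle position** — continuous theta = atan2(e2, e1) in a 2-D
  cell-cycle PC space built from 500 cell-cycle genes, cycling calls on
  the [0.5π, 1.5π) arc, periodic loess expression dynamics.
* **Synthetic cohorts** — a generator with known ground truth (gene
  programs, lineages, batches, an age-structured MEN-like composition
  following the measured proportions, empty droplets, bulk mixtures,
  planted circular cell-cycle structure) that makes every claim above
  testable offline.

## Worked example

```r
library(enspatterns)

cfg <- sim_config(seed = 42, cells_per_sample = 200)
ref <- simulate_reference_cohort(cfg)
ref$counts
#> <sc_counts> 500 genes x 1000 cells (59.07% non-zero)

qc   <- filter_cells(ref$counts, min_umi = 200, max_mito = 0.20)
sum(qc$mask)
#> [1] 848                      # cells passing QC
norm <- normalize_counts(qc$filtered, log_base = 10)

fit <- nmf_fit(norm, k = 6, seed = 1, n_restarts = 2)
fit
#> <pattern_model> k = 6 over 500 genes x 848 cells; objective 8810 after 92 sweeps

spec <- pattern_specificity(fit, qc$filtered$cells$type)
lin  <- setNames(cfg$cell_types$lineage, cfg$cell_types$label)
spec$cluster <- unname(lin[spec$cluster])
select_specific_patterns(spec, "MEN-like", m = 4)
#> [1] "p1" "p2"                # the two planted MEN programs, AUROC = 1
```

The two selected patterns are exactly the generator's MEN-like
programs; the warning that only two patterns clear the 0.9 AUROC floor
is expected, since this cohort plants two. Projecting a degraded
target (half the sequencing depth, 70% of the genes) still lands each
cell on its generating program:

```r
tgt   <- simulate_target_dataset(ref, depth_fraction = 0.5,
                                 gene_subset_fraction = 0.7, seed = 9)
tnorm <- normalize_counts(tgt$counts)
rownames(tnorm) <- tgt$counts$genes$gene_symbol
A <- fit$A; rownames(A) <- ref$counts$genes$gene_symbol
mf   <- match_features(rownames(A), rownames(tnorm))
proj <- project_patterns(tnorm[mf$target_index, ], A[mf$ref_index, ])
proj
#> <projection_result> 1000 cells onto 6 patterns (350 matched genes); median R2 0.776
```

`tidy()` and `glance()` methods turn fitted objects into tibbles;
`plot_barcode_ranks()`, `plot_pattern_weights()` and
`plot_cc_dynamics()` give the standard diagnostics as ggplots.
`run_pipeline(pipeline_config(preset = "p180"))` chains the stages end
to end and emits a JSON run report.

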