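#' Simulation configuration for lineage-structured single-cell cohorts
#'
#' Builds the configuration object consumed by the cohort simulators. The
#' defaults describe a small myenteric-plexus-like cohort: six non-negative
#' gene programs generating six cell types across four lineages (two
#' MEN-like types, two NEN-like types, one glia-like, one other), with
#' negative-binomial counts, log-normal library sizes, Beta-distributed
#' mitochondrial content, gene-wise multiplicative batch effects and an
#' age-structured sample series whose MEN-like composition follows
#' [composition_curve()].
#'
#' @param n_genes Number of genes (mitochondrial genes included).
#' @param n_true_patterns Number of generating programs `k_true`.
#' @param cell_types A tibble with columns `label`, `lineage` (one of
#'   "MEN-like", "NEN-like", "glia-like", "other") and a list-column
#'   `mixture` of non-negative vectors of length `n_true_patterns`, each
#'   summing to 1. Defaults to one type per program.
#' @param cells_per_sample Cells sequenced per sample.
#' @param library_size Named list `meanlog`, `sdlog` of the log-normal UMI
#'   total per cell. Default meanlog `log(2000)`, sdlog 0.35.
#' @param nb_dispersion Negative-binomial size parameter `phi`
#'   (variance = mu + mu^2/phi). Default 10.
#' @param mito_gene_count Number of genes flagged mitochondrial (default 37,
#'   the murine mitochondrial annotation size).
#' @param mito_fraction Named list `a`, `b` of the Beta distribution of the
#'   per-cell mitochondrial fraction (default Beta(2, 18), mean 10%).
#' @param damaged_fraction Fraction of cells drawn from the high-mito
#'   "damaged" Beta(8, 12) subpopulation (default 0.05), exercising the 20%
#'   mitochondrial filter.
#' @param batch_effect_sd SD of gene-wise log-scale multiplicative batch
#'   shifts (default 0.15); batches alternate across samples.
#' @param n_batches Number of batches samples are cycled through (default 2).
#' @param age_points Tibble with columns `sample`, `age_days`. Defaults to
#'   the five-age murine series P11/P22/P60/P180/P510.
#' @param composition Parameters of the MEN-like composition curve; see
#'   [composition_curve()]. Default `NULL` uses the calibrated curve.
#' @param n_empty_droplets Empty droplets for [simulate_droplet_pool()].
#' @param ambient_scale Mean UMI total of an empty droplet (default 20).
#' @param seed Master seed; each simulator derives an operation-keyed
#'   child stream from it.
#'
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(n_genes = 500,
                       n_true_patterns = 6,
                       cell_types = NULL,
                       cells_per_sample = 200,
                       library_size = list(meanlog = log(2000), sdlog = 0.35),
                       nb_dispersion = 10,
                       mito_gene_count = 37,
                       mito_fraction = list(a = 2, b = 18),
                       damaged_fraction = 0.05,
                       batch_effect_sd = 0.15,
                       n_batches = 2,
                       age_points = NULL,
                       composition = NULL,
                       n_empty_droplets = 5000,
                       ambient_scale = 20,
                       seed = 1L) {
  if (n_genes < 1 || n_true_patterns < 1) {
    abort("n_genes and n_true_patterns must be positive", class = "config_error")
  }
  if (!is.finite(library_size$meanlog) || !is.finite(library_size$sdlog)) {
    abort("library-size parameters must be finite", class = "config_error")
  }
  if (nb_dispersion <= 0) abort("nb_dispersion must be > 0", class = "config_error")
  if (n_empty_droplets < 0) abort("n_empty_droplets must be >= 0", class = "config_error")
  if (mito_gene_count >= n_genes) {
    abort("mito_gene_count must be < n_genes", class = "config_error")
  }
  if (is.null(cell_types)) cell_types <- default_cell_types(n_true_patterns)
  for (m in cell_types$mixture) {
    if (length(m) != n_true_patterns || any(m < 0) ||
        abs(sum(m) - 1) > 1e-12) {
      abort("each pattern mixture must be non-negative, of length k_true, and sum to 1",
            class = "config_error")
    }
  }
  if (is.null(age_points)) {
    age_points <- tibble::tibble(
      sample = paste0("S", 1:5),
      age_days = c(11, 22, 60, 180, 510)
    )
  }
  structure(list(
    n_genes = n_genes, n_true_patterns = n_true_patterns,
    cell_types = cell_types, cells_per_sample = cells_per_sample,
    library_size = library_size, nb_dispersion = nb_dispersion,
    mito_gene_count = mito_gene_count, mito_fraction = mito_fraction,
    damaged_fraction = damaged_fraction,
    batch_effect_sd = batch_effect_sd, n_batches = n_batches,
    age_points = age_points, composition = composition,
    n_empty_droplets = n_empty_droplets, ambient_scale = ambient_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Default six-type catalogue: each type dominated by its own program
# (weight 0.85, remainder spread evenly), two MEN-like programs first.
default_cell_types <- function(k) {
  lineages <- rep("other", k)
  if (k >= 1) lineages[1] <- "MEN-like"
  if (k >= 2) lineages[2] <- "MEN-like"
  if (k >= 3) lineages[3] <- "NEN-like"
  if (k >= 4) lineages[4] <- "NEN-like"
  if (k >= 5) lineages[5] <- "glia-like"
  mix <- lapply(seq_len(k), function(j) {
    m <- rep(if (k > 1) 0.15 / (k - 1) else 0, k)
    m[j] <- if (k > 1) 0.85 else 1
    m / sum(m)
  })
  tibble::tibble(
    label = paste0("type", seq_len(k)),
    lineage = lineages,
    mixture = mix
  )
}

#' MEN-like composition as a function of age
#'
#' A monotone curve through the measured proportions of mesoderm-derived
#' enteric neurons at postnatal days 11, 22, 60, 180 and 510 (4.12%,
#' 29.63%, 46.38%, 57.29% and 95.99% of myenteric neurons). The curve is a
#' monotone Hermite spline in log(age), clamped to \[0, 1\] with constant
#' extrapolation outside the measured age range; a smooth parametric
#' logistic in log-age cannot pass through this series (the late-life rise
#' is much steeper than the juvenile one), so the interpolant is used as
#' the calibrated composition target.
#'
#' @param age_days Age(s) in days, positive.
#' @param anchors Optional tibble with columns `age_days`, `fraction` to
#'   recalibrate the curve.
#' @return MEN-like fraction(s) in \[0, 1\].
#' @export
composition_curve <- function(age_days, anchors = NULL) {
  if (any(age_days <= 0)) abort("age_days must be positive", class = "config_error")
  if (is.null(anchors)) {
    anchors <- tibble::tibble(
      age_days = c(11, 22, 60, 180, 510),
      fraction = c(0.0412, 0.2963, 0.4638, 0.5729, 0.9599)
    )
  }
  f <- splinefun(log(anchors$age_days), anchors$fraction, method = "monoH.FC")
  x <- pmin(pmax(log(age_days), log(min(anchors$age_days))),
            log(max(anchors$age_days)))
  pmin(pmax(f(x), 0), 1)
}
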