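# The study-scale fixture used by the acceptance properties: a 2,000-cell
# reference cohort (500 genes, six generating programs of which two are
# MEN-like, NB dispersion 10) plus one NMF fit and the MEN-pattern
# selection derived from it. Built lazily and cached for the test run.
study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 1, cells_per_sample = 400)
      ref <- simulate_reference_cohort(cfg)
      qc <- filter_cells(ref$counts, 200, 0.2)
      norm <- normalize_counts(qc$filtered)
      fit <- nmf_fit(norm, k = 6, seed = 1, n_restarts = 1)
      spec <- pattern_specificity(fit, qc$filtered$cells$type)
      lin <- setNames(cfg$cell_types$lineage, cfg$cell_types$label)
      spec$cluster <- unname(lin[spec$cluster])
      sel <- select_specific_patterns(spec, "MEN-like", m = 4)
      mm <- match_patterns(fit$A, ref$truth$A_true)
      cache <<- list(cfg = cfg, ref = ref, qc = qc, norm = norm,
                     fit = fit, spec = spec, selected = sel, matched = mm)
    }
    cache
  }
})

# Eleven-sample age series spanning the juvenile, adult and aged stages,
# with the grouping used for trend testing (5/3/3 samples).
age_series <- function() {
  tibble::tibble(
    sample = paste0("S", 1:11),
    age_days = c(11, 14, 18, 22, 26, 120, 150, 180, 450, 480, 510),
    group = rep(c("Juvenile", "Adult", "Aged"), c(5, 3, 3))
  )
}

# Mean MEN-pattern weight per sample after projecting a cohort onto the
# selected amplitude columns.
men_weight_by_sample <- function(norm, cells, A_sel) {
  proj <- project_patterns(norm, A_sel)
  tibble::tibble(sample = cells$sample, w = colMeans(proj$weights)) |>
    dplyr::group_by(sample) |>
    dplyr::summarise(mean_weight = mean(w), .groups = "drop")
}
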