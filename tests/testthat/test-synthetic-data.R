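test_that("composition curve reproduces the measured MEN proportions", {
  got <- composition_curve(c(11, 22, 60, 180, 510))
  expect_equal(got, c(0.0412, 0.2963, 0.4638, 0.5729, 0.9599), tolerance = 1e-12)
  # monotone and clamped
  ages <- exp(seq(log(5), log(900), length.out = 50))
  f <- composition_curve(ages)
  expect_true(all(diff(f) >= -1e-12))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(composition_curve(-1), class = "config_error")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(nb_dispersion = 0), class = "config_error")
  expect_error(sim_config(n_genes = 0), class = "config_error")
  expect_error(sim_config(n_empty_droplets = -1), class = "config_error")
  bad_types <- default_types <- sim_config()$cell_types
  bad_types$mixture[[1]] <- c(0.5, 0.4, 0, 0, 0, 0)   # sums to 0.9
  expect_error(sim_config(cell_types = bad_types), class = "config_error")
})

test_that("reference cohort is deterministic and structurally valid", {
  cfg <- small_config(seed = 11)
  a <- simulate_reference_cohort(cfg)
  b <- simulate_reference_cohort(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$counts$cells, b$counts$cells)
  m <- a$counts$counts
  expect_true(all(m@x >= 0))
  expect_true(all(m@x == round(m@x)))
  expect_equal(nrow(a$counts$cells), ncol(m))
  expect_equal(nrow(a$counts$genes), nrow(m))
  expect_equal(sum(a$counts$genes$is_mito), 37)
  expect_true(all(a$truth$A_true >= 0))
  # p_true columns are exactly the configured mixtures
  mixes <- do.call(cbind, cfg$cell_types$mixture)
  type_idx <- match(a$counts$cells$type, cfg$cell_types$label)
  expect_equal(a$truth$p_true, mixes[, type_idx], ignore_attr = TRUE)
})

test_that("per-cell totals track the configured library-size distribution", {
  cfg <- sim_config(seed = 3, cells_per_sample = 1000,
                    age_points = tibble::tibble(sample = "S1", age_days = 60),
                    batch_effect_sd = 0)
  sim <- simulate_reference_cohort(cfg)
  tot <- Matrix::colSums(sim$counts$counts)
  target <- exp(cfg$library_size$meanlog + cfg$library_size$sdlog^2 / 2)
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - target), 3 * se)
})

test_that("realized MEN fractions converge to the composition curve", {
  cfg <- sim_config(seed = 5, cells_per_sample = 5000,
                    age_points = tibble::tibble(sample = "S1", age_days = 180),
                    batch_effect_sd = 0)
  sim <- simulate_reference_cohort(cfg)
  p <- composition_curve(180)
  got <- sim$truth$men_fraction_by_sample$men_fraction
  expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / 5000))
})

test_that("target thinning behaves as binomial downsampling", {
  ref <- ref_cohort()
  ident <- simulate_target_dataset(ref, depth_fraction = 1,
                                   gene_subset_fraction = 1)
  expect_identical(as.matrix(ident$counts$counts), as.matrix(ref$counts$counts))
  half <- simulate_target_dataset(ref, depth_fraction = 0.5, seed = 99)
  t_ref <- Matrix::colSums(ref$counts$counts)
  t_half <- Matrix::colSums(half$counts$counts)
  # 99% two-sided binomial bounds per cell
  lo <- qbinom(0.005, size = t_ref, prob = 0.5)
  hi <- qbinom(0.995, size = t_ref, prob = 0.5)
  expect_gt(mean(t_half >= lo & t_half <= hi), 0.97)
  expect_error(simulate_target_dataset(ref, depth_fraction = 0),
               class = "config_error")
  expect_error(simulate_target_dataset(ref, depth_fraction = 1.2),
               class = "config_error")
})

test_that("renamed target genes are recovered by case-insensitive matching", {
  ref <- ref_cohort()
  map <- tibble::tibble(from = ref$counts$genes$gene_symbol,
                        to = toupper(ref$counts$genes$gene_symbol))
  tgt <- simulate_target_dataset(ref, depth_fraction = 1,
                                 gene_subset_fraction = 0.8,
                                 rename_map = map, seed = 4)
  mf <- match_features(tgt$counts$genes$gene_symbol,
                       ref$counts$genes$gene_symbol)
  expect_equal(nrow(mf), nrow(tgt$counts$genes))
})

test_that("bulk cohort mixes type profiles with the planted shift", {
  ref <- ref_cohort()
  null_bulk <- simulate_bulk_cohort(ref, men_shift = 0, noise_sd = 0)
  g1 <- colMeans(null_bulk$expr[null_bulk$samples$group == "control", ])
  g2 <- colMeans(null_bulk$expr[null_bulk$samples$group == "disease", ])
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(sum(null_bulk$samples$group == "control"), 3)

  shift <- simulate_bulk_cohort(ref, men_shift = 0.3, noise_sd = 0)
  lin1 <- 2^shift$expr[1, ] - 1
  lin2 <- 2^shift$expr[4, ] - 1
  # closed-form mixture algebra on the linear scale
  types <- ref$truth$config$cell_types
  profiles <- vapply(types$mixture, function(mx) {
    v <- as.numeric(ref$truth$A_true %*% mx); v / sum(v)
  }, numeric(nrow(ref$truth$A_true)))
  f0 <- shift$truth$fractions_control
  f1 <- shift$truth$fractions_disease
  expected_diff <- 1e4 * as.numeric(profiles %*% (f1 - f0))
  expect_equal(as.numeric(lin2 - lin1), expected_diff, tolerance = 1e-6)
  expect_error(simulate_bulk_cohort(ref, men_shift = 0.9),
               class = "config_error")
})

test_that("cell-cycle cohort plants recoverable angular structure", {
  cfg <- small_config(seed = 21)
  cc <- simulate_cellcycle_cohort(cfg, n_cc_genes = 100)
  expect_true(all(cc$truth$theta_true >= 0 & cc$truth$theta_true < 2 * pi,
                  na.rm = TRUE))
  expect_equal(length(cc$truth$cc_genes), 100)
  expect_error(simulate_cellcycle_cohort(cfg, n_cc_genes = 3),
               class = "config_error")
  # zero amplitude carries no angular signal: estimates at chance
  null_cc <- simulate_cellcycle_cohort(
    sim_config(seed = 22, cells_per_sample = 40,
               age_points = tibble::tibble(sample = "S1", age_days = 60)),
    n_cc_genes = 100, cc_amplitude = 0)
  nn <- normalize_counts(null_cc$counts)
  ref <- build_cc_reference(nn, null_cc$truth$cc_genes)
  pos <- cc_position(nn, ref)
  al <- align_theta(pos$theta, null_cc$truth$theta_true)
  expect_lt(abs(circular_cor(al$theta, null_cc$truth$theta_true)), 0.3)
})

test_that("droplet pool separates cells from ambient droplets", {
  cfg <- sim_config(seed = 2, cells_per_sample = 20, n_empty_droplets = 500,
                    ambient_scale = 0)
  pool <- simulate_droplet_pool(cfg)
  tot <- Matrix::colSums(pool$counts$counts)
  expect_true(all(tot[!pool$counts$cells$is_cell] == 0))
  pool2 <- simulate_droplet_pool(cfg)
  expect_identical(as.matrix(pool$counts$counts), as.matrix(pool2$counts$counts))
})
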