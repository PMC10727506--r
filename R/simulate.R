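#' @title Single-cell count container
#' @description A light container for a gene-by-cell UMI count matrix with
#'   aligned gene and cell metadata. `counts` is a sparse `dgCMatrix`
#'   (genes in rows), `genes` a tibble with `gene_id`, `gene_symbol`,
#'   `is_mito`, and `cells` a tibble with `barcode` plus any per-cell
#'   annotation (sample, batch, age, lineage, ...).
#' @param counts Matrix or sparse Matrix, genes x cells.
#' @param genes,cells Metadata tibbles; generated if omitted.
#' @return An `sc_counts` object.
#' @export
sc_counts <- function(counts, genes = NULL, cells = NULL) {
  counts <- to_sparse(counts)
  if (is.null(genes)) {
    genes <- tibble::tibble(
      gene_id = rownames(counts) %||% paste0("g", seq_len(nrow(counts))),
      gene_symbol = rownames(counts) %||% paste0("g", seq_len(nrow(counts))),
      is_mito = FALSE
    )
  }
  if (is.null(cells)) {
    cells <- tibble::tibble(
      barcode = colnames(counts) %||% paste0("bc", seq_len(ncol(counts)))
    )
  }
  if (nrow(genes) != nrow(counts) || nrow(cells) != ncol(counts)) {
    abort(sprintf(
      "metadata does not align with matrix: %d x %d matrix vs %d gene rows, %d cell rows",
      nrow(counts), ncol(counts), nrow(genes), nrow(cells)
    ), class = "format_error")
  }
  rownames(counts) <- genes$gene_id
  colnames(counts) <- cells$barcode
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "sc_counts")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("<sc_counts> %d genes x %d cells (%.2f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

# ---- internal generator pieces -------------------------------------------

# Marker-structured non-negative amplitude matrix: every gene carries a
# small baseline in all programs, and gene blocks are boosted in one
# program each so programs are identifiable.
make_A_true <- function(n_genes, k, mito_idx, cell_types) {
  # programs are marker-block structured: a near-zero baseline everywhere
  # plus a moderate-variance amplitude on the program's own gene block, so
  # the programs remain identifiable after log-scale normalization
  A <- matrix(rgamma(n_genes * k, shape = 0.2, rate = 10), n_genes, k)
  free <- setdiff(seq_len(n_genes), mito_idx)
  blocks <- split(free, rep(seq_len(k), length.out = length(free)))
  for (j in seq_len(k)) {
    A[blocks[[j]], j] <- A[blocks[[j]], j] + rgamma(length(blocks[[j]]), shape = 25, rate = 5)
  }
  # lineage marker genes used by the default annotation signatures
  sym <- rep(NA_character_, n_genes)
  sig <- list("MEN-like" = c("Calcb", "Met", "Cdh3"),
              "NEN-like" = c("Ret"),
              "glia-like" = c("Sox10", "Ncam1"))
  used <- integer(0)
  for (lin in names(sig)) {
    pats <- which(cell_types$lineage == lin)
    if (length(pats) == 0) next
    for (s in sig[[lin]]) {
      g <- setdiff(free, used)[1]
      if (is.na(g)) break
      used <- c(used, g)
      A[g, ] <- 0.01
      A[g, pats] <- 6
      sym[g] <- s
    }
  }
  list(A = A, marker_symbols = sym)
}

# Per-cell expected gene profile (sums to 1) after imposing the cell's
# mitochondrial fraction and its batch's multiplicative gene shifts.
cell_profiles <- function(A, P, mito_idx, mito_frac, batch_shift) {
  base <- A %*% P                       # genes x cells
  base <- sweep(base, 2, colSums(base), "/")
  base <- base * exp(batch_shift)       # genes x cells shift matrix
  base <- sweep(base, 2, colSums(base), "/")
  nonmito <- setdiff(seq_len(nrow(base)), mito_idx)
  out <- base
  nm_sum <- colSums(base[nonmito, , drop = FALSE])
  mt_sum <- colSums(base[mito_idx, , drop = FALSE])
  out[nonmito, ] <- sweep(base[nonmito, , drop = FALSE], 2,
                          (1 - mito_frac) / pmax(nm_sum, 1e-12), "*")
  mt_prof <- base[mito_idx, , drop = FALSE]
  flat <- mt_sum < 1e-12
  if (any(flat)) mt_prof[, flat] <- 1 / length(mito_idx)
  mt_prof <- sweep(mt_prof, 2, colSums(mt_prof), "/")
  out[mito_idx, ] <- sweep(mt_prof, 2, mito_frac, "*")
  out
}

#' Simulate the age-structured reference cohort
#'
#' Draws, per sample, cells whose type is chosen with MEN-like probability
#' given by the composition curve at the sample's age; per-cell expression
#' is a negative-binomial draw around a library-size-scaled convex mixture
#' of the generating programs, with mitochondrial mass, batch shifts and a
#' configurable "damaged" high-mitochondrial subpopulation.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `counts`
#'   ([sc_counts]) and `truth` (generating amplitudes `A_true`, per-cell
#'   mixtures `p_true`, labels, realized `men_fraction_by_sample`).
#' @export
simulate_reference_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_child_seed(config$seed, "reference", {
    ng <- config$n_genes; k <- config$n_true_patterns
    mito_idx <- seq_len(config$mito_gene_count) + (ng - config$mito_gene_count)
    made <- make_A_true(ng, k, mito_idx, config$cell_types)
    A <- made$A
    types <- config$cell_types
    men_types <- which(types$lineage == "MEN-like")
    other_types <- setdiff(seq_len(nrow(types)), men_types)

    samples <- config$age_points
    n_batches <- max(1L, config$n_batches)
    batch_of_sample <- ((seq_len(nrow(samples)) - 1L) %% n_batches) + 1L
    batch_shift_gene <- matrix(rnorm(ng * n_batches, 0, config$batch_effect_sd),
                               ng, n_batches)

    cells_list <- list(); count_list <- list(); p_list <- list()
    for (si in seq_len(nrow(samples))) {
      nc <- config$cells_per_sample
      p_men <- composition_curve(samples$age_days[si], config$composition)
      is_men <- runif(nc) < p_men
      type_id <- integer(nc)
      if (length(men_types)) {
        type_id[is_men] <- sample(rep(men_types, 2), sum(is_men), replace = TRUE)
      } else is_men[] <- FALSE
      type_id[!is_men] <- sample(rep(other_types, 2), sum(!is_men), replace = TRUE)

      P <- do.call(cbind, types$mixture[type_id])   # k x nc
      damaged <- runif(nc) < config$damaged_fraction
      mf <- ifelse(damaged,
                   rbeta(nc, 8, 12),
                   rbeta(nc, config$mito_fraction$a, config$mito_fraction$b))
      shift <- matrix(batch_shift_gene[, batch_of_sample[si]], ng, nc)
      prof <- cell_profiles(A, P, mito_idx, mf, shift)
      s_c <- rlnorm(nc, config$library_size$meanlog, config$library_size$sdlog)
      mu <- sweep(prof, 2, s_c, "*")
      cnt <- matrix(rnbinom(ng * nc, mu = mu, size = config$nb_dispersion), ng, nc)
      count_list[[si]] <- cnt
      p_list[[si]] <- P
      cells_list[[si]] <- tibble::tibble(
        barcode = sprintf("%s_c%04d", samples$sample[si], seq_len(nc)),
        sample = samples$sample[si],
        batch = paste0("batch", batch_of_sample[si]),
        age_days = samples$age_days[si],
        type = types$label[type_id],
        lineage = types$lineage[type_id],
        mito_fraction_true = mf,
        library_size_true = s_c
      )
    }
    cells <- dplyr::bind_rows(cells_list)
    counts <- do.call(cbind, count_list)
    genes <- tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(ng)),
      gene_symbol = ifelse(is.na(made$marker_symbols),
                           sprintf("Gene%04d", seq_len(ng)),
                           made$marker_symbols),
      is_mito = seq_len(ng) %in% mito_idx
    )
    genes$gene_symbol[mito_idx] <- sprintf("mt-Gene%02d", seq_along(mito_idx))
    sc <- sc_counts(counts, genes, cells)
    men_frac <- cells |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(men_fraction = mean(.data$lineage == "MEN-like"),
                       n = dplyr::n(), .groups = "drop")
    truth <- list(
      A_true = A, p_true = do.call(cbind, p_list),
      cell_labels = cells, theta_true = NULL,
      men_fraction_by_sample = men_frac, config = config
    )
    structure(list(counts = sc, truth = truth), class = "sim_cohort")
  })
}

#' Simulate a platform-shifted target dataset from a reference cohort
#'
#' Binomially thins every count (emulating shallower sequencing), keeps a
#' random gene subset (emulating a different panel/annotation) and
#' optionally renames gene symbols through a map to exercise
#' cross-annotation feature matching. Cell labels carry over.
#'
#' @param ref A `sim_cohort` from [simulate_reference_cohort()].
#' @param depth_fraction Retention probability per UMI, in (0, 1].
#' @param gene_subset_fraction Fraction of genes retained, in (0, 1].
#' @param rename_map Optional tibble with columns `from`, `to` renaming
#'   gene symbols.
#' @param seed Seed; defaults to the reference configuration's seed.
#' @return A `sim_cohort` with thinned counts and the carried-over truth.
#' @export
simulate_target_dataset <- function(ref, depth_fraction, gene_subset_fraction = 1,
                                    rename_map = NULL, seed = NULL) {
  stopifnot(inherits(ref, "sim_cohort"))
  if (depth_fraction <= 0 || depth_fraction > 1) {
    abort("depth_fraction must be in (0, 1]", class = "config_error")
  }
  if (gene_subset_fraction <= 0 || gene_subset_fraction > 1) {
    abort("gene_subset_fraction must be in (0, 1]", class = "config_error")
  }
  seed <- seed %||% ref$truth$config$seed
  with_child_seed(seed, "target", {
    m <- ref$counts$counts
    if (depth_fraction < 1) {
      m@x <- as.double(rbinom(length(m@x), size = as.integer(m@x),
                              prob = depth_fraction))
      m <- Matrix::drop0(m)
    }
    genes <- ref$counts$genes
    keep <- sort(sample(nrow(genes), ceiling(gene_subset_fraction * nrow(genes))))
    m <- m[keep, , drop = FALSE]
    genes <- genes[keep, ]
    if (!is.null(rename_map)) {
      i <- match(genes$gene_symbol, rename_map$from)
      genes$gene_symbol[!is.na(i)] <- rename_map$to[i[!is.na(i)]]
    }
    sc <- sc_counts(m, genes, ref$counts$cells)
    structure(list(counts = sc, truth = ref$truth, kept_genes = keep),
              class = "sim_cohort")
  })
}

#' Simulate a two-group bulk cohort with a planted MEN-fraction shift
#'
#' Each sample's linear-scale expression is a convex mixture of the
#' cell-type mean profiles; the disease group's MEN-like proportion is
#' raised by `men_shift` (other types rescaled proportionally). Gene-wise
#' log-normal noise is applied and the matrix returned on the log2(x+1)
#' scale, samples in rows.
#'
#' @param ref A `sim_cohort` reference.
#' @param n_per_group Samples per group (default 3, the obstructed-
#'   defecation study design).
#' @param men_shift Additive shift of the MEN-like fraction in group 2.
#' @param noise_sd SD of gene-wise log-normal noise.
#' @param base_fractions Optional baseline cell-type fractions (defaults
#'   to uniform over types).
#' @param scale Linear-scale library constant before logging (default 1e4).
#' @param seed Seed (defaults to config seed).
#' @return List with `expr` (samples x genes log2 matrix), `samples`
#'   tibble (sample, group) and `truth` (noise-free group means, fractions).
#' @export
simulate_bulk_cohort <- function(ref, n_per_group = 3, men_shift = 0.3,
                                 noise_sd = 0.1, base_fractions = NULL,
                                 scale = 1e4, seed = NULL) {
  stopifnot(inherits(ref, "sim_cohort"))
  types <- ref$truth$config$cell_types
  k <- nrow(types)
  f0 <- base_fractions %||% rep(1 / k, k)
  stopifnot(length(f0) == k, abs(sum(f0) - 1) < 1e-8)
  men <- types$lineage == "MEN-like"
  f_men <- sum(f0[men])
  if (f_men + men_shift > 1 || f_men + men_shift < 0) {
    abort("men_shift pushes the MEN-like fraction outside [0, 1]",
          class = "config_error")
  }
  f1 <- f0
  f1[men] <- f0[men] * (f_men + men_shift) / f_men
  f1[!men] <- f0[!men] * (1 - f_men - men_shift) / (1 - f_men)

  A <- ref$truth$A_true
  profiles <- vapply(types$mixture, function(mx) {
    v <- as.numeric(A %*% mx); v / sum(v)
  }, numeric(nrow(A)))                     # genes x types
  mean0 <- scale * as.numeric(profiles %*% f0)
  mean1 <- scale * as.numeric(profiles %*% f1)
  seed <- seed %||% ref$truth$config$seed
  with_child_seed(seed, "bulk", {
    ng <- nrow(A)
    make_group <- function(mu, g) {
      t(vapply(seq_len(n_per_group), function(i) {
        mu * exp(rnorm(ng, 0, noise_sd))
      }, numeric(ng)))
    }
    lin <- rbind(make_group(mean0, 1), make_group(mean1, 2))
    expr <- log2(lin + 1)
    rownames(expr) <- sprintf("sample%d", seq_len(2 * n_per_group))
    colnames(expr) <- ref$counts$genes$gene_id
    samples <- tibble::tibble(
      sample = rownames(expr),
      group = rep(c("control", "disease"), each = n_per_group)
    )
    list(expr = expr, samples = samples,
         truth = list(mean_control = mean0, mean_disease = mean1,
                      fractions_control = f0, fractions_disease = f1))
  })
}

#' Simulate a cohort with planted circular cell-cycle structure
#'
#' A configured fraction of cells receives a true cell-cycle position
#' theta; cell-cycle genes have log-mean `a_g + b_g cos(theta - phi_g)`
#' with gene-wise phases, so expression traces a closed loop over theta.
#' Cells without theta (and all non-cycle genes) use the `b_g`-independent
#' baseline. Counts are negative-binomial around the library-size-scaled
#' profile.
#'
#' @param config A [sim_config()].
#' @param n_cc_genes Number of cell-cycle genes (default 500).
#' @param frac_with_theta Fraction of cells assigned a position.
#' @param theta_mode `"uniform"` draws theta uniformly on the circle;
#'   `"arcs"` plants a cycling arc (theta in \[0.5pi, 1.5pi)) for
#'   `arc_cycling_fraction` of positioned cells and a quiescent arc for the
#'   rest, both kept `arc_margin` away from the boundaries.
#' @param arc_cycling_fraction,arc_margin Arc-mode parameters.
#' @param cc_amplitude Multiplier on the angular amplitudes `b_g`
#'   (0 gives a structure-free negative control).
#' @param seed Seed (defaults to config seed).
#' @return A `sim_cohort`; `truth$theta_true` holds per-cell angles
#'   (NA where no position was planted).
#' @export
simulate_cellcycle_cohort <- function(config, n_cc_genes = 500,
                                      frac_with_theta = 1,
                                      theta_mode = c("uniform", "arcs"),
                                      arc_cycling_fraction = 0.4,
                                      arc_margin = 0.1 * pi,
                                      cc_amplitude = 1, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  theta_mode <- match.arg(theta_mode)
  if (n_cc_genes < 4) abort("n_cc_genes must be >= 4", class = "config_error")
  if (n_cc_genes > config$n_genes) {
    abort("n_cc_genes cannot exceed n_genes", class = "config_error")
  }
  seed <- seed %||% config$seed
  with_child_seed(seed, "cellcycle", {
    ng <- config$n_genes
    nc <- config$cells_per_sample * nrow(config$age_points)
    cc <- seq_len(n_cc_genes)
    a <- rnorm(ng, 0, 0.5)
    b <- numeric(ng)
    b[cc] <- cc_amplitude * runif(n_cc_genes, 0.5, 1.5)
    phase <- runif(ng, 0, 2 * pi)

    has_theta <- runif(nc) < frac_with_theta
    theta <- rep(NA_real_, nc)
    if (theta_mode == "uniform") {
      theta[has_theta] <- runif(sum(has_theta), 0, 2 * pi)
    } else {
      n_pos <- sum(has_theta)
      cyc <- runif(n_pos) < arc_cycling_fraction
      th <- numeric(n_pos)
      th[cyc] <- runif(sum(cyc), 0.5 * pi + arc_margin, 1.5 * pi - arc_margin)
      th[!cyc] <- (runif(sum(!cyc), 1.5 * pi + arc_margin,
                         2.5 * pi - arc_margin)) %% (2 * pi)
      theta[has_theta] <- th
    }
    logmu <- matrix(a, ng, nc)
    pos <- which(!is.na(theta))
    if (length(pos)) {
      logmu[, pos] <- logmu[, pos] +
        outer(b, theta[pos], function(bg, th) bg) *
        cos(outer(phase, theta[pos], function(ph, th) th - ph))
    }
    prof <- exp(logmu)
    prof <- sweep(prof, 2, colSums(prof), "/")
    s_c <- rlnorm(nc, config$library_size$meanlog, config$library_size$sdlog)
    mu <- sweep(prof, 2, s_c, "*")
    cnt <- matrix(rnbinom(ng * nc, mu = mu, size = config$nb_dispersion), ng, nc)
    genes <- tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(ng)),
      gene_symbol = ifelse(seq_len(ng) %in% cc,
                           sprintf("Ccg%03d", seq_len(ng)),
                           sprintf("Gene%04d", seq_len(ng))),
      is_mito = FALSE,
      is_cc = seq_len(ng) %in% cc
    )
    cells <- tibble::tibble(
      barcode = sprintf("cc_c%05d", seq_len(nc)),
      sample = "cc_cohort",
      theta_true = theta,
      cycling_true = !is.na(theta) & classify_cycling(ifelse(is.na(theta), 0, theta))
    )
    sc <- sc_counts(cnt, genes, cells)
    truth <- list(theta_true = theta, cc_genes = genes$gene_id[cc],
                  amplitudes = b[cc], phases = phase[cc], config = config)
    structure(list(counts = sc, truth = truth), class = "sim_cohort")
  })
}

#' Simulate an unfiltered droplet pool (cells plus empty droplets)
#'
#' Concatenates the reference cohort's cells with empty droplets whose
#' totals are Poisson around `ambient_scale` and whose gene profile is the
#' ambient (mean cell) profile; barcode order is shuffled. The truth
#' records which barcodes contain cells.
#'
#' @param config A [sim_config()].
#' @return A `sim_cohort`; `counts$cells$is_cell` flags real cells.
#' @export
simulate_droplet_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_empty_droplets <= 0) {
    abort("n_empty_droplets must be > 0 for a two-population pool",
          class = "config_error")
  }
  ref <- simulate_reference_cohort(config)
  with_child_seed(config$seed, "droplets", {
    m <- ref$counts$counts
    ng <- nrow(m)
    ambient <- Matrix::rowSums(m)
    ambient <- if (sum(ambient) > 0) ambient / sum(ambient) else rep(1 / ng, ng)
    ne <- config$n_empty_droplets
    # independent Poisson per gene <=> Poisson total + multinomial profile
    lam <- config$ambient_scale * ambient
    empties <- matrix(rpois(ng * ne, lambda = rep(lam, ne)), ng, ne)
    empties <- to_sparse(empties)
    cells_meta <- dplyr::bind_rows(
      dplyr::mutate(ref$counts$cells, is_cell = TRUE),
      tibble::tibble(barcode = sprintf("empty_%05d", seq_len(ne)),
                     sample = "ambient", is_cell = FALSE)
    )
    all_counts <- cbind(m, empties)
    ord <- sample(ncol(all_counts))
    sc <- sc_counts(all_counts[, ord, drop = FALSE],
                    ref$counts$genes, cells_meta[ord, ])
    structure(list(counts = sc, truth = ref$truth), class = "sim_cohort")
  })
}
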