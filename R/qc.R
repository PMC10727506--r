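#' Per-cell QC metrics
#'
#' Computes total UMI, mitochondrial UMI (the sum over the annotated
#' mitochondrial genes) and the mitochondrial read ratio for every cell.
#' No filtering is applied. An all-zero cell gets `mito_ratio = 0` and is
#' flagged `degenerate`.
#'
#' @param x An [sc_counts] object.
#' @param mito_gene_ids Gene ids treated as mitochondrial; defaults to the
#'   `is_mito` flag of the gene metadata. Ids absent from the matrix are
#'   dropped with a warning.
#' @return A tibble (barcode, total_umi, mito_umi, mito_ratio, degenerate).
#' @export
compute_qc_metrics <- function(x, mito_gene_ids = NULL) {
  stopifnot(inherits(x, "sc_counts"))
  if (nrow(x$counts) == 0 || ncol(x$counts) == 0) {
    abort("empty count matrix", class = "format_error")
  }
  if (is.null(mito_gene_ids)) mito_gene_ids <- x$genes$gene_id[x$genes$is_mito]
  miss <- setdiff(mito_gene_ids, x$genes$gene_id)
  if (length(miss)) {
    warn(sprintf("%d mitochondrial ids not present in the matrix", length(miss)))
    mito_gene_ids <- setdiff(mito_gene_ids, miss)
  }
  total <- unname(Matrix::colSums(x$counts))
  mito <- if (length(mito_gene_ids)) {
    unname(Matrix::colSums(x$counts[x$genes$gene_id %in% mito_gene_ids, , drop = FALSE]))
  } else rep(0, ncol(x$counts))
  tibble::tibble(
    barcode = x$cells$barcode,
    total_umi = total,
    mito_umi = mito,
    mito_ratio = ifelse(total > 0, mito / total, 0),
    degenerate = total == 0
  )
}

#' Barcode-rank knee and inflection statistics
#'
#' Sorts barcode totals in decreasing order, collapses ties to unique
#' (rank, total) points, fits a smoothing spline to log10(total) against
#' log10(rank) and locates two landmarks of the curve: the inflection
#' point (minimum first derivative, restricted to ranks right of the upper
#' plateau) and the knee (minimum signed curvature left of the
#' inflection). These landmarks separate cell-containing droplets from the
#' ambient tail of a droplet pool.
#'
#' @param totals Per-barcode total UMI counts (>= 100 barcodes).
#' @param grid_n Evaluation grid size along log10(rank).
#' @return An object of class `barcode_rank_stats`: a list with
#'   `knee_rank`, `knee_total`, `inflection_rank`, `inflection_total`,
#'   `low_confidence` and the smoothed `curve` tibble.
#' @export
barcode_rank_stats <- function(totals, grid_n = 500) {
  totals <- as.numeric(totals)
  if (length(totals) < 100) abort("need >= 100 barcodes", class = "format_error")
  if (length(unique(totals)) < 2) {
    abort("constant totals: barcode-rank curve is degenerate",
          class = "degenerate_curve_error")
  }
  o <- order(totals, decreasing = TRUE)
  tot <- totals[o]
  pos <- tot > 0
  tot <- tot[pos]
  r <- seq_along(tot)
  # collapse ties: one point per distinct total at the mean rank of the tie
  agg <- tapply(r, tot, mean)
  utot <- as.numeric(names(agg))
  urank <- as.numeric(agg)
  ord <- order(urank)
  lx <- log10(urank[ord]); ly <- log10(utot[ord])
  if (length(lx) < 4) {
    abort("too few distinct totals for a smooth curve",
          class = "degenerate_curve_error")
  }
  fit <- smooth.spline(lx, ly, spar = 0.6)
  gx <- seq(min(lx), max(lx), length.out = grid_n)
  gy <- predict(fit, gx)$y
  d1 <- predict(fit, gx, deriv = 1)$y
  d2 <- predict(fit, gx, deriv = 2)$y
  # upper plateau: initial stretch where the curve is still near its maximum
  y_range <- max(gy) - min(gy)
  plateau <- gy > max(gy) - 0.05 * y_range
  right_edge <- if (any(plateau)) max(which(plateau)) else 1L
  search <- seq(min(right_edge + 1L, grid_n), grid_n)
  i_inf <- search[which.min(d1[search])]
  left <- seq_len(i_inf)
  curvature <- d2[left] / (1 + d1[left]^2)^1.5
  i_knee <- left[which.min(curvature)]
  # a near-constant slope means no two-population structure
  low_conf <- (max(d1) - min(d1)) < 0.25
  structure(list(
    knee_rank = round(10^gx[i_knee]),
    knee_total = 10^gy[i_knee],
    inflection_rank = round(10^gx[i_inf]),
    inflection_total = 10^gy[i_inf],
    low_confidence = low_conf,
    curve = tibble::tibble(log10_rank = gx, log10_total = gy,
                           d1 = d1, d2 = d2)
  ), class = "barcode_rank_stats")
}

#' @export
print.barcode_rank_stats <- function(x, ...) {
  cat(sprintf("<barcode_rank_stats> knee: rank %d (total %.1f); inflection: rank %d (total %.1f)%s\n",
              x$knee_rank, x$knee_total, x$inflection_rank, x$inflection_total,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Filter cells on total UMI and mitochondrial ratio
#'
#' A cell passes iff `total_umi >= min_umi` (the minimum threshold is
#' inclusive) and `mito_ratio < max_mito` (strictly below). Presets used
#' in the murine myenteric-plexus analyses: `min_umi = 200` (P180 cohort)
#' or `600` (P21 cohort), `max_mito = 0.20`.
#'
#' @param x An [sc_counts] object.
#' @param min_umi Inclusive minimum total UMI.
#' @param max_mito Exclusive maximum mitochondrial ratio, in (0, 1].
#' @param mito_gene_ids Passed to [compute_qc_metrics()].
#' @return List with `mask` (logical per cell), `filtered` ([sc_counts])
#'   and the QC `metrics` tibble with a `pass` column.
#' @export
filter_cells <- function(x, min_umi = 200, max_mito = 0.20,
                         mito_gene_ids = NULL) {
  stopifnot(min_umi >= 0, max_mito > 0, max_mito <= 1)
  qc <- compute_qc_metrics(x, mito_gene_ids)
  mask <- qc$total_umi >= min_umi & qc$mito_ratio < max_mito
  filtered <- sc_counts(x$counts[, mask, drop = FALSE],
                        x$genes, x$cells[mask, ])
  list(mask = mask, filtered = filtered,
       metrics = dplyr::mutate(qc, pass = mask))
}

#' Library-size size factors
#'
#' `sf_c = total_c / geometric_mean(totals)`; the mean of `log(sf)` is 0
#' and the product of the factors is 1.
#'
#' @param totals Per-cell totals, all strictly positive.
#' @return Positive size factors, one per cell.
#' @export
size_factors <- function(totals) {
  totals <- as.numeric(totals)
  if (any(totals <= 0)) {
    abort("all totals must be > 0; filter cells first", class = "config_error")
  }
  totals / geo_mean(totals)
}

#' Log-normalize a count matrix
#'
#' entry = log_base(count / sf + 1). Zero counts map to exactly 0, so
#' sparsity is preserved.
#'
#' @param x An [sc_counts] or a (sparse) genes x cells matrix.
#' @param sf Per-cell positive size factors; default library size over
#'   geometric mean.
#' @param log_base 10 (default) or 2.
#' @param pseudo Pseudo-count, fixed at 1.
#' @return A sparse `dgCMatrix` of normalized values (genes x cells).
#' @export
normalize_counts <- function(x, sf = NULL, log_base = 10, pseudo = 1) {
  if (!log_base %in% c(2, 10)) abort("log_base must be 2 or 10", class = "config_error")
  if (pseudo != 1) abort("pseudo-count is fixed at 1", class = "config_error")
  m <- if (inherits(x, "sc_counts")) x$counts else
    to_sparse(x)
  if (is.null(sf)) sf <- size_factors(Matrix::colSums(m))
  if (any(sf <= 0)) abort("size factors must be > 0", class = "config_error")
  sfrep <- rep(sf, diff(m@p))
  out <- m
  out@x <- log(m@x / sfrep + 1, base = log_base)
  out
}
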