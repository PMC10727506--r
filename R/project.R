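#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves argmin_{p >= 0} ||y - A p||^2. At the solution the KKT
#' conditions hold: the gradient is zero on the active (positive) support
#' and non-negative where p = 0.
#'
#' @param A n x m design matrix.
#' @param y Length-n response.
#' @param tol Dual-feasibility tolerance.
#' @return List with `coef` (length m, >= 0) and `residual_ss`.
#' @export
nnls_solve <- function(A, y, tol = 1e-10) {
  A <- as.matrix(A); y <- as.numeric(y)
  m <- ncol(A)
  passive <- logical(m)
  x <- numeric(m)
  w <- drop(crossprod(A, y))                 # gradient of -0.5||y - Ax||^2 at 0
  AtA <- crossprod(A)
  max_outer <- 30 * m + 50
  for (iter in seq_len(max_outer)) {
    w <- drop(crossprod(A, y) - AtA %*% x)
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      idx <- which(passive)
      s <- numeric(m)
      s[idx] <- drop(solve(AtA[idx, idx, drop = FALSE],
                           crossprod(A[, idx, drop = FALSE], y)))
      if (all(s[idx] > tol)) { x <- s; break }
      neg <- idx[s[idx] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
  }
  list(coef = x, residual_ss = sum((y - A %*% x)^2))
}

#' Match reference features to a target gene list
#'
#' Case-insensitive exact symbol matching, optionally translating target
#' symbols through a 1:1 ortholog/synonym map first (ambiguous map rows
#' are dropped with a warning). Errors when fewer than `min_match_frac`
#' of the reference genes find a partner.
#'
#' @param ref_genes Reference gene symbols (the pattern rows).
#' @param target_genes Target gene symbols.
#' @param ortholog_map Optional tibble with columns `from` (target
#'   vocabulary) and `to` (reference vocabulary).
#' @param min_match_frac Minimum matched fraction of reference genes.
#' @return Tibble (ref_index, target_index, ref_gene, target_gene).
#' @export
match_features <- function(ref_genes, target_genes, ortholog_map = NULL,
                           min_match_frac = 0.5) {
  if (!length(ref_genes) || !length(target_genes)) {
    abort("gene lists must be non-empty", class = "config_error")
  }
  translated <- target_genes
  if (!is.null(ortholog_map)) {
    dup <- unique(c(ortholog_map$from[duplicated(ortholog_map$from)],
                    ortholog_map$to[duplicated(ortholog_map$to)]))
    if (length(dup)) {
      warn(sprintf("dropping %d ambiguous ortholog-map rows", length(dup)))
      ortholog_map <- ortholog_map[!(ortholog_map$from %in% dup |
                                       ortholog_map$to %in% dup), ]
    }
    i <- match(tolower(target_genes), tolower(ortholog_map$from))
    translated[!is.na(i)] <- ortholog_map$to[i[!is.na(i)]]
  }
  ti <- match(tolower(ref_genes), tolower(translated))
  ok <- !is.na(ti)
  frac <- mean(ok)
  if (frac < min_match_frac) {
    abort(sprintf("only %.1f%% of reference genes matched (minimum %.1f%%)",
                  100 * frac, 100 * min_match_frac),
          class = "feature_match_error")
  }
  tibble::tibble(
    ref_index = which(ok),
    target_index = ti[ok],
    ref_gene = ref_genes[ok],
    target_gene = target_genes[ti[ok]]
  )
}

#' Project expression profiles into a fixed pattern space
#'
#' Regresses each target column (cell, nucleus or bulk sample) onto the
#' selected pattern amplitudes: non-negative least squares by default
#' (respecting the NMF cone), ordinary least squares when
#' `nonneg = FALSE`. Reports per-target R^2 = 1 - RSS/TSS.
#'
#' @param target_norm genes x targets matrix, rows aligned with `A_sel`
#'   (use [match_features()] first for unaligned data).
#' @param A_sel genes x m amplitude matrix of the selected patterns.
#' @param nonneg Constrain weights to be non-negative (default TRUE).
#' @param target_kind "cell", "nucleus" or "bulk-sample" (metadata only).
#' @return An object of class `projection_result`: list with `weights`
#'   (m x targets), `r2`, `matched_gene_count`, `target_kind`, `nonneg`.
#' @export
project_patterns <- function(target_norm, A_sel, nonneg = TRUE,
                             target_kind = c("cell", "nucleus", "bulk-sample")) {
  target_kind <- match.arg(target_kind)
  Y <- as_dense(target_norm)
  A <- as.matrix(A_sel)
  if (nrow(Y) != nrow(A)) {
    abort("target and amplitude rows are not aligned; run match_features()",
          class = "feature_match_error")
  }
  if (ncol(A) < 1) abort("need >= 1 pattern", class = "config_error")
  m <- ncol(A); nt <- ncol(Y)
  W <- matrix(0, m, nt)
  r2 <- numeric(nt)
  if (nonneg) {
    for (j in seq_len(nt)) {
      fit <- nnls_solve(A, Y[, j])
      W[, j] <- fit$coef
      tss <- sum((Y[, j] - mean(Y[, j]))^2)
      r2[j] <- if (tss > 0) 1 - fit$residual_ss / tss else NA_real_
    }
  } else {
    qr_a <- qr(A)
    if (qr_a$rank < m) {
      warn("rank-deficient amplitude matrix; minimum-norm OLS solution used")
      Ap <- svd_pinv(A)
      W <- Ap %*% Y
    } else {
      W <- qr.coef(qr_a, Y)
    }
    res <- Y - A %*% W
    tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
    r2 <- ifelse(tss > 0, 1 - colSums(res^2) / tss, NA_real_)
  }
  rownames(W) <- colnames(A) %||% paste0("p", seq_len(m))
  colnames(W) <- colnames(Y)
  structure(list(weights = W, r2 = r2,
                 matched_gene_count = nrow(A),
                 target_kind = target_kind, nonneg = nonneg),
            class = "projection_result")
}

svd_pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %d %ss onto %d patterns (%d matched genes); median R2 %.3f\n",
              ncol(x$weights), x$target_kind, nrow(x$weights),
              x$matched_gene_count, median(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' Cluster targets on their projected pattern weights
#'
#' Builds a shared-nearest-neighbor graph in the m-dimensional weight
#' space and runs community detection — the route used to identify
#' pattern-defined populations in projected single-nucleus data.
#'
#' @param proj A `projection_result` (or m x targets weight matrix).
#' @param knn_k,method,resolution,seed Passed to [snn_graph()] /
#'   [cluster_graph()].
#' @return A [cluster_graph()] tibble.
#' @export
cluster_on_projection <- function(proj, knn_k = 10, method = "leiden",
                                  resolution = 5e-4, seed = 1L) {
  W <- if (inherits(proj, "projection_result")) proj$weights else as.matrix(proj)
  if (nrow(W) < 2) abort("need >= 2 patterns", class = "config_error")
  g <- snn_graph(t(W), knn_k = knn_k)
  cluster_graph(g, method = method, resolution = resolution, seed = seed)
}

#' Aggregate projection weights to per-sample means
#'
#' @param proj A `projection_result` or m x targets weight matrix.
#' @param sample_ids Sample id per target column.
#' @return Tibble (sample, pattern, mean_weight, n_cells).
#' @export
aggregate_by_sample <- function(proj, sample_ids) {
  W <- if (inherits(proj, "projection_result")) proj$weights else as.matrix(proj)
  stopifnot(length(sample_ids) == ncol(W))
  tibble::tibble(
    sample = rep(as.character(sample_ids), each = nrow(W)),
    pattern = rep(rownames(W) %||% paste0("p", seq_len(nrow(W))), ncol(W)),
    weight = as.numeric(W)
  ) |>
    dplyr::group_by(.data$sample, .data$pattern) |>
    dplyr::summarise(mean_weight = mean(.data$weight),
                     n_cells = dplyr::n(), .groups = "drop")
}

#' Assign human samples to coarse age groups
#'
#' Juvenile = 4-12 years, Adult = 20-50, Aged = 60-75 (all inclusive);
#' ages outside every range are "unassigned".
#'
#' @param age_years Non-negative ages in years.
#' @return Character vector of group labels.
#' @export
assign_age_group <- function(age_years) {
  if (any(age_years < 0)) abort("age must be >= 0", class = "config_error")
  dplyr::case_when(
    age_years >= 4 & age_years <= 12 ~ "Juvenile",
    age_years >= 20 & age_years <= 50 ~ "Adult",
    age_years >= 60 & age_years <= 75 ~ "Aged",
    TRUE ~ "unassigned"
  )
}

#' Differential pattern usage across sample groups
#'
#' Per pattern, compares per-sample mean weights across groups: a
#' two-sided equal-variance Student t-test for two groups (Welch
#' switchable), one-way ANOVA with (DFn, DFd) for three or more.
#' Benjamini-Hochberg q-values across patterns are reported alongside the
#' raw p-values.
#'
#' @param sample_weights Tibble from [aggregate_by_sample()] (columns
#'   sample, pattern, mean_weight).
#' @param groups Named vector or tibble (sample, group) mapping samples
#'   to groups; every group needs >= 2 samples.
#' @param test "auto" (default: t for 2 groups, anova otherwise),
#'   "t", "welch" or "anova".
#' @return Tibble (pattern, test, statistic, df1, df2, p, bh_q, plus one
#'   `mean_<group>` and `sem_<group>` column per group).
#' @export
differential_usage <- function(sample_weights, groups, test = "auto") {
  gmap <- if (is.data.frame(groups)) {
    setNames(as.character(groups$group), groups$sample)
  } else setNames(as.character(groups), names(groups))
  dat <- sample_weights |>
    dplyr::mutate(group = unname(gmap[.data$sample]))
  if (any(is.na(dat$group))) abort("every sample needs a group", class = "config_error")
  counts <- dat |> dplyr::distinct(.data$sample, .data$group) |> dplyr::count(.data$group)
  if (nrow(counts) < 2) abort("need >= 2 groups", class = "config_error")
  if (any(counts$n < 2)) abort("every group needs >= 2 samples", class = "config_error")
  n_groups <- nrow(counts)
  if (test == "auto") test <- if (n_groups == 2) "t" else "anova"
  if (test %in% c("t", "welch") && n_groups != 2) {
    abort("t-test requires exactly 2 groups", class = "config_error")
  }
  res <- dat |>
    dplyr::group_by(.data$pattern) |>
    dplyr::group_modify(function(d, key) {
      sp <- split(d$mean_weight, d$group)
      if (var(d$mean_weight) == 0) {
        # degenerate: no variation at all -> no evidence of a difference
        return(tibble::tibble(
          test = test, statistic = 0,
          df1 = if (test == "anova") n_groups - 1 else nrow(d) - 2,
          df2 = if (test == "anova") nrow(d) - n_groups else NA_real_,
          p = 1
        ))
      }
      if (test == "anova") {
        fit <- aov(mean_weight ~ group, data = d)
        s <- summary(fit)[[1]]
        tibble::tibble(test = "anova", statistic = s[["F value"]][1],
                       df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                       p = s[["Pr(>F)"]][1])
      } else {
        tt <- t.test(sp[[1]], sp[[2]], var.equal = (test == "t"))
        tibble::tibble(test = test, statistic = unname(tt$statistic),
                       df1 = unname(tt$parameter), df2 = NA_real_,
                       p = tt$p.value)
      }
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(bh_q = p.adjust(.data$p, "BH"))
  means <- dat |>
    dplyr::group_by(.data$pattern, .data$group) |>
    dplyr::summarise(mean = mean(.data$mean_weight),
                     sem = sd(.data$mean_weight) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = c("mean", "sem"))
  dplyr::left_join(res, means, by = "pattern")
}
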