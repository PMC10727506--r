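#' PCA embedding of a normalized matrix
#'
#' Selects the top highly variable genes by variance of the normalized
#' values, centers genes and returns the top `d` principal directions.
#'
#' @param norm Normalized genes x cells matrix (sparse or dense).
#' @param d Number of components (>= 2). Default 50 for a full dataset;
#'   the MEN-subset re-embedding uses `d = 20`.
#' @param n_hvg Number of highly variable genes (default 2000; `Inf` keeps
#'   all genes).
#' @return An object of class `embedding`: list with `coords`
#'   (cells x d), `loadings` (features x d), `feature_genes`, `d`,
#'   `sdev`.
#' @export
pca_embed <- function(norm, d = 50, n_hvg = 2000) {
  if (d < 2) abort("d must be >= 2", class = "config_error")
  m <- as_dense(norm)
  v <- apply(m, 1, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, sum(v > 0)))]
  keep <- sort(keep)
  x <- t(m[keep, , drop = FALSE])            # cells x features
  if (d > min(dim(x))) abort("d exceeds the rank bound", class = "config_error")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = d)
  structure(list(
    coords = pc$x[, seq_len(d), drop = FALSE],
    loadings = pc$rotation[, seq_len(d), drop = FALSE],
    center = pc$center,
    feature_genes = rownames(m)[keep] %||% as.character(keep),
    d = d, sdev = pc$sdev
  ), class = "embedding")
}

#' Mutual-nearest-neighbors batch correction in embedding space
#'
#' Batches are merged sequentially in input order. At each merge, mutual
#' k-nearest-neighbor pairs between the incoming batch and the current
#' reference define correction vectors (one per paired incoming cell,
#' taken to its nearest mutual partner); every incoming cell is shifted
#' by a Gaussian-kernel-weighted average of these vectors (kernel
#' bandwidth = median mutual-pair distance). Cells of coinciding batches
#' are left untouched; a single batch is returned unchanged. As in any
#' mutual-neighbor scheme, the displacement is identified only when
#' distinct populations are separated by more than the batch shift.
#'
#' @param embedding An [pca_embed()] result or a cells x d matrix.
#' @param batch Per-cell batch labels.
#' @param k_mnn Neighbors per direction (default 20); every batch must
#'   have at least `k_mnn` cells.
#' @return Corrected object of the same shape as the input.
#' @export
mnn_correct <- function(embedding, batch, k_mnn = 20) {
  is_emb <- inherits(embedding, "embedding")
  X <- if (is_emb) embedding$coords else as.matrix(embedding)
  batch <- as.character(batch)
  stopifnot(length(batch) == nrow(X))
  levels <- unique(batch)
  if (length(levels) == 1L) return(embedding)
  if (any(table(batch) < k_mnn)) {
    abort("every batch needs at least k_mnn cells", class = "config_error")
  }
  out <- X
  ref_idx <- which(batch == levels[1])
  for (b in levels[-1]) {
    idx <- which(batch == b)
    R <- out[ref_idx, , drop = FALSE]
    B <- out[idx, , drop = FALSE]
    D <- cross_dist(B, R)                    # incoming x reference
    knn_b <- t(apply(D, 1, function(row) order(row)[seq_len(k_mnn)]))
    knn_r <- t(apply(D, 2, function(col) order(col)[seq_len(k_mnn)]))
    pair_b <- integer(0); pair_r <- integer(0)
    for (i in seq_len(nrow(B))) {
      for (j in knn_b[i, ]) {
        if (i %in% knn_r[j, ]) { pair_b <- c(pair_b, i); pair_r <- c(pair_r, j) }
      }
    }
    if (length(pair_b) == 0L) {
      warn(sprintf("no mutual pairs between batch '%s' and the reference; batch left uncorrected", b))
      ref_idx <- c(ref_idx, idx)
      next
    }
    # one correction vector per paired incoming cell: its nearest mutual
    # partner (coinciding batches then yield exactly zero corrections)
    d_pair <- D[cbind(pair_b, pair_r)]
    keep <- vapply(split(seq_along(pair_b), pair_b),
                   function(ii) ii[which.min(d_pair[ii])], integer(1))
    pair_b <- pair_b[keep]; pair_r <- pair_r[keep]
    vecs <- R[pair_r, , drop = FALSE] - B[pair_b, , drop = FALSE]
    pair_dist <- D[cbind(pair_b, pair_r)]
    sigma <- median(pair_dist)
    if (sigma == 0) sigma <- 1e-8
    Dp <- cross_dist(B, B[pair_b, , drop = FALSE])  # incoming x pairs
    W <- exp(-Dp^2 / (2 * sigma^2))
    rs <- rowSums(W)
    zero <- rs == 0
    if (any(zero)) { W[zero, ] <- 1; rs[zero] <- ncol(W) }
    shift <- (W %*% vecs) / rs
    out[idx, ] <- B + shift
    ref_idx <- c(ref_idx, idx)
  }
  if (is_emb) { embedding$coords <- out; embedding } else out
}

# Euclidean cross-distance matrix (rows of A vs rows of B).
cross_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Shared-nearest-neighbor graph
#'
#' Edges connect cells whose k-nearest-neighbor lists (self excluded)
#' share at least one member; edge weight is the Jaccard index of the two
#' neighbor sets. No self loops.
#'
#' @param embedding An `embedding` or cells x d matrix.
#' @param knn_k Neighborhood size, `< n_cells`.
#' @return An undirected weighted [igraph::graph] with one vertex per cell.
#' @export
snn_graph <- function(embedding, knn_k = 20) {
  X <- if (inherits(embedding, "embedding")) embedding$coords else as.matrix(embedding)
  n <- nrow(X)
  if (knn_k >= n) abort("knn_k must be < n_cells", class = "config_error")
  D <- cross_dist(X, X)
  diag(D) <- Inf
  nb <- t(apply(D, 1, function(row) order(row)[seq_len(knn_k)]))
  # sparse indicator of neighbor sets; shared counts via cross product
  N <- Matrix::sparseMatrix(i = rep(seq_len(n), each = knn_k),
                            j = as.integer(t(nb)), x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(N)                 # shared-neighbor counts
  S <- to_sparse(S)
  tri <- Matrix::which(S > 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  shared <- S[tri]
  w <- shared / (2 * knn_k - shared)         # Jaccard of two k-sets
  g <- igraph::graph_from_data_frame(
    data.frame(from = tri[, 1], to = tri[, 2], weight = w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  g
}

#' Community detection on a cell graph
#'
#' Leiden (constant Potts model objective) or Louvain (modularity) at a
#' given resolution; deterministic under a fixed seed. Labels are
#' contiguous integers starting at 0.
#'
#' @param graph An [igraph::graph], e.g. from [snn_graph()].
#' @param method "leiden" or "louvain".
#' @param resolution Positive resolution parameter.
#' @param seed Integer seed.
#' @return Tibble (cell, cluster) with an attribute `params`.
#' @export
cluster_graph <- function(graph, method = c("leiden", "louvain"),
                          resolution = 1, seed = 1L) {
  method <- match.arg(method)
  if (igraph::vcount(graph) == 0) abort("empty graph", class = "config_error")
  set.seed(as.integer(seed))
  comm <- if (method == "leiden") {
    igraph::cluster_leiden(graph, objective_function = "CPM",
                           resolution = resolution, n_iterations = 5)
  } else {
    igraph::cluster_louvain(graph, resolution = resolution)
  }
  memb <- igraph::membership(comm)
  lab <- as.integer(factor(memb, levels = unique(memb[order(memb)]))) - 1L
  out <- tibble::tibble(cell = seq_along(lab), cluster = lab)
  attr(out, "params") <- list(method = method, resolution = resolution,
                              knn_k = NA_integer_, seed = as.integer(seed))
  out
}

# Vectorized two-sample Welch statistics per gene (one-sided, "greater"
# for group 1 over group 2). Zero-variance, zero-difference genes get p = 1.
welch_rows <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- pt(t_stat, df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- 1
  t_stat[degen] <- 0
  df[degen] <- NA_real_
  list(t = t_stat, df = df, p = p, lfc = m1 - m2)
}

#' Per-cluster marker genes by pairwise one-sided Welch tests
#'
#' For every gene and cluster, a one-sided Welch t-test ("upregulated in
#' this cluster") is run against every other cluster; the pairwise
#' p-values are combined per gene with Simes' method (or the maximum,
#' i.e. "greater than all others"), Benjamini-Hochberg correction is
#' applied across genes within each cluster, and the summary log fold
#' change is the mean difference from the pairwise comparison with the
#' lowest p-value. Genes are ranked by combined p; the top `top_n` are
#' flagged as markers. Clusters of a single cell are excluded with a
#' warning.
#'
#' @param norm Normalized genes x cells matrix.
#' @param clusters Per-cell integer labels (or a [cluster_graph()] tibble).
#' @param top_n Markers flagged per cluster (default 30).
#' @param combine "simes" (default) or "max".
#' @return Tibble (cluster, gene, combined_p, bh_q, summary_lfc, rank,
#'   is_marker).
#' @export
find_markers <- function(norm, clusters, top_n = 30,
                         combine = c("simes", "max")) {
  combine <- match.arg(combine)
  cl <- cluster_vector(clusters, ncol(norm))
  m <- as_dense(norm)
  sizes <- table(cl)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(sprintf("excluding %d singleton cluster(s)", length(small)))
    keep <- !(cl %in% small)
    m <- m[, keep, drop = FALSE]; cl <- cl[keep]
  }
  labs <- sort(unique(cl))
  if (length(labs) < 2) abort("need >= 2 clusters of >= 2 cells", class = "config_error")
  stats <- lapply(labs, function(a) {
    ia <- cl == a
    ma <- rowMeans(m[, ia, drop = FALSE])
    va <- apply(m[, ia, drop = FALSE], 1, var)
    list(mean = ma, var = va, n = sum(ia))
  })
  names(stats) <- as.character(labs)
  purrr::map_dfr(labs, function(a) {
    sa <- stats[[as.character(a)]]
    others <- setdiff(labs, a)
    pw <- lapply(others, function(b) {
      sb <- stats[[as.character(b)]]
      welch_rows(sa$mean, sa$var, sa$n, sb$mean, sb$var, sb$n)
    })
    P <- do.call(cbind, lapply(pw, `[[`, "p"))       # genes x comparisons
    L <- do.call(cbind, lapply(pw, `[[`, "lfc"))
    comb <- if (combine == "simes") {
      apply(P, 1, function(p) min(sort(p) * length(p) / seq_along(p)))
    } else apply(P, 1, max)
    comb <- pmin(comb, 1)
    best <- max.col(-P, ties.method = "first")
    lfc <- L[cbind(seq_len(nrow(L)), best)]
    tibble::tibble(
      cluster = a,
      gene = rownames(m) %||% as.character(seq_len(nrow(m))),
      combined_p = unname(comb),
      bh_q = unname(p.adjust(comb, "BH")),
      summary_lfc = unname(lfc)
    ) |>
      dplyr::arrange(.data$combined_p) |>
      dplyr::mutate(rank = dplyr::row_number(),
                    is_marker = .data$rank <= top_n)
  })
}

cluster_vector <- function(clusters, n) {
  cl <- if (is.data.frame(clusters)) clusters$cluster else clusters
  stopifnot(length(cl) == n)
  cl
}

# Ridge-penalized logistic log-likelihood and fit by IRLS; slope-only
# penalty, intercept free.
ridge_logistic <- function(x, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(qlogis(mean(y) * 0.98 + 0.01), 0)
  pen <- diag(c(0, lambda))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, w * X) + 2 * pen
    beta_new <- drop(solve(H, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(beta = beta, loglik = ll)
}

#' McFadden pseudo-R2 of cluster membership on gene expression
#'
#' One-vs-rest ridge logistic regression (L2 penalty 1e-4 on the slope)
#' of cluster membership on each gene's normalized expression;
#' pseudo-R2 = 1 - loglik(fit)/loglik(null), clipped to \[0, 1\]. This is
#' the score behind ranking the 30 marker genes per cluster.
#'
#' @param norm Normalized genes x cells matrix.
#' @param clusters Per-cell labels (>= 2 distinct).
#' @param genes Optional subset of gene ids/rows to score.
#' @param lambda Ridge penalty (default 1e-4).
#' @return Tibble (cluster, gene, pseudo_r2).
#' @export
marker_score_pseudo_r2 <- function(norm, clusters, genes = NULL, lambda = 1e-4) {
  cl <- cluster_vector(clusters, ncol(norm))
  if (length(unique(cl)) < 2) abort("need >= 2 clusters", class = "config_error")
  m <- as_dense(norm)
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (!is.null(genes)) {
    idx <- if (is.character(genes)) match(genes, rn) else genes
    m <- m[idx, , drop = FALSE]; rn <- rn[idx]
  }
  purrr::map_dfr(sort(unique(cl)), function(a) {
    y <- as.numeric(cl == a)
    p0 <- mean(y)
    ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
    r2 <- vapply(seq_len(nrow(m)), function(g) {
      x <- m[g, ]
      if (var(x) == 0) return(0)
      fit <- ridge_logistic(x, y, lambda)
      min(max(1 - fit$loglik / ll0, 0), 1)
    }, numeric(1))
    tibble::tibble(cluster = a, gene = rn, pseudo_r2 = r2)
  })
}

#' Annotate clusters from marker-gene signatures
#'
#' Each cluster receives the label whose signature genes have the highest
#' mean z-scored expression in that cluster, provided it beats the
#' runner-up by a margin; otherwise "unassigned". The bundled default
#' signatures identify neural-crest-derived enteric neurons (NENs) by
#' *Ret*, neuroglia by *Sox10*/*Ncam1* and mesoderm-derived enteric
#' neurons (MENs) by co-expression of *Calcb*, *Met* and *Cdh3*.
#'
#' @param norm Normalized genes x cells matrix with gene symbols as
#'   rownames (or supply `gene_symbols`).
#' @param clusters Per-cell labels.
#' @param signatures Named list of gene-symbol vectors; default
#'   [default_signatures()].
#' @param margin Required z-score lead over the runner-up (default 0.25).
#' @param gene_symbols Optional symbols aligned with the matrix rows.
#' @return Tibble (cluster, label, score, runner_up, margin_met).
#' @export
annotate_clusters <- function(norm, clusters, signatures = default_signatures(),
                              margin = 0.25, gene_symbols = NULL) {
  if (!length(signatures) || any(!lengths(signatures))) {
    abort("signatures must be non-empty gene sets", class = "config_error")
  }
  cl <- cluster_vector(clusters, ncol(norm))
  m <- as_dense(norm)
  syms <- gene_symbols %||% rownames(m)
  if (is.null(syms)) abort("gene symbols required", class = "config_error")
  miss <- setdiff(tolower(unlist(signatures)), tolower(syms))
  if (length(miss)) warn(sprintf("%d signature genes absent from the data", length(miss)))
  # z-score per gene across cells; flat genes contribute 0
  mu <- rowMeans(m); sdv <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  labs <- sort(unique(cl))
  purrr::map_dfr(labs, function(a) {
    in_cl <- cl == a
    score <- vapply(signatures, function(gs) {
      idx <- which(tolower(syms) %in% tolower(gs))
      if (!length(idx)) return(NA_real_)
      mean(z[idx, in_cl, drop = FALSE])
    }, numeric(1))
    if (all(is.na(score))) {
      return(tibble::tibble(cluster = a, label = "unassigned",
                            score = NA_real_, runner_up = NA_real_,
                            margin_met = FALSE))
    }
    o <- order(score, decreasing = TRUE)
    best <- o[1]
    second <- if (length(score) > 1) score[o[2]] else -Inf
    ok <- is.finite(score[best]) && (score[best] - second) >= margin
    tibble::tibble(
      cluster = a,
      label = if (ok) names(signatures)[best] else "unassigned",
      score = score[best], runner_up = second, margin_met = ok
    )
  })
}

#' Default lineage marker signatures
#' @return Named list of gene-symbol vectors.
#' @export
default_signatures <- function() {
  list(
    "NEN" = c("Ret"),
    "neuroglia" = c("Sox10", "Ncam1"),
    "MEN" = c("Calcb", "Met", "Cdh3")
  )
}
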