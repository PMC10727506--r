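#' Non-negative matrix factorization by HALS
#'
#' Minimizes 0.5 * ||V - A P||_F^2 over elementwise non-negative A
#' (genes x k amplitudes) and P (k x cells weights) by hierarchical
#' alternating least squares: each factor column/row is updated in closed
#' form with projection onto the non-negative orthant, which makes the
#' objective non-increasing at every sweep. Several random restarts are
#' fitted and the best objective kept. After fitting, columns of A are
#' rescaled to unit L2 norm with the scale absorbed into P.
#'
#' @param norm Non-negative genes x cells matrix (log-normalized values).
#' @param k Number of patterns (default 50, the reference analysis
#'   choice).
#' @param seed Integer seed; restart r uses a child stream keyed by r.
#' @param max_iter Maximum sweeps (default 500).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param n_restarts Random restarts (default 3).
#' @return An object of class `pattern_model`: list with `A`, `P`, `k`,
#'   `objective_trace`, `seed`, `feature_genes`, `iterations`.
#' @export
nmf_fit <- function(norm, k = 50, seed = 1L, max_iter = 500, tol = 1e-6,
                    n_restarts = 3) {
  V <- as_dense(norm)
  if (k < 1 || k > min(dim(V))) abort("k must be in [1, min(dim)]", class = "config_error")
  if (any(V < 0)) abort("input must be non-negative", class = "config_error")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_child_seed(seed, paste0("nmf_restart_", r),
                           hals_fit(V, k, max_iter, tol))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  A <- best$A; P <- best$P
  nrm <- sqrt(colSums(A^2))
  nz <- nrm > 0
  A[, nz] <- sweep(A[, nz, drop = FALSE], 2, nrm[nz], "/")
  P[nz, ] <- sweep(P[nz, , drop = FALSE], 1, nrm[nz], "*")
  rownames(A) <- rownames(V)
  colnames(A) <- rownames(P) <- paste0("p", seq_len(k))
  colnames(P) <- colnames(V)
  structure(list(
    A = A, P = P, k = k,
    objective_trace = best$trace,
    objective = best$objective,
    iterations = length(best$trace),
    seed = as.integer(seed),
    feature_genes = rownames(V) %||% as.character(seq_len(nrow(V)))
  ), class = "pattern_model")
}

hals_fit <- function(V, k, max_iter, tol) {
  ng <- nrow(V); nc <- ncol(V)
  scale0 <- sqrt(mean(V) / k)
  A <- matrix(runif(ng * k, 0, 2 * scale0), ng, k)
  P <- matrix(runif(k * nc, 0, 2 * scale0), k, nc)
  v_sq <- sum(V^2)
  trace <- numeric(0)
  obj_prev <- Inf
  eps <- 1e-16
  for (it in seq_len(max_iter)) {
    # update A given P
    VPt <- V %*% t(P)                        # ng x k
    PPt <- P %*% t(P)                        # k x k
    for (j in seq_len(k)) {
      denom <- PPt[j, j]
      if (denom < eps) { A[, j] <- 0; next }
      a_j <- A[, j] + (VPt[, j] - A %*% PPt[, j]) / denom
      A[, j] <- pmax(a_j, 0)
    }
    # update P given A
    AtV <- t(A) %*% V                        # k x nc
    AtA <- t(A) %*% A
    for (j in seq_len(k)) {
      denom <- AtA[j, j]
      if (denom < eps) { P[j, ] <- 0; next }
      p_j <- P[j, ] + (AtV[j, ] - AtA[j, ] %*% P) / denom
      P[j, ] <- pmax(p_j, 0)
    }
    obj <- 0.5 * (v_sq - 2 * sum(A * (V %*% t(P))) + sum((t(A) %*% A) * (P %*% t(P))))
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= tol * max(obj_prev, eps)) break
    obj_prev <- obj
  }
  list(A = A, P = P, objective = trace[length(trace)], trace = trace)
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("<pattern_model> k = %d over %d genes x %d cells; objective %.4g after %d sweeps\n",
              x$k, nrow(x$A), ncol(x$P), x$objective, x$iterations))
  invisible(x)
}

#' Pattern-by-cluster specificity (AUROC)
#'
#' Scores how exclusively each pattern's cell weights mark each cluster:
#' the AUROC of the weight row as a classifier of cluster membership,
#' with the mean weight inside and outside the cluster recorded.
#'
#' @param model A `pattern_model` (or a k x cells weight matrix).
#' @param clusters Per-cell labels covering all cells; empty clusters are
#'   skipped.
#' @return Tibble (pattern, cluster, auroc, mean_in, mean_out).
#' @export
pattern_specificity <- function(model, clusters) {
  P <- if (inherits(model, "pattern_model")) model$P else as.matrix(model)
  cl <- cluster_vector(clusters, ncol(P))
  pats <- rownames(P) %||% paste0("p", seq_len(nrow(P)))
  purrr::map_dfr(seq_len(nrow(P)), function(i) {
    purrr::map_dfr(sort(unique(cl)), function(a) {
      lab <- cl == a
      tibble::tibble(
        pattern = pats[i], cluster = a,
        auroc = auroc(P[i, ], lab),
        mean_in = mean(P[i, lab]),
        mean_out = mean(P[i, !lab])
      )
    })
  })
}

#' Select the patterns most specific to a target label
#'
#' Ranks the patterns whose best (highest-AUROC) cluster is the target
#' label and returns the top `m` (default 4, mirroring the four
#' MEN-specific patterns). Patterns below `min_auroc` are only returned,
#' with a warning, when fewer than `m` clear the bar.
#'
#' @param spec A [pattern_specificity()] tibble.
#' @param target_label Cluster label to select for.
#' @param m Number of patterns (default 4).
#' @param min_auroc Specificity floor (default 0.9).
#' @return Character vector of pattern ids, most specific first.
#' @export
select_specific_patterns <- function(spec, target_label, m = 4, min_auroc = 0.9) {
  best <- spec |>
    dplyr::group_by(.data$pattern) |>
    dplyr::slice_max(.data$auroc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  hits <- best |>
    dplyr::filter(.data$cluster == target_label) |>
    dplyr::arrange(dplyr::desc(.data$auroc))
  if (nrow(hits) == 0) {
    warn(sprintf("no pattern peaks on '%s'", target_label))
    return(character(0))
  }
  strong <- hits |> dplyr::filter(.data$auroc >= min_auroc)
  if (nrow(strong) < min(m, nrow(hits))) {
    warn(sprintf("only %d pattern(s) reach AUROC >= %.2f for '%s'",
                 nrow(strong), min_auroc, target_label))
  }
  sel <- if (nrow(strong) >= m) head(strong, m) else strong
  sel$pattern
}

#' Hierarchical leaf order of pattern weight rows
#'
#' Euclidean-distance hierarchical clustering (average linkage by
#' default) of the rows of P, for heatmap display.
#'
#' @param P k x cells weight matrix or a `pattern_model`.
#' @param method Linkage (default "average").
#' @return Integer leaf order.
#' @export
hcluster_patterns <- function(P, method = "average") {
  if (inherits(P, "pattern_model")) P <- P$P
  if (nrow(P) < 2) abort("need >= 2 patterns", class = "config_error")
  hc <- hclust(dist(P, method = "euclidean"), method = method)
  hc$order
}
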