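#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pattern model
#'
#' Long tibble of gene amplitudes per pattern (`matrix = "A"`) or cell
#' weights per pattern (`matrix = "P"`).
#'
#' @param x A `pattern_model`.
#' @param matrix "A" (default) or "P".
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pattern_model <- function(x, matrix = c("A", "P"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "A") {
    tibble::tibble(
      gene = rep(rownames(x$A) %||% x$feature_genes, ncol(x$A)),
      pattern = rep(colnames(x$A), each = nrow(x$A)),
      amplitude = as.numeric(x$A)
    )
  } else {
    tibble::tibble(
      pattern = rep(rownames(x$P), ncol(x$P)),
      barcode = rep(colnames(x$P) %||% as.character(seq_len(ncol(x$P))),
                    each = nrow(x$P)),
      weight = as.numeric(x$P)
    )
  }
}

#' One-row summary of a pattern model fit
#' @param x A `pattern_model`.
#' @param ... Unused.
#' @return A one-row tibble (k, objective, iterations, n_genes, n_cells,
#'   seed).
#' @export
glance.pattern_model <- function(x, ...) {
  tibble::tibble(k = x$k, objective = x$objective,
                 iterations = x$iterations,
                 n_genes = nrow(x$A), n_cells = ncol(x$P),
                 seed = x$seed)
}

#' Tidy a projection result into long weights
#' @param x A `projection_result`.
#' @param ... Unused.
#' @return Tibble (target, pattern, weight, r2).
#' @export
tidy.projection_result <- function(x, ...) {
  tibble::tibble(
    target = rep(colnames(x$weights) %||%
                   as.character(seq_len(ncol(x$weights))), each = nrow(x$weights)),
    pattern = rep(rownames(x$weights), ncol(x$weights)),
    weight = as.numeric(x$weights),
    r2 = rep(x$r2, each = nrow(x$weights))
  )
}

#' One-row summary of a projection
#' @param x A `projection_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.projection_result <- function(x, ...) {
  tibble::tibble(n_targets = ncol(x$weights), n_patterns = nrow(x$weights),
                 matched_gene_count = x$matched_gene_count,
                 target_kind = x$target_kind, nonneg = x$nonneg,
                 median_r2 = median(x$r2, na.rm = TRUE))
}
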