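#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx[.gz]`, `features.tsv[.gz]` (or `genes.tsv[.gz]`;
#' 2 or 3 columns: id, symbol, optional feature type) and
#' `barcodes.tsv[.gz]`. Genes are rows of the returned matrix.
#'
#' @param dir Directory holding the triplet.
#' @return An [sc_counts] object.
#' @export
read_10x <- function(dir) {
  find1 <- function(stems) {
    for (s in stems) for (ext in c("", ".gz")) {
      p <- file.path(dir, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
    abort(sprintf("none of %s found in %s", paste(stems, collapse = "/"), dir),
          class = "format_error")
  }
  mtx <- find1("matrix.mtx")
  feat <- find1(c("features.tsv", "genes.tsv"))
  bc <- find1("barcodes.tsv")
  m <- tryCatch(Matrix::readMM(mtx), error = function(e) {
    abort(sprintf("malformed MatrixMarket file %s: %s", mtx, conditionMessage(e)),
          class = "format_error")
  })
  m <- to_sparse(m)
  ft <- readr::read_tsv(feat, col_names = FALSE, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  bcs <- readr::read_tsv(bc, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(ft) != nrow(m) || nrow(bcs) != ncol(m)) {
    abort(sprintf(
      "dimension mismatch: matrix is %d x %d but features has %d rows and barcodes %d",
      nrow(m), ncol(m), nrow(ft), nrow(bcs)), class = "format_error")
  }
  genes <- tibble::tibble(
    gene_id = ft[[1]],
    gene_symbol = if (ncol(ft) >= 2) ft[[2]] else ft[[1]],
    feature_type = if (ncol(ft) >= 3) ft[[3]] else "Gene Expression",
    is_mito = grepl("^mt-", if (ncol(ft) >= 2) ft[[2]] else ft[[1]],
                    ignore.case = TRUE)
  )
  sc_counts(m, genes, tibble::tibble(barcode = bcs[[1]]))
}

#' Write an sc_counts object as a 10x-style triplet
#'
#' Coordinate integer MatrixMarket with 1-based indices, a 3-column
#' features file (id, symbol, feature type) and a barcodes file; `.gz`
#' compression optional.
#'
#' @param x An [sc_counts] object.
#' @param dir Output directory (created if needed).
#' @param gzip Compress the three files (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_10x <- function(x, dir, gzip = FALSE) {
  stopifnot(inherits(x, "sc_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  mtx_plain <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(x$counts, mtx_plain)
  if (gzip) {
    con <- gzfile(paste0(mtx_plain, ".gz"), "wb")
    writeLines(readLines(mtx_plain), con)
    close(con)
    unlink(mtx_plain)
  }
  ftype <- if ("feature_type" %in% names(x$genes)) x$genes$feature_type
  else rep("Gene Expression", nrow(x$genes))
  ft <- data.frame(x$genes$gene_id, x$genes$gene_symbol, ftype)
  readr::write_tsv(ft, file.path(dir, paste0("features.tsv", ext)),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(data.frame(x$cells$barcode),
                   file.path(dir, paste0("barcodes.tsv", ext)),
                   col_names = FALSE, progress = FALSE)
  invisible(dir)
}

#' Serialize a pattern model to CSV + JSON sidecar
#'
#' Writes `amplitudes.csv` (genes x k with gene ids), `weights.csv`
#' (k x cells with barcodes) and `model.json` (k, seed, objective,
#' feature list).
#'
#' @param model A [nmf_fit()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pattern_model <- function(model, dir) {
  stopifnot(inherits(model, "pattern_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  amp <- tibble::as_tibble(model$A) |>
    dplyr::mutate(gene = rownames(model$A) %||% model$feature_genes,
                  .before = 1)
  readr::write_csv(amp, file.path(dir, "amplitudes.csv"), progress = FALSE)
  wt <- tibble::as_tibble(t(model$P)) |>
    dplyr::mutate(barcode = colnames(model$P) %||%
                    as.character(seq_len(ncol(model$P))), .before = 1)
  readr::write_csv(wt, file.path(dir, "weights.csv"), progress = FALSE)
  jsonlite::write_json(
    list(k = model$k, seed = model$seed, objective = model$objective,
         iterations = model$iterations, feature_genes = model$feature_genes),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a serialized pattern model
#' @param dir Directory written by [write_pattern_model()].
#' @return A `pattern_model`.
#' @export
read_pattern_model <- function(dir) {
  amp <- readr::read_csv(file.path(dir, "amplitudes.csv"),
                         show_col_types = FALSE, progress = FALSE)
  wt <- readr::read_csv(file.path(dir, "weights.csv"),
                        show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  A <- as.matrix(amp[, -1]); rownames(A) <- amp[[1]]
  P <- t(as.matrix(wt[, -1])); colnames(P) <- wt[[1]]
  structure(list(A = A, P = P, k = meta$k,
                 objective_trace = numeric(0), objective = meta$objective,
                 iterations = meta$iterations, seed = meta$seed,
                 feature_genes = meta$feature_genes),
            class = "pattern_model")
}

#' Write result tables as CSV with a schema header
#'
#' Writes each named tibble to `<name>.csv` with a `# enspatterns-schema:`
#' comment line, stable column order and floats at full precision.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(results, function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# enspatterns-schema: %s v1", name), con)
    close(con)
    readr::write_csv(tibble::as_tibble(df), path, append = TRUE,
                     col_names = TRUE, progress = FALSE)
    path
  })
  invisible(paths)
}
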