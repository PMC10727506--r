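#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the end-to-end analysis. Presets
#' mirror the two murine cohorts: `"p180"` (min_umi 200) and `"p21"`
#' (min_umi 600); both filter mitochondrial ratio at 0.20 and learn
#' `k = 50` patterns by default. Any field can be overridden.
#'
#' @param preset "p180", "p21" or "custom".
#' @param seed Master seed.
#' @param ... Named overrides of the stage blocks `qc`, `cluster`, `nmf`,
#'   `project`, `cellcycle`, `sim`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("p180", "p21", "custom"), seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    qc = list(min_umi = if (preset == "p21") 600 else 200, max_mito = 0.20),
    cluster = list(d = 50, n_hvg = 2000, knn_k = 20, method = "leiden",
                   resolution = 0.005, batch_key = "batch"),
    nmf = list(k = 50, n_restarts = 3, max_iter = 500, tol = 1e-6),
    project = list(m = 4, min_auroc = 0.9, target_label = "MEN"),
    cellcycle = list(n_cc_genes = 500, span = 0.3),
    sim = list()
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      modifyList(cfg[[nm]], over[[nm]])
    } else over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end analysis on a cohort
#'
#' Orchestrates the stages on an [sc_counts] input (simulated when none
#' is given): QC filtering, normalization, PCA + MNN batch correction,
#' SNN graph clustering, marker detection and annotation, NMF pattern
#' discovery, specificity-based pattern selection. Returns the per-stage
#' results plus a JSON-serializable run report; any stage failure aborts
#' with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param counts Optional [sc_counts]; defaults to
#'   [simulate_reference_cohort()] under `config$sim`.
#' @param out_dir Optional directory for the run report and tables.
#' @return List of class `pipeline_result` with stage outputs and
#'   `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), counts = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "pipeline_error")
    })
  }
  report <- list(package_version = as.character(utils::packageVersion("enspatterns")),
                 preset = config$preset, seed = config$seed, stages = list())
  if (is.null(counts)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      simulate_reference_cohort(sc)
    })
    counts <- sim$counts
    report$stages$simulate <- list(n_genes = nrow(counts$counts),
                                   n_cells = ncol(counts$counts))
  }
  qc <- stage("qc", filter_cells(counts, config$qc$min_umi, config$qc$max_mito))
  report$stages$qc <- list(n_in = ncol(counts$counts),
                           n_pass = sum(qc$mask),
                           min_umi = config$qc$min_umi,
                           max_mito = config$qc$max_mito)
  norm <- stage("normalize", normalize_counts(qc$filtered, log_base = 10))
  emb <- stage("embed", {
    d <- min(config$cluster$d, floor(min(dim(norm)) / 2))
    e <- pca_embed(norm, d = d, n_hvg = config$cluster$n_hvg)
    bk <- config$cluster$batch_key
    if (!is.null(bk) && bk %in% names(qc$filtered$cells) &&
        length(unique(qc$filtered$cells[[bk]])) > 1) {
      e <- mnn_correct(e, qc$filtered$cells[[bk]],
                       k_mnn = min(20, min(table(qc$filtered$cells[[bk]])) - 1))
    }
    e
  })
  clusters <- stage("cluster", {
    g <- snn_graph(emb, knn_k = config$cluster$knn_k)
    cluster_graph(g, method = config$cluster$method,
                  resolution = config$cluster$resolution, seed = config$seed)
  })
  report$stages$cluster <- list(n_clusters = length(unique(clusters$cluster)),
                                method = config$cluster$method,
                                resolution = config$cluster$resolution)
  rownames(norm) <- qc$filtered$genes$gene_symbol
  markers <- stage("markers", find_markers(norm, clusters))
  annot <- stage("annotate", annotate_clusters(norm, clusters))
  model <- stage("nmf", {
    k <- min(config$nmf$k, floor(min(dim(norm)) / 4))
    nmf_fit(norm, k = k, seed = config$seed,
            max_iter = config$nmf$max_iter, tol = config$nmf$tol,
            n_restarts = config$nmf$n_restarts)
  })
  report$stages$nmf <- list(k = model$k, objective = model$objective,
                            iterations = model$iterations)
  selection <- stage("select", {
    # specificity is scored against the fine clusters, then each cluster is
    # translated to its annotation label: a pattern is target-specific when
    # its best cluster is annotated as the target
    spec <- pattern_specificity(model, clusters$cluster)
    lab_map <- setNames(annot$label, annot$cluster)
    spec$cluster <- unname(lab_map[as.character(spec$cluster)])
    select_specific_patterns(spec, config$project$target_label,
                             m = config$project$m,
                             min_auroc = config$project$min_auroc)
  })
  report$stages$select <- list(target = config$project$target_label,
                               patterns = selection)
  out <- structure(list(
    qc = qc, norm = norm, embedding = emb, clusters = clusters,
    markers = markers, annotation = annot, model = model,
    selected_patterns = selection, report = report
  ), class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tables(list(qc_metrics = qc$metrics, clusters = clusters,
                      markers = markers, annotation = annot), out_dir)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cells passed QC; %d clusters; k = %d patterns; selected: %s\n",
              sum(x$qc$mask), length(unique(x$clusters$cluster)), x$model$k,
              paste(x$selected_patterns, collapse = ", ")))
  invisible(x)
}
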