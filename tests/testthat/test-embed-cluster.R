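test_that("PCA embedding captures low-rank structure", {
  set.seed(1)
  a <- runif(30); b <- runif(40)
  rank1 <- outer(a, b)                      # genes x cells, exact rank 1
  emb <- pca_embed(rank1, d = 2, n_hvg = Inf)
  expect_lt(emb$sdev[2], 1e-10)
  expect_error(pca_embed(rank1, d = 1), class = "config_error")
  # variance explained non-decreasing in d against a direct SVD oracle
  X <- matrix(rnorm(100 * 50), 100, 50)
  sv <- svd(scale(t(X), center = TRUE, scale = FALSE))$d
  ve <- sapply(2:10, function(d) sum(pca_embed(X, d = d, n_hvg = Inf)$sdev[1:d]^2))
  expect_true(all(diff(ve) >= -1e-8))
  expect_equal(pca_embed(X, d = 5, n_hvg = Inf)$sdev[1:5] * sqrt(49),
               sv[1:5], tolerance = 1e-8)
})

test_that("MNN correction removes a constant batch shift", {
  # the identifiable regime: displacement below the nearest-neighbor
  # spacing, so mutual pairs are the matched cells themselves
  set.seed(3)
  base <- matrix(rnorm(200 * 5, sd = 3), 200, 5)
  delta <- c(0.3, -0.2, 0.1, 0.05, -0.15)
  X <- rbind(base, sweep(base, 2, delta, "+"))
  batch <- rep(c("b1", "b2"), each = 200)
  corr <- mnn_correct(X, batch, k_mnn = 20)
  shift <- colMeans(corr[201:400, ] - X[201:400, ])
  expect_lt(max(abs(shift + delta)) / max(abs(delta)), 0.01)
  # identical batches: no correction
  X2 <- rbind(base, base)
  corr2 <- mnn_correct(X2, batch, k_mnn = 20)
  expect_lt(max(abs(corr2 - X2)), 1e-8)
  # single batch: identity
  expect_identical(mnn_correct(base, rep("b1", 200)), base)
  expect_error(mnn_correct(X, batch, k_mnn = 500), class = "config_error")
})

test_that("MNN correction reduces batch separation on matched synthetic batches", {
  sim <- simulate_reference_cohort(
    sim_config(seed = 13, cells_per_sample = 150, batch_effect_sd = 0.3,
               age_points = tibble::tibble(sample = c("S1", "S2"),
                                           age_days = c(60, 60))))
  qc <- filter_cells(sim$counts, 200, 0.2)
  norm <- normalize_counts(qc$filtered)
  emb <- pca_embed(norm, d = 10, n_hvg = 300)
  corr <- mnn_correct(emb, qc$filtered$cells$batch, k_mnn = 20)
  bsil <- function(coords, batch) {
    d <- as.matrix(dist(coords)); n <- nrow(d)
    mean(vapply(seq_len(n), function(i) {
      same <- batch == batch[i]; same[i] <- FALSE
      a <- mean(d[i, same]); b <- mean(d[i, !same & seq_len(n) != i])
      (b - a) / max(a, b)
    }, 1.0))
  }
  keep <- qc$filtered$cells$type == "type3"
  before <- bsil(emb$coords[keep, ], qc$filtered$cells$batch[keep])
  after <- bsil(corr$coords[keep, ], qc$filtered$cells$batch[keep])
  expect_lt(after, before)
})

test_that("SNN graph has Jaccard weights and respects geometry", {
  set.seed(5)
  X <- matrix(rnorm(20 * 3), 20, 3)
  g <- snn_graph(X, knn_k = 19)
  expect_equal(igraph::ecount(g), choose(20, 2))       # complete graph
  w <- igraph::E(g)$weight
  expect_true(all(w > 0 & w <= 1))
  # two well-separated blobs, small k: no cross edges
  blobs <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
                 matrix(rnorm(60, 50, 0.1), 30, 2))
  g2 <- snn_graph(blobs, knn_k = 5)
  el <- igraph::as_edgelist(g2, names = FALSE)
  expect_false(any((el[, 1] <= 30) != (el[, 2] <= 30)))
  expect_error(snn_graph(X, knn_k = 20), class = "config_error")
})

test_that("community detection separates components and is deterministic", {
  cl1 <- igraph::make_full_graph(10)
  cl2 <- igraph::make_full_graph(12)
  g <- igraph::disjoint_union(cl1, cl2)
  igraph::E(g)$weight <- 1
  for (method in c("leiden", "louvain")) {
    res <- cluster_graph(g, method, resolution = if (method == "leiden") 0.05 else 1,
                         seed = 4)
    expect_equal(length(unique(res$cluster)), 2)
    expect_equal(length(unique(res$cluster[1:10])), 1)
    expect_equal(min(res$cluster), 0)
    res2 <- cluster_graph(g, method, resolution = if (method == "leiden") 0.05 else 1,
                          seed = 4)
    expect_identical(res$cluster, res2$cluster)
  }
})

test_that("clustering the default cohort recovers the planted cell types", {
  sim <- simulate_reference_cohort(sim_config(seed = 7))
  qc <- filter_cells(sim$counts, 200, 0.2)
  norm <- normalize_counts(qc$filtered)
  emb <- pca_embed(norm, d = 20, n_hvg = 400)
  emb <- mnn_correct(emb, qc$filtered$cells$batch, k_mnn = 20)
  g <- snn_graph(emb, knn_k = 15)
  cl <- cluster_graph(g, "leiden", resolution = 0.005, seed = 1)
  expect_gte(ari(cl$cluster, qc$filtered$cells$type), 0.8)
  # MEN-like and NEN-like clusters get the right annotation
  rownames(norm) <- qc$filtered$genes$gene_symbol
  ann <- annotate_clusters(norm, cl$cluster)
  truth_lab <- tapply(qc$filtered$cells$lineage, cl$cluster, function(x)
    names(which.max(table(x))))
  map <- c("MEN-like" = "MEN", "NEN-like" = "NEN", "glia-like" = "neuroglia")
  for (i in seq_len(nrow(ann))) {
    expected <- map[truth_lab[as.character(ann$cluster[i])]]
    if (!is.na(expected)) expect_equal(ann$label[i], unname(expected))
  }
})

test_that("Welch statistics match the closed form", {
  w <- enspatterns:::welch_rows(mean(c(1, 2, 3)), var(c(1, 2, 3)), 3,
                                mean(c(4, 5, 6)), var(c(4, 5, 6)), 3)
  expect_equal(w$t, -3.6742, tolerance = 1e-4)
  expect_equal(w$df, 4, tolerance = 1e-10)
  expect_gt(w$p, 0.5)                        # one-sided "greater"
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), alternative = "greater")
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
})

test_that("marker detection ranks planted markers first", {
  set.seed(10)
  n <- 50
  base <- matrix(rnbinom(50 * 2 * n, mu = 5, size = 10), 50, 2 * n)
  cl <- rep(c(0, 1), each = n)
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    m <- base
    m[1, cl == 0] <- rnbinom(n, mu = 50, size = 10)   # 10x mean in cluster 0
    norm <- log10(m + 1)
    rownames(norm) <- paste0("g", 1:50)
    mk <- find_markers(norm, cl, top_n = 5)
    top <- mk[mk$cluster == 0 & mk$rank == 1, ]
    if (top$gene == "g1") hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("constant genes are never markers and BH matches the oracle", {
  set.seed(11)
  m <- matrix(rnorm(20 * 40, 5), 20, 40)
  m[7, ] <- 3                               # constant gene
  rownames(m) <- paste0("g", 1:20)
  cl <- rep(c(0, 1), each = 20)
  mk <- find_markers(m, cl, top_n = 3)
  g7 <- mk[mk$gene == "g7", ]
  expect_true(all(g7$combined_p == 1))
  expect_false(any(g7$is_marker))
  # BH within each cluster reproduces the step-up definition
  p10 <- c(0.003, 0.04, 0.2, 0.9, 0.01, 0.0001, 0.31, 0.5, 0.049, 0.07)
  expect_equal(p.adjust(p10, "BH"), bh_stepup(p10), tolerance = 1e-12)
  for (a in unique(mk$cluster)) {
    sub <- mk[mk$cluster == a, ]
    expect_equal(sub$bh_q, bh_stepup(sub$combined_p), tolerance = 1e-12)
  }
  expect_warning(find_markers(m, c(rep(0, 20), rep(1, 19), 2)), "singleton")
})

test_that("pseudo-R2 agrees with a direct penalized-likelihood oracle", {
  set.seed(12)
  x <- c(rnorm(10, 0), rnorm(10, 3))
  y <- rep(c(0, 1), each = 10)
  m <- rbind(x, rep(1, 20))
  rownames(m) <- c("sep", "const")
  r2 <- marker_score_pseudo_r2(m, y, lambda = 1e-4)
  expect_equal(r2$pseudo_r2[r2$gene == "const"], c(0, 0))
  # direct numerical maximization of the ridge-penalized likelihood
  oracle <- function(x, y, lambda) {
    nll <- function(b) {
      eta <- b[1] + b[2] * x
      sum(log(1 + exp(eta))) - sum(y * eta) + lambda * b[2]^2
    }
    fit <- optim(c(0, 0), nll, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-14))
    eta <- fit$par[1] + fit$par[2] * x
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    ll0 <- sum(y * log(mean(y)) + (1 - y) * log(1 - mean(y)))
    min(max(1 - ll / ll0, 0), 1)
  }
  got <- r2$pseudo_r2[r2$gene == "sep" & r2$cluster == 1]
  expect_equal(got, oracle(x, y, 1e-4), tolerance = 1e-4)
  # clean separation drives pseudo-R2 toward 1
  xs <- c(rep(0, 10), rep(10, 10))
  ms <- rbind(sep = xs)
  r2s <- marker_score_pseudo_r2(ms, y, lambda = 1e-4)
  expect_gte(max(r2s$pseudo_r2), 0.99)
  expect_error(marker_score_pseudo_r2(m, rep(0, 20)), class = "config_error")
})

test_that("signature annotation assigns disjoint signatures and abstains on noise", {
  set.seed(13)
  m <- matrix(rnorm(6 * 60, 1, 0.1), 6, 60)
  rownames(m) <- c("Ret", "Sox10", "Ncam1", "Calcb", "Met", "Cdh3")
  cl <- rep(0:2, each = 20)
  m[1, cl == 0] <- 5
  m[2:3, cl == 1] <- 5
  m[4:6, cl == 2] <- 5
  ann <- annotate_clusters(m, cl)
  expect_equal(ann$label, c("NEN", "neuroglia", "MEN"))
  flat <- matrix(1, 6, 60, dimnames = list(rownames(m), NULL))
  ann2 <- annotate_clusters(flat, cl)
  expect_true(all(ann2$label == "unassigned"))
  expect_error(annotate_clusters(m, cl, signatures = list()),
               class = "config_error")
})
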