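test_that("NNLS solves worked examples and satisfies KKT", {
  A <- matrix(c(1, 0, 1,
                0, 1, 1), nrow = 3)
  fit <- nnls_solve(A, c(1, 2, 3))
  expect_equal(fit$coef, c(1, 2), tolerance = 1e-10)
  expect_lt(fit$residual_ss, 1e-20)
  # active constraint: negative target forced to zero
  fit0 <- nnls_solve(matrix(1, 2, 1), c(-1, -1))
  expect_equal(fit0$coef, 0)
  # consistency: y in the cone is recovered exactly
  set.seed(1)
  for (i in 1:10) {
    Ar <- matrix(runif(40), 10, 4)
    p <- runif(4)
    fitc <- nnls_solve(Ar, Ar %*% p)
    expect_lt(max(abs(fitc$coef - p)), 1e-10)
  }
})

test_that("NNLS agrees with exhaustive support enumeration", {
  set.seed(2)
  worst <- 0
  for (i in 1:200) {
    m <- sample(2:6, 1)
    n <- sample(4:12, 1)
    A <- matrix(rnorm(n * m), n, m)
    y <- rnorm(n)
    got <- nnls_solve(A, y)$coef
    want <- nnls_bruteforce(A, y)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-8)
})

test_that("projection is scale-equivariant and reports R2", {
  set.seed(3)
  A <- matrix(runif(60), 20, 3)
  y <- A %*% c(1, 2, 0.5) + rnorm(20, 0, 0.01)
  p1 <- project_patterns(y, A)
  p4 <- project_patterns(4 * y, A)
  expect_equal(4 * p1$weights, p4$weights, tolerance = 1e-8)
  expect_gt(p1$r2[1], 0.99)
  # OLS mode matches lm on full-rank problems
  pols <- project_patterns(y, A, nonneg = FALSE)
  ref <- unname(coef(lm(y ~ A - 1)))
  expect_equal(as.numeric(pols$weights), ref, tolerance = 1e-10)
  # rank-deficient OLS falls back to minimum norm with a warning
  Ad <- cbind(A[, 1], A[, 1])
  expect_warning(project_patterns(y, Ad, nonneg = FALSE), "rank-deficient")
  expect_error(project_patterns(y[1:10, , drop = FALSE], A),
               class = "feature_match_error")
})

test_that("feature matching is case-insensitive and honors ortholog maps", {
  mf <- match_features(c("A", "B", "C"), c("b", "c", "d"),
                       min_match_frac = 0.5)
  expect_equal(mf$ref_gene, c("B", "C"))
  expect_equal(mf$target_index, c(1, 2))
  map <- tibble::tibble(from = c("HGNC1", "HGNC2", "HGNC3", "AMBIG", "AMBIG"),
                        to = c("Calcb", "Met", "Cdh3", "X1", "X2"))
  expect_warning(
    mf2 <- match_features(c("Calcb", "Met", "Cdh3"),
                          c("HGNC1", "HGNC2", "HGNC3", "AMBIG"),
                          ortholog_map = map, min_match_frac = 0.5),
    "ambiguous")
  expect_equal(nrow(mf2), 3)
  expect_error(match_features(c("A", "B"), c("X", "Y")),
               class = "feature_match_error")
  expect_error(match_features(character(0), "A"), class = "config_error")
})

test_that("clustering on projection weights separates generating programs", {
  set.seed(4)
  W <- cbind(matrix(c(5, 0.2), 2, 60) + matrix(runif(120, 0, 0.3), 2),
             matrix(c(0.2, 5), 2, 60) + matrix(runif(120, 0, 0.3), 2))
  rownames(W) <- c("p1", "p2")
  cl <- cluster_on_projection(W, knn_k = 10, resolution = 5e-4, seed = 2)
  truth <- rep(c(1, 2), each = 60)
  expect_gte(ari(cl$cluster, truth), 0.9)
  cl2 <- cluster_on_projection(W, knn_k = 10, resolution = 5e-4, seed = 2)
  expect_identical(cl$cluster, cl2$cluster)
  # all-equal weights collapse to one community
  We <- matrix(1, 2, 50, dimnames = list(c("p1", "p2"), NULL))
  cle <- cluster_on_projection(We, knn_k = 5, resolution = 5e-4, seed = 1)
  expect_equal(length(unique(cle$cluster)), 1)
})

test_that("per-sample aggregation is exact and order-invariant", {
  W <- matrix(c(1, 10,
                3, 30,
                5, 50,
                7, 70), nrow = 2)
  rownames(W) <- c("p1", "p2")
  ids <- c("s1", "s1", "s2", "s2")
  agg <- aggregate_by_sample(W, ids)
  expect_equal(agg$mean_weight[agg$sample == "s1" & agg$pattern == "p1"], 2)
  expect_equal(agg$mean_weight[agg$sample == "s2" & agg$pattern == "p2"], 60)
  expect_equal(unique(agg$n_cells), 2)
  perm <- c(3, 1, 4, 2)
  agg2 <- aggregate_by_sample(W[, perm], ids[perm])
  expect_equal(agg, agg2)
  # single cell per sample: mean equals the cell's weight
  agg1 <- aggregate_by_sample(W[, 1, drop = FALSE], "solo")
  expect_equal(agg1$mean_weight, c(1, 10))
})

test_that("age groups follow the inclusive range definitions", {
  expect_equal(assign_age_group(c(10, 25, 65)),
               c("Juvenile", "Adult", "Aged"))
  expect_equal(assign_age_group(15), "unassigned")
  expect_equal(assign_age_group(12), "Juvenile")
  expect_equal(assign_age_group(c(4, 20, 50, 60, 75)),
               c("Juvenile", "Adult", "Adult", "Aged", "Aged"))
  expect_error(assign_age_group(-1), class = "config_error")
})

test_that("differential usage reproduces textbook statistics", {
  sw <- tibble::tibble(
    sample = rep(paste0("s", 1:9), each = 1),
    pattern = "p1",
    mean_weight = c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  )
  grp <- setNames(rep(c("g1", "g2", "g3"), each = 3), paste0("s", 1:9))
  res <- differential_usage(sw, grp)
  expect_equal(res$statistic, 21, tolerance = 1e-10)       # SSB 42 / SSW 6
  expect_equal(c(res$df1, res$df2), c(2, 6))
  expect_equal(res$test, "anova")
  # two-group Student t, pooled variance
  sw2 <- tibble::tibble(sample = paste0("s", 1:6), pattern = "p1",
                        mean_weight = c(1, 2, 3, 4, 5, 6))
  grp2 <- setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6))
  res2 <- differential_usage(sw2, grp2)
  expect_equal(res2$statistic, -3.6742, tolerance = 1e-4)
  expect_equal(res2$df1, 4)
  # identical groups: F = 0, p = 1
  sw3 <- tibble::tibble(sample = paste0("s", 1:9), pattern = "p1",
                        mean_weight = rep(5, 9))
  res3 <- differential_usage(sw3, grp)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p, 1)
  expect_error(differential_usage(sw2, setNames(c("a", "a", "a", "a", "a", "b"),
                                                paste0("s", 1:6))),
               class = "config_error")
})
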