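# Shared fixtures: small cohorts built once per test run.

small_config <- function(seed = 7, ...) {
  sim_config(seed = seed, cells_per_sample = 120, ...)
}

# Reference cohort without batch effects, used where batch correction is
# not the property under test.
ref_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_reference_cohort(
        sim_config(seed = 7, cells_per_sample = 200, batch_effect_sd = 0))
    }
    cache
  }
})

ref_norm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      qc <- filter_cells(ref_cohort()$counts, 200, 0.2)
      cache <<- list(qc = qc, norm = normalize_counts(qc$filtered))
    }
    cache
  }
})

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Brute-force NNLS oracle: enumerate all 2^m supports, solve the
# unconstrained least squares on each support, keep feasible solutions
# and return the one with the smallest residual.
nnls_bruteforce <- function(A, y) {
  m <- ncol(A)
  best <- rep(0, m); best_rss <- sum(y^2)
  for (mask in seq_len(2^m) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    if (!length(idx)) next
    Ai <- A[, idx, drop = FALSE]
    b <- tryCatch(qr.solve(Ai, y), error = function(e) NULL)
    if (is.null(b) || any(b < 0)) next
    rss <- sum((y - Ai %*% b)^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- rep(0, m); best[idx] <- b
    }
  }
  best
}

# Definitional Benjamini-Hochberg step-up oracle.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# O(n^2) pairwise-sum Fisher-Lee circular correlation oracle.
circ_cor_pairwise <- function(a, b) {
  n <- length(a)
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + sin(a[i] - a[j]) * sin(b[i] - b[j])
    da <- da + sin(a[i] - a[j])^2
    db <- db + sin(b[i] - b[j])^2
  }
  num / sqrt(da * db)
}
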