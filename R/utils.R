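#' @importFrom rlang %||% abort warn .data
#' @importFrom stats aov coef cor dist hclust lm median optim p.adjust
#'   pbinom prcomp predict pt qlogis quantile rbeta rbinom rgamma rlnorm
#'   rmultinom rnbinom rnorm rpois runif sd setNames smooth.spline splinefun
#'   t.test var weighted.mean
#' @importFrom utils head modifyList
NULL

# Deterministic child seed for a named stochastic sub-operation of a master
# seed: modular hash of the op name folded into the seed, kept < 2^31.
child_seed <- function(seed, op) {
  stopifnot(is.character(op), length(op) == 1L)
  h <- 0
  for (ch in utf8ToInt(op)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

with_child_seed <- function(seed, op, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(child_seed(seed, op))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Fisher-Lee circular correlation between two angle vectors
#'
#' Rotation-invariant correlation for angular data; a reflection of one
#' vector flips its sign. Computed with the O(n) expansion of the pairwise
#' double sum.
#'
#' @param a,b Numeric vectors of angles in radians, same length.
#' @return A correlation in \[-1, 1\].
#' @export
circular_cor <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  n <- length(a)
  sa <- sin(a); ca <- cos(a); sb <- sin(b); cb <- cos(b)
  # sum_{ij} sin(ai-aj) sin(bi-bj) expands into products of aggregate sums
  num <- sum(sa * sb) * sum(ca * cb) - sum(sa * cb) * sum(ca * sb) -
    sum(cb * sa) * sum(sb * ca) + sum(ca * cb) * sum(sa * sb)
  den_a <- (n^2 - (sum(cos(2 * a))^2 + sum(sin(2 * a))^2)) / 2
  den_b <- (n^2 - (sum(cos(2 * b))^2 + sum(sin(2 * b))^2)) / 2
  if (den_a <= 0 || den_b <= 0) return(NA_real_)
  num / sqrt(den_a * den_b)
}

#' Shortest angular distance on the circle
#' @param a,b Angles in radians.
#' @return Elementwise distances in \[0, pi\].
#' @export
circ_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

# Rank-based AUROC of a score vector against a binary label
# (Mann-Whitney formulation); ties handled by midranks.
auroc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimal one-to-one matching of estimated to true pattern columns
#'
#' Matches columns of `A_hat` to columns of `A_true` by maximizing total
#' cosine similarity over assignments (exhaustive for k <= 8, the sizes
#' used here). Used to score pattern recovery against a known generator.
#'
#' @param A_hat Estimated genes x k' amplitude matrix (k' >= k).
#' @param A_true True genes x k amplitude matrix.
#' @return Tibble (true_pattern, matched, cosine).
#' @export
match_patterns <- function(A_hat, A_true) {
  k <- ncol(A_true)
  stopifnot(ncol(A_hat) >= k, k <= 8)
  cs <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(0)
    sum(x * y) / (nx * ny)
  }
  S <- outer(seq_len(ncol(A_hat)), seq_len(k),
             Vectorize(function(i, j) cs(A_hat[, i], A_true[, j])))
  perms <- all_perms(ncol(A_hat), k)
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    v <- sum(S[cbind(p, seq_len(k))])
    if (v > best_val) { best_val <- v; best <- p }
  }
  tibble::tibble(
    true_pattern = seq_len(k),
    matched = best,
    cosine = S[cbind(best, seq_len(k))]
  )
}

# All injections of 1..k into 1..n as a list of index vectors.
all_perms <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(n, k - 1L)) {
      if (!(i %in% rest)) out[[length(out) + 1L]] <- c(i, rest)
    }
  }
  out
}

# Geometric mean of strictly positive values.
geo_mean <- function(x) exp(mean(log(x)))

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

# Coerce base or Matrix input to a general dgCMatrix.
to_sparse <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(m, "CsparseMatrix")
  methods::as(m, "generalMatrix")
}
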