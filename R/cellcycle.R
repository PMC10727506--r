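#' Build a 2-D cell-cycle reference space
#'
#' PCA on the centered cell-cycle-gene submatrix of a reference cohort;
#' the first two principal components span the reference plane into which
#' new cells are projected. Component signs are fixed by a deterministic
#' convention (largest-magnitude loading positive); the absolute angular
#' origin of the plane is a gauge freedom — see [align_theta()].
#'
#' @param ref_norm Normalized genes x cells reference matrix with gene
#'   ids as rownames.
#' @param cc_genes Cell-cycle gene ids (>= 4 must be present; the
#'   reference analysis used 500 cell-cycle-correlated genes).
#' @return An object of class `cc_reference`: list with `loadings`
#'   (cc_genes x 2), `center`, `cc_genes`, `ref_coords`, `sdev`.
#' @export
build_cc_reference <- function(ref_norm, cc_genes) {
  m <- as_dense(ref_norm)
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  idx <- which(rn %in% cc_genes)
  if (length(idx) < 4) abort("need >= 4 matched cell-cycle genes", class = "config_error")
  if (ncol(m) < 10) abort("need >= 10 reference cells", class = "config_error")
  x <- t(m[idx, , drop = FALSE])             # cells x cc genes
  if (all(apply(x, 2, var) == 0)) {
    abort("constant-expression reference: zero variance", class = "config_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)
  L <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i_max <- which.max(abs(L[, j]))
    if (L[i_max, j] < 0) L[, j] <- -L[, j]
  }
  coords <- sweep(x, 2, pc$center) %*% L
  structure(list(loadings = L, center = pc$center,
                 cc_genes = rn[idx], ref_coords = coords,
                 sdev = pc$sdev[1:2]),
            class = "cc_reference")
}

#' Continuous cell-cycle position (theta)
#'
#' Projects each cell's centered cell-cycle-gene profile into the 2-D
#' reference space and measures theta as the angle from the origin
#' (`atan2(e2, e1) mod 2pi`). Cells with zero expression across the
#' matched cell-cycle genes are flagged low-confidence.
#'
#' @param norm Normalized genes x cells matrix.
#' @param reference A [build_cc_reference()] object (>= 4 genes matched).
#' @return Tibble (barcode, e1, e2, theta, cycling, low_confidence).
#' @export
cc_position <- function(norm, reference) {
  stopifnot(inherits(reference, "cc_reference"))
  m <- as_dense(norm)
  rn <- rownames(m) %||% as.character(seq_len(nrow(m)))
  idx <- match(reference$cc_genes, rn)
  ok <- !is.na(idx)
  if (sum(ok) < 4) abort("fewer than 4 cell-cycle genes matched", class = "config_error")
  x <- t(m[idx[ok], , drop = FALSE])
  e <- sweep(x, 2, reference$center[ok]) %*% reference$loadings[ok, , drop = FALSE]
  theta <- atan2(e[, 2], e[, 1]) %% (2 * pi)
  tibble::tibble(
    barcode = colnames(m) %||% as.character(seq_len(ncol(m))),
    e1 = e[, 1], e2 = e[, 2],
    theta = theta,
    cycling = classify_cycling(theta),
    low_confidence = rowSums(x) == 0
  )
}

#' Binarize theta into cycling / non-cycling
#'
#' Cycling iff theta lies in the half-open arc \[0.5pi, 1.5pi) — the S
#' through G2M stretch of the reference plane; the boundary values belong
#' to "cycling". The complementary arc (G1/G0) is non-cycling.
#'
#' @param theta Angles in \[0, 2pi).
#' @return Logical vector.
#' @export
classify_cycling <- function(theta) {
  theta >= 0.5 * pi & theta < 1.5 * pi
}

#' Align estimated positions to a reference set of angles
#'
#' The absolute origin (rotation) and handedness (reflection) of a PCA
#' cell-cycle plane are not identified by the data; this helper estimates
#' the rotation (circular mean of the differences) and, if it improves
#' the circular correlation, a reflection, returning aligned angles.
#'
#' @param theta Estimated angles.
#' @param theta_ref Reference angles (e.g. from anchor cells).
#' @return List with `theta` (aligned), `rotation`, `reflected`.
#' @export
align_theta <- function(theta, theta_ref) {
  ok <- !is.na(theta) & !is.na(theta_ref)
  fit_one <- function(th) {
    d <- theta_ref[ok] - th[ok]
    rot <- atan2(mean(sin(d)), mean(cos(d)))
    aligned <- (th + rot) %% (2 * pi)
    list(aligned = aligned, rot = rot,
         score = mean(cos(theta_ref[ok] - aligned[ok])))
  }
  direct <- fit_one(theta)
  mirrored <- fit_one((-theta) %% (2 * pi))
  if (mirrored$score > direct$score) {
    list(theta = mirrored$aligned, rotation = mirrored$rot, reflected = TRUE)
  } else {
    list(theta = direct$aligned, rotation = direct$rot, reflected = FALSE)
  }
}

#' Periodic loess smoothing of expression over theta
#'
#' Local linear regression with tricube weights on the circular distance
#' `min(|dtheta|, 2pi - |dtheta|)`, evaluated on a regular angular grid;
#' the fit wraps at 0/2pi. Used to display expression dynamics of
#' cell-cycle genes over the cell cycle.
#'
#' @param theta Angles in \[0, 2pi).
#' @param y Response values (one per angle).
#' @param span Fraction of points in each local window, in (0, 1].
#' @param grid_n Grid resolution.
#' @return Tibble (theta, fitted).
#' @export
periodic_loess <- function(theta, y, span = 0.3, grid_n = 100) {
  stopifnot(length(theta) == length(y))
  if (length(theta) < 10) abort("need >= 10 points", class = "config_error")
  if (span <= 0 || span > 1) abort("span must be in (0, 1]", class = "config_error")
  if (length(unique(theta)) == 1) {
    abort("all theta identical: no angular spread to smooth over",
          class = "config_error")
  }
  n <- length(theta)
  k <- max(4L, ceiling(span * n))
  grid <- seq(0, 2 * pi, length.out = grid_n + 1)[seq_len(grid_n)]
  fitted <- vapply(grid, function(t0) {
    d <- circ_dist(theta, t0)
    h <- sort(d)[k]
    if (h == 0) h <- max(d[d > 0], 1e-8)
    w <- (1 - pmin(d / h, 1)^3)^3
    use <- w > 0
    # signed angular offset in (-pi, pi] for the local linear term
    delta <- atan2(sin(theta - t0), cos(theta - t0))
    df <- data.frame(y = y[use], delta = delta[use], w = w[use])
    fit <- lm(y ~ delta, data = df, weights = w)
    unname(coef(fit)[1])
  }, numeric(1))
  tibble::tibble(theta = grid, fitted = fitted)
}

#' Cycling-cell summary for a subset
#'
#' @param positions A [cc_position()] tibble.
#' @param subset Logical mask or barcode vector; default all cells.
#' @return Tibble (n_cycling, n_total, fraction).
#' @export
cycling_summary <- function(positions, subset = NULL) {
  keep <- if (is.null(subset)) rep(TRUE, nrow(positions))
  else if (is.logical(subset)) subset
  else positions$barcode %in% subset
  if (!any(keep)) abort("subset is empty", class = "config_error")
  cyc <- positions$cycling[keep]
  tibble::tibble(n_cycling = sum(cyc), n_total = length(cyc),
                 fraction = mean(cyc))
}
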