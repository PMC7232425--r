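#' Bray-Curtis dissimilarity between stations
#'
#' `d(a, b) = sum |a_j - b_j| / sum (a_j + b_j)`, computed with
#' \code{vegan::vegdist}.  The distance between two all-zero stations is
#' undefined under this formula and is set to 0 with a warning.
#'
#' @param x stations x features matrix of nonnegative values.
#' @return a `dist` object with values in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  x <- as_feature_matrix(x)
  check_nonnegative(x)
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (anyNA(d)) {
    warning("all-zero station pair(s): Bray-Curtis distance set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Embeds a distance matrix via Gower double-centering of -d^2/2 and
#' eigendecomposition (through \code{stats::cmdscale}).  Coordinates are
#' eigenvector times sqrt(eigenvalue) for the positive eigenvalues; negative
#' eigenvalues (possible for semi-metric dissimilarities such as
#' Bray-Curtis) are counted and reported, not corrected.  Axis signs are
#' fixed by forcing the largest-magnitude coordinate of each axis positive,
#' so runs are reproducible.
#'
#' @param d a `dist` or a symmetric, zero-diagonal, nonnegative matrix.
#' @return object of class `ordination`: `coordinates` (stations x positive
#'   axes), `eigenvalues` (all, descending), `proportion_explained` (over
#'   positive eigenvalues), `method = "pcoa"`, `n_negative_eig`.
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("asymmetric distance matrix")
  if (any(diag(m) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(m < 0)) stop("distance matrix must be nonnegative")
  n <- nrow(m)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m),
                                          k = max(n - 1, 1), eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig), 0) * 1e-8 + 1e-12
  npos <- sum(eig > tol)
  coords <- fit$points[, seq_len(min(npos, ncol(fit$points))), drop = FALSE]
  coords <- fix_axis_signs(coords)
  rownames(coords) <- rownames(m)
  if (npos > 0) colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  prop <- if (npos > 0) eig[seq_len(npos)] / sum(eig[seq_len(npos)]) else numeric(0)
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = prop,
                 method = "pcoa",
                 n_negative_eig = sum(eig < -tol)),
            class = "ordination")
}

#' Principal component analysis of environmental covariates
#'
#' Transforms the selected columns as `log10(x + 1)`, scales each column by
#' its maximum, then runs a covariance PCA (Euclidean geometry) via
#' \code{stats::prcomp}.  Columns that are constant after the transform are
#' dropped with a warning.  Axis signs are fixed by forcing the
#' largest-magnitude loading of each axis positive.
#'
#' @param covariates station covariate data.frame.
#' @param columns names of the columns to ordinate.
#' @return object of class `ordination` with `coordinates` (scores),
#'   `eigenvalues`, `proportion_explained`, `loadings`, `method = "pca"`.
#' @export
env_pca <- function(covariates, columns = env_covariate_names()) {
  missing_cov <- setdiff(columns, names(covariates))
  if (length(missing_cov))
    stop(sprintf("unknown covariate: '%s'", missing_cov[1]))
  x <- as.matrix(covariates[, columns, drop = FALSE])
  if (!is.numeric(x)) stop("selected columns must be numeric")
  if (any(x <= -1)) stop("log10(x + 1) requires values > -1")
  tx <- log10(x + 1)
  keep <- apply(tx, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(columns[!keep], collapse = ", ")))
    tx <- tx[, keep, drop = FALSE]
    if (ncol(tx) == 0) stop("no non-constant columns left")
  }
  tx <- sweep(tx, 2, apply(abs(tx), 2, max), "/")
  fit <- stats::prcomp(tx, center = TRUE, scale. = FALSE)
  eig <- fit$sdev^2
  tol <- max(eig) * 1e-12
  npos <- sum(eig > tol)
  scores <- fit$x[, seq_len(npos), drop = FALSE]
  load <- fit$rotation[, seq_len(npos), drop = FALSE]
  flip <- vapply(seq_len(npos), function(j) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(scores, 2, flip, "*")
  load <- sweep(load, 2, flip, "*")
  rownames(scores) <- if (!is.null(covariates$station_id))
    covariates$station_id else rownames(covariates)
  structure(list(coordinates = scores,
                 eigenvalues = eig,
                 proportion_explained = eig[seq_len(npos)] / sum(eig[seq_len(npos)]),
                 loadings = load,
                 method = "pca",
                 n_negative_eig = 0L),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d stations, %d axes retained\n",
              toupper(x$method), nrow(x$coordinates), ncol(x$coordinates)))
  if (length(x$proportion_explained))
    cat("Proportion explained (first axes):",
        paste0(round(100 * utils::head(x$proportion_explained, 4), 1), "%",
               collapse = ", "), "\n")
  if (x$n_negative_eig > 0)
    cat(sprintf("Negative eigenvalues: %d (reported, not corrected)\n",
                x$n_negative_eig))
  invisible(x)
}

#' @export
plot.ordination <- function(x, axes = c(1, 2), ...) {
  if (ncol(x$coordinates) < max(axes))
    stop("not enough axes to plot")
  graphics::plot(x$coordinates[, axes[1]], x$coordinates[, axes[2]],
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1],
                                100 * x$proportion_explained[axes[1]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2],
                                100 * x$proportion_explained[axes[2]]),
                 ...)
  invisible(x)
}

# force the largest-magnitude entry of each column positive
fix_axis_signs <- function(coords) {
  if (ncol(coords) == 0) return(coords)
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Expected richness under rarefaction
#'
#' Hypergeometric expectation of the number of distinct features observed in
#' a random subsample of `n` reads from one station:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, computed with
#' \code{vegan::rarefy} (numerically stable log-binomials).
#'
#' @param counts integer count vector for one station.
#' @param n subsample size, `0 <= n <= sum(counts)`.
#' @return expected richness (a single number).
#' @export
rarefaction_expected_richness <- function(counts, n) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  N <- sum(counts)
  if (length(n) != 1 || n < 0 || n != round(n))
    stop("n must be a single nonnegative integer")
  if (n > N)
    stop(sprintf("subsample size n = %d exceeds the total count N = %d", n, N))
  out <- suppressWarnings(vegan::rarefy(counts, sample = n))
  as.numeric(out)
}
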