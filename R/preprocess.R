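#' Quantile-normalize a feature table across stations
#'
#' Forces every station (row) to share one value distribution: the reference
#' distribution is the per-rank mean of the sorted rows, and each row's values
#' are replaced by the reference values at their ranks.  Ties within a row
#' receive the mean of the reference values their ranks span, so a constant
#' row maps to the mean of the whole reference vector.  Delegates to
#' \code{limma::normalizeQuantiles} (stations as arrays), the standard
#' implementation of this normalization for expression-type count tables.
#'
#' @param x stations x features matrix of nonnegative values.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as_feature_matrix(x)
  check_nonnegative(x)
  if (nrow(x) < 2) {
    warning("single-station table: quantile normalization is a no-op")
    return(x)
  }
  if (ncol(x) < 1) stop("every station row needs at least one feature")
  out <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  dimnames(out) <- dimnames(x)
  out
}

#' Hellinger transformation
#'
#' Square root of row relative abundance: `h_ij = sqrt(x_ij / sum_j x_ij)`.
#' Rows then have unit sum of squares, making Euclidean distances between
#' them appropriate for species/feature abundance data.  All-zero rows are
#' left all-zero.  Delegates to \code{vegan::decostand(method =
#' "hellinger")}.
#'
#' @param x stations x features matrix of nonnegative values.
#' @return transformed matrix, values in \[0, 1\].
#' @export
hellinger <- function(x) {
  x <- as_feature_matrix(x)
  if (any(x < 0)) stop("invalid input: Hellinger transform requires nonnegative values")
  out <- suppressWarnings(vegan::decostand(x, method = "hellinger", MARGIN = 1))
  out <- matrix(as.numeric(out), nrow(x), ncol(x), dimnames = dimnames(x))
  out[rowSums(x) == 0, ] <- 0
  out
}

#' Log transformation with pseudocount
#'
#' `y = log_base(x + pseudocount)`; the modeling-scale transform applied
#' before variance partitioning (log2 with pseudocount 1 by default, so a
#' zero count maps to 0 and additive covariate effects act multiplicatively
#' on counts).
#'
#' @param x stations x features matrix of nonnegative values.
#' @param base logarithm base, > 1 (default 2).
#' @param pseudocount positive offset added before the log (default 1).
#' @return transformed matrix.
#' @export
log_transform <- function(x, base = 2, pseudocount = 1) {
  x <- as_feature_matrix(x)
  check_nonnegative(x)
  if (!is.numeric(base) || base <= 1) stop("base must be > 1")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  log(x + pseudocount, base = base)
}
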