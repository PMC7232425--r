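#' Per-feature variance-fraction decomposition
#'
#' Fits, for every feature, an ordinary least squares model of transformed
#' abundance on the column-standardized covariates plus an intercept, and
#' decomposes the variance into per-covariate fractions
#' \deqn{v_c = \frac{\mathrm{Var}(\beta_c z_c)}
#'                 {\sum_k \mathrm{Var}(\beta_k z_k) + \mathrm{Var}(r)}}
#' plus a residual fraction over the same denominator.  Because covariates
#' are standardized, \eqn{\mathrm{Var}(\beta_c z_c) = \beta_c^2}.
#' Covariances between components are excluded from the denominator, so
#' fractions are nonnegative and every row sums to exactly 1 — the
#' invariants the dominant-driver rule in [attribute_dominant()] relies on.
#' With correlated covariates the fractions are therefore a rescaling of the
#' marginal component variances, not a unique decomposition of
#' \eqn{\mathrm{Var}(y)}; for mutually orthogonal covariates they equal the
#' marginal R-squared of each covariate.
#'
#' All features are fitted through a single QR decomposition of the shared
#' design matrix, so the fit is deterministic and fast for tables with
#' thousands of features.
#'
#' @param y stations x features matrix of transformed (e.g. log2) abundances.
#' @param covariates station covariate data.frame with a `station_id` column
#'   matching `rownames(y)`.
#' @param covariate_set character vector of covariate column names to model.
#' @return an object of class `variance_fractions`: list with `fractions`
#'   (features x (covariates + "residual"), rows summing to 1),
#'   `coefficients` (features x covariates, slopes on the standardized
#'   scale), `covariates`, `n_stations`.
#' @seealso [dual_taxon_models()], [attribute_dominant()]
#' @export
fit_variance_fractions <- function(y, covariates,
                                   covariate_set = env_covariate_names()) {
  y <- as_feature_matrix(y)
  covariates <- align_stations(covariates, y)
  n <- nrow(y)
  p <- length(covariate_set)
  if (p < 1) stop("covariate_set must name at least one covariate")
  missing_cov <- setdiff(covariate_set, names(covariates))
  if (length(missing_cov))
    stop(sprintf("unknown covariate: '%s'", missing_cov[1]))
  if (n < p + 2)
    stop(sprintf("too few stations: need at least %d for %d covariates, got %d",
                 p + 2, p, n))

  Zraw <- as.matrix(covariates[, covariate_set, drop = FALSE])
  if (!is.numeric(Zraw)) stop("covariates must be numeric columns")
  if (anyNA(Zraw)) stop("missing values among modeled covariates")
  sds <- apply(Zraw, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant covariate: '%s'", covariate_set[which(sds == 0)[1]]))
  Z <- scale(Zraw)

  X <- cbind(`(Intercept)` = 1, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design: modeled covariates are linearly dependent")

  B <- qr.coef(qrX, y)                       # (p + 1) x features
  res <- qr.resid(qrX, y)
  comp <- B[-1, , drop = FALSE]^2            # Var(beta_c z_c), sd(z_c) = 1
  resvar <- colSums(res^2) / (n - 1)
  denom <- colSums(comp) + resvar
  zero <- denom <= 0                         # constant feature: all residual
  denom[zero] <- 1

  fractions <- t(rbind(comp, residual = resvar) / rep(denom, each = p + 1))
  if (any(zero)) fractions[zero, ] <- rep(c(rep(0, p), 1), each = sum(zero))
  colnames(fractions) <- c(covariate_set, "residual")
  rownames(fractions) <- colnames(y)
  coefficients <- t(B[-1, , drop = FALSE])   # features x covariates
  dimnames(coefficients) <- list(colnames(y), covariate_set)

  structure(list(fractions = fractions,
                 coefficients = coefficients,
                 covariates = covariate_set,
                 n_stations = n,
                 call = match.call()),
            class = "variance_fractions")
}

#' @export
print.variance_fractions <- function(x, ...) {
  cat(sprintf("Variance-fraction decomposition: %d features, %d stations\n",
              nrow(x$fractions), x$n_stations))
  cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat("Mean fractions:\n")
  print(round(colMeans(x$fractions), 3))
  invisible(x)
}

#' @export
summary.variance_fractions <- function(object, ...) {
  fr <- object$fractions
  covs <- object$covariates
  dom <- attribute_dominant(object)
  out <- list(n_features = nrow(fr), n_stations = object$n_stations,
              covariates = covs,
              mean_fractions = colMeans(fr),
              n_dominant = table(factor(dom$driver,
                                        levels = c(covs, "unattributed"))))
  class(out) <- "summary.variance_fractions"
  out
}

#' @export
print.summary.variance_fractions <- function(x, ...) {
  cat(sprintf("Variance-fraction decomposition: %d features, %d stations\n",
              x$n_features, x$n_stations))
  cat("Mean fraction per component:\n")
  print(round(x$mean_fractions, 3))
  cat("Features per dominant driver (fraction > 0.5):\n")
  print(x$n_dominant)
  invisible(x)
}

#' @export
coef.variance_fractions <- function(object, ...) object$coefficients

#' @export
as.data.frame.variance_fractions <- function(x, ...) {
  fr <- as.data.frame(x$fractions)
  cf <- as.data.frame(x$coefficients)
  names(cf) <- paste0("coef_", names(cf))
  cbind(data.frame(feature_id = rownames(x$fractions),
                   stringsAsFactors = FALSE),
        fr, cf, row.names = NULL)
}

#' @export
plot.variance_fractions <- function(x, ...) {
  graphics::boxplot(x$fractions, las = 2,
                    ylab = "fraction of variance", ...)
  invisible(x)
}

#' Dual single-taxon variance-partition models
#'
#' When two taxon covariates are strongly (anti-)collinear — as
#' dinoflagellate and diatom relative abundances are in a community where
#' the two groups trade off — a joint fit cannot separate them.  Instead two
#' models are fitted, each combining the environmental covariates with one
#' taxon fraction, and their attributions are reconciled afterwards with
#' [venn_reconcile()].
#'
#' @param y stations x features matrix of transformed abundances.
#' @param covariates station covariate data.frame.
#' @param env_set environmental covariate names; must not contain the taxon
#'   columns.
#' @return list with elements `dino` and `diatom`, each a
#'   `variance_fractions` fit over `env_set` plus the respective taxon
#'   fraction.
#' @export
dual_taxon_models <- function(y, covariates,
                              env_set = env_covariate_names()) {
  if (any(.taxon_covariates %in% env_set))
    stop("env_set must not include the taxon fraction columns")
  list(dino = fit_variance_fractions(y, covariates, c(env_set, "dino_frac")),
       diatom = fit_variance_fractions(y, covariates, c(env_set, "diatom_frac")))
}
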