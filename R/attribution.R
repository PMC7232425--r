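#' Dominant-driver attribution
#'
#' Attributes a feature to covariate c if and only if c's variance fraction
#' strictly exceeds 0.5 — equivalently, exceeds the sum of the variances
#' explained by every other covariate plus the residual, since fractions sum
#' to 1.  The residual can never be a driver; a tie at exactly 0.5 leaves
#' the feature unattributed.  The association sign is the sign of the fitted
#' slope of the dominant covariate.
#'
#' @param vf a `variance_fractions` fit.
#' @param source_model label recorded with each attribution (e.g. `"env"`,
#'   `"dino"`, `"diatom"`), identifying which model the fractions came from.
#' @return data.frame of class `attribution_table` with columns
#'   `feature_id`, `driver` (covariate name or `"unattributed"`),
#'   `dominant_fraction` (largest covariate fraction), `sign` (+1/-1, 0 when
#'   unattributed) and `source_model`.
#' @export
attribute_dominant <- function(vf, source_model = "env") {
  stopifnot(inherits(vf, "variance_fractions"))
  fr <- vf$fractions
  covs <- vf$covariates
  frc <- fr[, covs, drop = FALSE]
  best_j <- max.col(frc, ties.method = "first")
  dom <- frc[cbind(seq_len(nrow(frc)), best_j)]
  best <- covs[best_j]
  attributed <- dom > 0.5
  driver <- ifelse(attributed, best, "unattributed")
  sgn <- integer(nrow(frc))
  sgn[attributed] <- sign(vf$coefficients[cbind(which(attributed),
                                                best_j[attributed])])
  out <- data.frame(feature_id = rownames(fr),
                    driver = driver,
                    dominant_fraction = dom,
                    sign = as.integer(sgn),
                    source_model = source_model,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("attribution_table", "data.frame")
  out
}

#' Reconcile environmental and dual-taxon attributions as a Venn summary
#'
#' Counts the features attributed to any environmental covariate in the
#' environmental model (`n_env`), to the dinoflagellate fraction in the
#' dinoflagellate model (`n_dino`), and to the diatom fraction in the diatom
#' model (`n_diatom`); `n_shared` is the intersection of the two taxon sets
#' and `n_taxon_total` their union, so the inclusion-exclusion identity
#' `n_taxon_total = n_dino + n_diatom - n_shared` holds by construction.  A
#' feature may appear in both the environmental and a taxon count; the
#' overlap is reported, not forced away.
#'
#' @param env_attr attribution from the environmental model.
#' @param dino_attr attribution from the dinoflagellate model.
#' @param diatom_attr attribution from the diatom model.
#' @return object of class `venn_summary`: list with `n_env`, `n_dino`,
#'   `n_diatom`, `n_shared`, `n_taxon_total`, plus the underlying feature-id
#'   sets in `sets`.
#' @export
venn_reconcile <- function(env_attr, dino_attr, diatom_attr) {
  ids <- env_attr$feature_id
  if (!setequal(ids, dino_attr$feature_id) ||
      !setequal(ids, diatom_attr$feature_id))
    stop("mismatched feature sets across the three attribution tables")

  env_set <- env_attr$feature_id[env_attr$driver != "unattributed"]
  dino_set <- dino_attr$feature_id[dino_attr$driver == "dino_frac"]
  diatom_set <- diatom_attr$feature_id[diatom_attr$driver == "diatom_frac"]
  shared <- intersect(dino_set, diatom_set)

  structure(list(n_env = length(env_set),
                 n_dino = length(dino_set),
                 n_diatom = length(diatom_set),
                 n_shared = length(shared),
                 n_taxon_total = length(union(dino_set, diatom_set)),
                 sets = list(env = env_set, dino = dino_set,
                             diatom = diatom_set)),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("Driver attribution Venn summary\n")
  cat(sprintf("  environment-attributed: %d\n", x$n_env))
  cat(sprintf("  dinoflagellate-attributed: %d\n", x$n_dino))
  cat(sprintf("  diatom-attributed: %d\n", x$n_diatom))
  cat(sprintf("  shared between taxa: %d\n", x$n_shared))
  cat(sprintf("  taxon-attributed total (union): %d\n", x$n_taxon_total))
  invisible(x)
}
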