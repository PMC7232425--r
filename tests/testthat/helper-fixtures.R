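# in-code fixtures shared across the suite

# small random station covariate table (not via the generator, so unit tests
# of the modeling stages do not depend on the synthetic module)
make_stations <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(station_id = sprintf("S%03d", seq_len(n)),
                   region = factor(rep_len(paste0("region_", 1:4), n)),
                   stringsAsFactors = FALSE)
  for (cv in env_covariate_names()) df[[cv]] <- runif(n, 1, 10)
  df$dino_frac <- runif(n, 0.05, 0.9)
  df$diatom_frac <- pmin(1 - df$dino_frac, runif(n, 0.05, 0.9))
  df
}

# station table whose covariate columns c1..cp are exactly orthogonal after
# centering and have unit sd (orthogonality survives the fit's standardization)
make_orthogonal_stations <- function(n, p, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n))))[, 2:(p + 1), drop = FALSE]
  Z <- scale(Q)
  df <- data.frame(station_id = sprintf("S%03d", seq_len(n)),
                   region = rep_len(c("a", "b"), n),
                   stringsAsFactors = FALSE)
  for (j in seq_len(p)) df[[paste0("c", j)]] <- Z[, j]
  list(stations = df, Z = Z)
}

# feature matrix with dimnames
make_counts <- function(n, f, seed = 1, lambda = 50) {
  set.seed(seed)
  matrix(rpois(n * f, lambda), n, f,
         dimnames = list(sprintf("S%03d", seq_len(n)),
                         sprintf("F%05d", seq_len(f))))
}

# attribution table realizing prescribed driver assignments
make_attr <- function(feature_id, driver, source_model = "env") {
  out <- data.frame(feature_id = feature_id, driver = driver,
                    dominant_fraction = ifelse(driver == "unattributed", 0.4, 0.8),
                    sign = ifelse(driver == "unattributed", 0L, 1L),
                    source_model = source_model, stringsAsFactors = FALSE)
  class(out) <- c("attribution_table", "data.frame")
  out
}

# variance_fractions object built directly from a fraction matrix
make_vf <- function(fractions, coefficients = NULL) {
  covs <- setdiff(colnames(fractions), "residual")
  if (is.null(coefficients)) {
    coefficients <- matrix(1, nrow(fractions), length(covs),
                           dimnames = list(rownames(fractions), covs))
  }
  structure(list(fractions = fractions, coefficients = coefficients,
                 covariates = covs, n_stations = NA_integer_,
                 call = NULL),
            class = "variance_fractions")
}

# the three attribution tables used by the worked Venn example: set sizes
# follow from the requested dino/diatom/overlap counts
make_venn_inputs <- function(n_dino, n_diatom, n_shared, n_extra = 5) {
  n_total <- n_dino + n_diatom - n_shared + n_extra
  ids <- sprintf("PF%05d", seq_len(n_total))
  dino_set <- ids[seq_len(n_dino)]
  diatom_set <- ids[seq(n_dino - n_shared + 1, n_dino - n_shared + n_diatom)]
  list(env = make_attr(ids, "unattributed"),
       dino = make_attr(ids, ifelse(ids %in% dino_set, "dino_frac",
                                    "unattributed"), "dino"),
       diatom = make_attr(ids, ifelse(ids %in% diatom_set, "diatom_frac",
                                      "unattributed"), "diatom"))
}
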