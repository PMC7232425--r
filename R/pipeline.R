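#' Configure an end-to-end pipeline run
#'
#' Inputs may be given as file paths (TSV, read with the package readers) or
#' as in-memory objects; alternatively `simulate` may carry a
#' [generator_config()] so the run starts from synthetic data.
#'
#' @param features stations x features count matrix, or a TSV path.
#' @param stations station covariate data.frame, or a TSV path.
#' @param mapping optional Pfam-to-KO mapping data.frame or TSV path.
#' @param simulate optional [generator_config()]; used when `features` /
#'   `stations` are NULL.
#' @param env_covariates environmental covariate names for the
#'   environmental model (the taxon fractions are modeled separately).
#' @param n_perm permutations for the regional significance test.
#' @param alpha uncorrected significance level.
#' @param seed top-level seed; per-stage seeds are derived from it.
#' @param out_dir optional output directory; when set, every intermediate
#'   table is written as TSV and the summary as JSON.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(features = NULL, stations = NULL, mapping = NULL,
                            simulate = NULL,
                            env_covariates = env_covariate_names(),
                            n_perm = 1000L, alpha = 0.05, seed = 1L,
                            out_dir = NULL) {
  if (is.null(simulate) && (is.null(features) || is.null(stations)))
    stop("either 'features' and 'stations' or a 'simulate' generator_config is required")
  structure(list(features = features, stations = stations, mapping = mapping,
                 simulate = simulate, env_covariates = env_covariates,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a flat YAML pipeline configuration
#'
#' Recognized keys mirror the [pipeline_config()] arguments
#' (`features`, `stations`, `mapping` as paths; `env_covariates` as a list
#' or comma-separated string; `n_perm`, `alpha`, `seed`, `out_dir`).
#'
#' @param path YAML file path.
#' @return object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("features", "stations", "mapping")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop(sprintf("config file '%s': %s path '%s' does not exist",
                   path, key, cfg[[key]]))
  }
  env <- cfg$env_covariates
  if (is.character(env) && length(env) == 1)
    env <- trimws(strsplit(env, ",")[[1]])
  pipeline_config(features = cfg$features, stations = cfg$stations,
                  mapping = cfg$mapping,
                  env_covariates = if (is.null(env)) env_covariate_names() else env,
                  n_perm = if (is.null(cfg$n_perm)) 1000L else cfg$n_perm,
                  alpha = if (is.null(cfg$alpha)) 0.05 else cfg$alpha,
                  seed = if (is.null(cfg$seed)) 1L else cfg$seed,
                  out_dir = cfg$out_dir)
}

#' Run the full driver-attribution pipeline
#'
#' Stages, in order: load or simulate inputs; quantile-normalize and
#' log2-transform the feature table; fit the environmental
#' variance-partition model and the two single-taxon models; apply the
#' dominant-driver rule to each; reconcile the taxon attributions as a Venn
#' summary; run the region permutation test; ordinate (Hellinger +
#' Bray-Curtis PCoA of the features, PCA of the environmental covariates);
#' aggregate to KO and export signed associations when a mapping is
#' provided.  Any stage failure aborts with the stage name prepended.
#' Identical config + seed reproduces every output.
#'
#' @param config a [pipeline_config()].
#' @return object of class `run_report` (all stage outputs plus summary
#'   counts and provenance).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_community(config$simulate))
    features <- sim$features; stations <- sim$stations; truth <- sim$truth
  } else {
    features <- stage("load", if (is.character(config$features))
      read_feature_table(config$features) else as_feature_matrix(config$features))
    stations <- stage("load", if (is.character(config$stations))
      read_station_table(config$stations) else config$stations)
  }
  mapping <- if (is.character(config$mapping))
    stage("load", read_pfam_ko_map(config$mapping)) else config$mapping

  env_set <- config$env_covariates
  bad <- setdiff(env_set, names(stations))
  if (length(bad))
    stop(sprintf("pipeline stage 'validate' failed: unknown covariate '%s'",
                 bad[1]), call. = FALSE)

  norm <- stage("preprocess", quantile_normalize(features))
  ylog <- stage("preprocess", log_transform(norm))

  fit_env <- stage("variance_partition",
                   fit_variance_fractions(ylog, stations, env_set))
  dual <- stage("variance_partition",
                dual_taxon_models(ylog, stations, env_set))

  attr_env <- stage("attribution", attribute_dominant(fit_env, "env"))
  attr_dino <- stage("attribution", attribute_dominant(dual$dino, "dino"))
  attr_diatom <- stage("attribution", attribute_dominant(dual$diatom, "diatom"))
  venn <- stage("attribution", venn_reconcile(attr_env, attr_dino, attr_diatom))

  perm <- stage("permutation",
                region_permutation_test(ylog, stations$region,
                                        n_perm = config$n_perm,
                                        seed = config$seed + 1000L,
                                        alpha = config$alpha))

  hel <- stage("ordination", hellinger(norm))
  pcoa_fit <- stage("ordination", pcoa(bray_curtis(hel)))
  pca_fit <- stage("ordination", env_pca(stations, env_set))

  ko <- pa <- NULL
  signed <- list()
  if (!is.null(mapping)) {
    ko <- stage("aggregation", aggregate_to_ko(norm, mapping))
    pa <- stage("aggregation",
                presence_absence_profile(ko, stations$region))
    for (drv in setdiff(unique(attr_env$driver), "unattributed"))
      signed[[drv]] <- stage("aggregation",
                             signed_driver_export(attr_env, mapping, drv))
  }

  env_counts <- table(factor(attr_env$driver,
                             levels = c(env_set, "unattributed")))
  report <- structure(list(
    venn = venn,
    n_env_attributed = as.list(env_counts),
    n_significant = sum(perm$table$significant),
    alpha_corrected = perm$alpha_corrected,
    ko_coverage_percent = if (!is.null(ko))
      coverage_percent(attr(ko, "n_pfam_mapped"), attr(ko, "n_pfam_total"))
      else NA,
    pcoa_proportion = utils::head(pcoa_fit$proportion_explained, 2),
    pca_proportion = utils::head(pca_fit$proportion_explained, 2),
    provenance = list(seed = config$seed, n_perm = config$n_perm,
                      alpha = config$alpha,
                      env_covariates = env_set,
                      package_version = as.character(utils::packageVersion("funcpart")),
                      config_hash = config_hash(config)),
    stages = list(normalized = norm, log2 = ylog,
                  fit_env = fit_env, dual = dual,
                  attr_env = attr_env, attr_dino = attr_dino,
                  attr_diatom = attr_diatom,
                  perm = perm, pcoa = pcoa_fit, pca = pca_fit,
                  ko = ko, presence_absence = pa, signed = signed,
                  stations = stations, features = features, truth = truth)),
    class = "run_report")

  if (!is.null(config$out_dir)) write_run_outputs(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("funcpart pipeline report\n")
  print(x$venn)
  cat("Environment-model attributions:\n")
  cnt <- unlist(x$n_env_attributed)
  print(cnt[cnt > 0])
  cat(sprintf("Regionally significant features: %d (alpha_corrected = %.3g)\n",
              x$n_significant, x$alpha_corrected))
  if (!is.na(x$ko_coverage_percent))
    cat(sprintf("Domains mapped to KO: %d%%\n", x$ko_coverage_percent))
  cat(sprintf("PCoA axes 1-2: %s of positive-eigenvalue variance\n",
              paste0(round(100 * x$pcoa_proportion, 1), "%", collapse = " + ")))
  cat(sprintf("Seed: %d; config hash: %s\n",
              x$provenance$seed, x$provenance$config_hash))
  invisible(x)
}

# write every intermediate table plus the JSON summary into out_dir
write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- report$stages
  write_feature_table(st$normalized, file.path(out_dir, "features_normalized.tsv"))
  write_station_table(st$stations, file.path(out_dir, "stations.tsv"))
  utils::write.table(as.data.frame(st$fit_env),
                     file.path(out_dir, "fractions_env.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(st$dual$dino),
                     file.path(out_dir, "fractions_dino.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(st$dual$diatom),
                     file.path(out_dir, "fractions_diatom.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  attribution <- rbind(st$attr_env, st$attr_dino, st$attr_diatom)
  utils::write.table(attribution, file.path(out_dir, "attribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(st$perm$table, file.path(out_dir, "ptable.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(station_id = rownames(st$pcoa$coordinates),
                                st$pcoa$coordinates, check.names = FALSE),
                     file.path(out_dir, "pcoa_coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(st$truth))
    utils::write.table(st$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  venn <- report$venn
  jsonlite::write_json(venn[c("n_env", "n_dino", "n_diatom", "n_shared",
                              "n_taxon_total")],
                       file.path(out_dir, "venn.json"), auto_unbox = TRUE)
  summary_out <- report[c("n_env_attributed", "n_significant",
                          "alpha_corrected", "ko_coverage_percent",
                          "pcoa_proportion", "pca_proportion", "provenance")]
  summary_out$venn <- venn[c("n_env", "n_dino", "n_diatom", "n_shared",
                             "n_taxon_total")]
  jsonlite::write_json(summary_out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

# small stable rolling hash of the config (timestamps never enter)
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
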