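#' Configure the synthetic community generator
#'
#' Builds a validated configuration for [generate_covariates()] and
#' [generate_feature_table()].  The generator emulates a small multi-region
#' plankton survey: stations in contiguous regional blocks, abiotic
#' covariates drawn uniformly on oceanographically plausible ranges plus a
#' region-level offset, and dinoflagellate/diatom relative abundances built
#' from a latent bivariate normal with correlation `rho_taxa` pushed through
#' a softmax, so that a strong negative latent correlation yields strongly
#' anti-correlated fractions.  Feature abundances follow a linear-Gaussian
#' model on the log2 scale with a planted driver per feature at a chosen
#' signal fraction — exactly the structure the variance-fraction model
#' estimates, so parameter recovery is meaningful.
#'
#' @param n_stations number of stations (default 20).
#' @param n_regions number of regions, at most `n_stations` (default 4).
#' @param rho_taxa latent correlation between the dinoflagellate and diatom
#'   generators, in \[-1, 1\] (default -0.8: strongly anti-correlated taxa).
#' @param driver_plan data.frame with columns `driver` (a covariate name, a
#'   taxon fraction name, or `"none"`), `n` (feature count) and `s` (signal
#'   fraction in \[0, 1)).  Defaults to [default_driver_plan()].
#' @param n_features total number of features; must equal `sum(driver_plan$n)`
#'   (defaults to that sum).
#' @param baseline_log2_mean intercept of the log2-abundance model (default 8,
#'   i.e. around 256 counts for a null feature).
#' @param noise_sd residual standard deviation on the log2 scale (default 1).
#' @param region_offset_frac region-level covariate offset scale, as a
#'   fraction of each covariate's uniform range (default 0.1).
#' @param count_model `"round"` (deterministic `round(2^y)`, the default; keeps
#'   the planted signal fraction interpretable) or `"poisson"`
#'   (`rpois(2^y)` sampling layer).
#' @param seed integer seed; identical config + seed reproduces all outputs
#'   bit for bit.
#' @return an object of class `generator_config`.
#' @seealso [simulate_community()] for the one-call generator.
#' @export
generator_config <- function(n_stations = 20L, n_regions = 4L,
                             rho_taxa = -0.8, driver_plan = NULL,
                             n_features = NULL, baseline_log2_mean = 8,
                             noise_sd = 1, region_offset_frac = 0.1,
                             count_model = c("round", "poisson"),
                             seed = 1L) {
  count_model <- match.arg(count_model)
  if (is.null(driver_plan)) driver_plan <- default_driver_plan()
  driver_plan <- as.data.frame(driver_plan, stringsAsFactors = FALSE)
  if (!all(c("driver", "n", "s") %in% names(driver_plan)))
    stop("driver_plan needs columns 'driver', 'n', 's'")
  if (is.null(n_features)) n_features <- sum(driver_plan$n)

  if (!is.numeric(n_stations) || n_stations < 1)
    stop("invalid parameter: n_stations must be a positive integer")
  if (!is.numeric(n_regions) || n_regions < 1 || n_regions > n_stations)
    stop("invalid parameter: n_regions must be in [1, n_stations]")
  if (!is.numeric(rho_taxa) || rho_taxa < -1 || rho_taxa > 1)
    stop("invalid parameter: rho_taxa must lie in [-1, 1]")
  if (sum(driver_plan$n) != n_features)
    stop("invalid parameter: driver_plan feature counts must sum to n_features")
  if (any(driver_plan$n < 0) || any(driver_plan$n != round(driver_plan$n)))
    stop("invalid parameter: driver_plan counts must be nonnegative integers")
  if (any(driver_plan$s < 0) || any(driver_plan$s >= 1))
    stop("invalid parameter: signal fraction s must lie in [0, 1); s = 1 implies an infinite effect size")
  ok <- c(.env_covariates, .taxon_covariates, "none")
  bad <- setdiff(driver_plan$driver, ok)
  if (length(bad))
    stop(sprintf("invalid parameter: unknown driver '%s' in driver_plan", bad[1]))
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("invalid parameter: noise_sd must be positive")

  structure(list(n_stations = as.integer(n_stations),
                 n_regions = as.integer(n_regions),
                 rho_taxa = rho_taxa,
                 n_features = as.integer(n_features),
                 driver_plan = driver_plan,
                 baseline_log2_mean = baseline_log2_mean,
                 noise_sd = noise_sd,
                 region_offset_frac = region_offset_frac,
                 count_model = count_model,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default planted-driver plan
#'
#' 100 features at signal fraction 0.6 and 100 at 0.8 for each of the eight
#' modeled covariates (six abiotic plus the two taxon fractions), plus 400
#' undriven features: 2000 features in total.
#'
#' @return a data.frame with columns `driver`, `n`, `s`.
#' @export
default_driver_plan <- function() {
  drivers <- c(.env_covariates, .taxon_covariates)
  rbind(
    data.frame(driver = rep(drivers, each = 2),
               n = 100L,
               s = rep(c(0.6, 0.8), times = length(drivers)),
               stringsAsFactors = FALSE),
    data.frame(driver = "none", n = 400L, s = 0, stringsAsFactors = FALSE)
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic community generator configuration\n")
  cat(sprintf("  stations: %d in %d regions; rho_taxa = %.2f; seed = %d\n",
              x$n_stations, x$n_regions, x$rho_taxa, x$seed))
  cat(sprintf("  features: %d (%d driven, %d null); noise sd = %.2f (log2)\n",
              x$n_features,
              sum(x$driver_plan$n[x$driver_plan$driver != "none"]),
              sum(x$driver_plan$n[x$driver_plan$driver == "none"]),
              x$noise_sd))
  invisible(x)
}

# uniform ranges for the abiotic covariates (temperature deg C, salinity PSU,
# nutrients and chlorophyll-a in the units the survey reports)
.covariate_ranges <- list(temperature   = c(3, 18),
                          salinity      = c(24, 35),
                          total_nitrogen = c(0, 5),
                          phosphate     = c(0, 5),
                          silicate      = c(0, 5),
                          chlorophyll_a = c(0, 10))

#' Generate station covariates
#'
#' Assigns stations to regions in contiguous near-equal blocks, draws each
#' abiotic covariate uniformly on its range plus a region-level normal offset
#' (sd = `region_offset_frac` of the range), and derives dinoflagellate,
#' diatom and "other" relative abundances by normalizing the exponentials of
#' three latent standard normals, the first two correlated at `rho_taxa`.
#' The emitted fractions lie in (0, 1) and sum to 1 with the implicit
#' "other" component.
#'
#' @param config a [generator_config()].
#' @return data.frame with columns `station_id`, `region`, the six abiotic
#'   covariates, `dino_frac`, `diatom_frac`.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_stations
  R <- config$n_regions

  sizes <- rep(n %/% R, R)
  if (n %% R) sizes[seq_len(n %% R)] <- sizes[seq_len(n %% R)] + 1L
  region <- factor(rep(sprintf("region_%d", seq_len(R)), times = sizes))

  out <- data.frame(station_id = sprintf("S%03d", seq_len(n)),
                    region = region, stringsAsFactors = FALSE)
  for (cv in names(.covariate_ranges)) {
    rg <- .covariate_ranges[[cv]]
    offs <- stats::rnorm(R, 0, config$region_offset_frac * diff(rg))
    val <- stats::runif(n, rg[1], rg[2]) + offs[as.integer(region)]
    if (rg[1] >= 0) val <- pmax(val, 0)  # concentrations cannot go negative
    out[[cv]] <- val
  }

  rho <- config$rho_taxa
  g1 <- stats::rnorm(n)
  g2 <- rho * g1 + sqrt(1 - rho^2) * stats::rnorm(n)
  g3 <- stats::rnorm(n)
  e <- exp(cbind(g1, g2, g3))
  fr <- e / rowSums(e)
  out$dino_frac <- fr[, 1]
  out$diatom_frac <- fr[, 2]
  out
}

#' Generate a feature table with planted drivers
#'
#' For a feature with planted driver c and signal fraction s, log2 abundance
#' is `y = baseline + beta * z_c + eps` with `z_c` the column-standardized
#' driver, `eps ~ N(0, noise_sd^2)` and
#' `beta = sign * noise_sd * sqrt(s / (1 - s))`, so that the population
#' variance fraction `Var(beta z) / (Var(beta z) + noise_sd^2)` equals s.
#' Undriven features use beta = 0.  Counts are `round(2^y)` clipped at zero
#' (or `rpois(2^y)` when `count_model = "poisson"`).  Effect signs are drawn
#' uniformly from \{-1, +1\} per driven feature and recorded in the truth
#' table (0 for undriven features).
#'
#' @param covariates output of [generate_covariates()] for the same config.
#' @param config a [generator_config()].
#' @return list with `features` (stations x features count matrix) and
#'   `truth` (data.frame `feature_id`, `driver`, `signal_fraction`, `sign`;
#'   the seed is attached as attribute `seed`).
#' @export
generate_feature_table <- function(covariates, config) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(covariates) != config$n_stations)
    stop("covariates are inconsistent with config: wrong number of stations")
  set.seed(config$seed + 1L)

  plan <- config$driver_plan
  driver <- rep(plan$driver, times = plan$n)
  s <- rep(plan$s, times = plan$n)
  if (any(s >= 1)) stop("invalid parameter: signal fraction s = 1 implies an infinite effect size")
  nf <- length(driver)
  n <- config$n_stations
  feature_id <- sprintf("F%05d", seq_len(nf))

  used <- unique(driver[driver != "none"])
  z <- matrix(0, n, 1, dimnames = list(NULL, ".none"))
  if (length(used)) {
    z <- scale(as.matrix(covariates[, used, drop = FALSE]))
    z <- cbind(z, .none = 0)
  }
  sgn <- ifelse(driver == "none", 0L, sample(c(-1L, 1L), nf, replace = TRUE))
  beta <- sgn * config$noise_sd * sqrt(s / (1 - s))
  col <- ifelse(driver == "none", ".none", driver)

  signal <- z[, col, drop = FALSE] * rep(beta, each = n)
  y <- config$baseline_log2_mean + signal +
    matrix(stats::rnorm(n * nf, 0, config$noise_sd), n, nf)
  counts <- switch(config$count_model,
                   round = pmax(round(2^y), 0),
                   poisson = matrix(stats::rpois(n * nf, 2^y), n, nf))
  dimnames(counts) <- list(covariates$station_id, feature_id)

  truth <- data.frame(feature_id = feature_id, driver = driver,
                      signal_fraction = s, sign = sgn,
                      stringsAsFactors = FALSE)
  attr(truth, "seed") <- config$seed
  list(features = counts, truth = truth)
}

#' Simulate a full synthetic community
#'
#' Convenience wrapper running [generate_covariates()] then
#' [generate_feature_table()].
#'
#' @param config a [generator_config()].
#' @return list with `stations`, `features`, `truth`, `config`.
#' @export
simulate_community <- function(config = generator_config()) {
  stations <- generate_covariates(config)
  ft <- generate_feature_table(stations, config)
  list(stations = stations, features = ft$features, truth = ft$truth,
       config = config)
}
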