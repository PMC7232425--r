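test_that("noiseless single covariate takes the whole variance", {
  st <- make_stations(12, seed = 1)
  y <- matrix(scale(st$temperature), ncol = 1,
              dimnames = list(st$station_id, "F1"))
  fit <- fit_variance_fractions(y, st, "temperature")
  expect_equal(unname(fit$fractions[1, "temperature"]), 1, tolerance = 1e-9)
  expect_equal(unname(fit$fractions[1, "residual"]), 0, tolerance = 1e-9)
})

test_that("orthogonal symmetric case splits 0.5 / 0.5 / 0", {
  o <- make_orthogonal_stations(20, 2, seed = 2)
  y <- matrix(o$Z[, 1] + o$Z[, 2], ncol = 1,
              dimnames = list(o$stations$station_id, "F1"))
  fit <- fit_variance_fractions(y, o$stations, c("c1", "c2"))
  expect_equal(unname(fit$fractions[1, c("c1", "c2", "residual")]),
               c(0.5, 0.5, 0), tolerance = 1e-9)
})

test_that("fractions match the closed-form normal-equation oracle", {
  # fixed 6-station, 2-covariate table; oracle solves the normal equations
  # explicitly, independent of the QR fitting path
  st <- data.frame(station_id = paste0("S", 1:6),
                   region = rep(c("a", "b"), 3),
                   c1 = c(1, 4, 2, 8, 5, 7),
                   c2 = c(10, 3, 6, 1, 9, 2),
                   stringsAsFactors = FALSE)
  y <- matrix(c(2.0, 5.5, 3.0, 9.0, 6.5, 8.0), ncol = 1,
              dimnames = list(st$station_id, "F1"))
  fit <- fit_variance_fractions(y, st, c("c1", "c2"))

  Z <- scale(cbind(st$c1, st$c2))
  X <- cbind(1, Z)
  beta <- solve(t(X) %*% X, t(X) %*% y)          # closed form
  comp <- beta[2:3]^2 * apply(Z, 2, var)
  resvar <- sum((y - X %*% beta)^2) / 5          # residual variance, n - 1
  denom <- sum(comp) + resvar
  expect_equal(unname(fit$fractions[1, c("c1", "c2", "residual")]),
               unname(c(comp, resvar) / denom), tolerance = 1e-9)
  expect_equal(unname(coef(fit)[1, ]), unname(beta[2:3]), tolerance = 1e-9)
})

test_that("degenerate designs raise named errors", {
  st <- make_stations(10)
  st$flat <- 5
  y <- make_counts(10, 3)
  expect_error(fit_variance_fractions(y, st, c("temperature", "flat")),
               "constant covariate: 'flat'")
  st$dup <- 2 * st$temperature + 1
  expect_error(fit_variance_fractions(y, st, c("temperature", "dup")),
               "rank-deficient")
  expect_error(fit_variance_fractions(make_counts(5, 2), make_stations(5),
                                      env_covariate_names()),
               "too few stations")
  expect_error(fit_variance_fractions(y, st, "oxygen"), "oxygen")
})

test_that("rows sum to one, fractions are nonnegative, scaling is irrelevant", {
  st <- make_stations(25, seed = 5)
  y <- log_transform(make_counts(25, 40, seed = 6))
  fit <- fit_variance_fractions(y, st)
  expect_true(all(fit$fractions >= 0))
  expect_equal(unname(rowSums(fit$fractions)), rep(1, 40), tolerance = 1e-9)

  st2 <- st
  st2$temperature <- st$temperature * 1000   # positive rescaling
  fit2 <- fit_variance_fractions(y, st2)
  expect_equal(fit$fractions, fit2$fractions, tolerance = 1e-9)
})

test_that("orthogonal covariate fractions equal marginal R-squared", {
  for (seed in 1:3) {
    o <- make_orthogonal_stations(30, 3, seed = seed)
    set.seed(seed + 100)
    y <- matrix(0.8 * o$Z[, 1] - 0.5 * o$Z[, 2] + 0.3 * o$Z[, 3] + rnorm(30),
                ncol = 1, dimnames = list(o$stations$station_id, "F1"))
    fit <- fit_variance_fractions(y, o$stations, c("c1", "c2", "c3"))
    for (j in 1:3) {
      marginal <- summary(lm(y ~ o$Z[, j]))$r.squared
      expect_equal(unname(fit$fractions[1, paste0("c", j)]), marginal,
                   tolerance = 1e-6)
    }
  }
})

test_that("estimated driver fraction increases with the planted signal", {
  fracs <- vapply(c(0.2, 0.5, 0.8), function(s) {
    sim <- simulate_community(generator_config(n_stations = 40, seed = 77,
      driver_plan = data.frame(driver = c("temperature", "none"),
                               n = c(40, 10), s = c(s, 0))))
    fit <- fit_variance_fractions(log_transform(sim$features), sim$stations)
    mean(fit$fractions[sim$truth$driver == "temperature", "temperature"])
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("dual single-taxon models resolve a perfectly collinear pair", {
  st <- make_stations(30, seed = 9)
  st$diatom_frac <- 1 - st$dino_frac        # perfect collinearity
  zd <- as.vector(scale(st$dino_frac))
  y <- matrix(zd, ncol = 1, dimnames = list(st$station_id, "F1"))
  dual <- dual_taxon_models(y, st)
  expect_gt(dual$dino$fractions[1, "dino_frac"], 0.5)
  expect_gt(dual$diatom$fractions[1, "diatom_frac"], 0.5)
  expect_error(dual_taxon_models(y, st, c("temperature", "dino_frac")),
               "taxon")
})

test_that("dual models agree on noise and on environment-driven features", {
  st <- make_stations(40, seed = 10)
  set.seed(11)
  noise <- matrix(rnorm(40 * 50), 40, 50,
                  dimnames = list(st$station_id, sprintf("N%02d", 1:50)))
  dual <- dual_taxon_models(noise, st)
  resid_dom <- function(fit)
    apply(fit$fractions, 1, function(r) names(which.max(r))) == "residual"
  expect_gte(mean(resid_dom(dual$dino) & resid_dom(dual$diatom)), 0.9)

  zt <- as.vector(scale(st$temperature))
  yt <- matrix(3 * zt + 0.3 * rnorm(40), ncol = 1,   # temperature, strong
               dimnames = list(st$station_id, "F1"))
  dual_t <- dual_taxon_models(yt, st)
  for (fit in dual_t) {
    fr <- fit$fractions[1, setdiff(colnames(fit$fractions), "residual")]
    expect_equal(names(which.max(fr)), "temperature")
    expect_gt(max(fr), 0.5)
  }
})
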