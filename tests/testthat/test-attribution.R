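# Shared fixture: smooth driver fields with a dominant radiation effect.
att_fixture <- function(seed = 5, nr = 30, nc = 30,
                        weights = c(radiation = 0.8, temperature = 0.15,
                                    precipitation = 0.1, soil_moisture = 0.15,
                                    vpd = 0.2),
                        noise_sd = 0.1) {
  cfg <- sim_config(n_rows = nr, n_cols = nc, seed = seed)
  drv <- simulate_drivers(cfg, driver_spec(weights = weights,
                                           noise_sd = noise_sd))
  build_feature_table(drv$covariates, drv$response, seed = seed)
}

test_that("feature table samples, scales and splits reproducibly", {
  x <- matrix(rnorm(10000 * 3), 10000, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(10000)
  tb <- build_feature_table(as.data.frame(x), y, train_frac = 0.6, seed = 2)
  expect_equal(sum(tb$split == "train"), 6000)
  expect_equal(sum(tb$split == "valid"), 4000)
  expect_true(all(abs(colMeans(tb$x)) < 1e-9))
  expect_true(all(abs(apply(tb$x, 2, sd) - 1) < 1e-9))
  tb2 <- build_feature_table(as.data.frame(x), y, train_frac = 0.6, seed = 2)
  expect_identical(tb$split, tb2$split)
  # constant predictor retained with a warning
  x2 <- cbind(x, k = 1)
  expect_warning(tbc <- build_feature_table(as.data.frame(x2), y, seed = 1),
                 "constant")
  expect_identical(tbc$constant, "k")
  expect_true(all(tbc$x[, "k"] == 0))
  # down-sampling respects the cap
  tb3 <- build_feature_table(as.data.frame(x), y, max_samples = 500, seed = 3)
  expect_equal(nrow(tb3$x), 500)
})

# the reference default configuration, spelled out independently of the
# package internals so a regression in the defaults is caught
default_gbt_params_exposed <- function()
  list(learning_rate = 0.05, max_depth = 8L, n_estimators = 500L)

test_that("model fit recovers strong signal and rejects pure noise", {
  tb <- att_fixture(seed = 7, weights = c(radiation = 1, temperature = 0),
                    noise_sd = 0)
  mod <- fit_stability_model(tb)
  expect_gt(mod$r2_valid, 0.95)
  expect_equal(mod$params, default_gbt_params_exposed())
  # pure noise: validation R^2 near zero
  cfg <- sim_config(n_rows = 25, n_cols = 25, seed = 8)
  drv <- simulate_drivers(cfg, driver_spec())
  set.seed(99)
  noise <- matrix(rnorm(625), 25, 25)
  tbn <- build_feature_table(drv$covariates, noise, seed = 8)
  modn <- fit_stability_model(tbn)
  expect_lt(modn$r2_valid, 0.1)
})

test_that("grid search is reproducible and honors the tie-break", {
  tb <- att_fixture(seed = 9, nr = 16, nc = 16)
  grid <- data.frame(learning_rate = c(0.1, 0.1),
                     max_depth = c(4L, 4L),
                     n_estimators = c(100L, 150L))
  m1 <- fit_stability_model(tb, grid = grid, seed = 4)
  m2 <- fit_stability_model(tb, grid = grid, seed = 4)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$cv_results), 2)
  expect_true(all(c("learning_rate", "max_depth", "n_estimators", "rmse")
                  %in% names(m1$cv_results)))
})

test_that("Shapley values satisfy local accuracy and sum-to-100 importance", {
  tb <- att_fixture(seed = 10, nr = 20, nc = 20)
  mod <- fit_stability_model(tb)
  att <- shapley_attribution(mod, tb, max_samples = 300, seed = 1)
  pred <- predict(mod, att$x)
  expect_lt(max(abs(rowSums(att$shap) + att$base_value - pred)), 1e-6)
  expect_equal(sum(att$importance), 100, tolerance = 0.01)
  expect_true(all(att$importance >= 0))
  expect_equal(sum(att$category_importance), 100, tolerance = 0.01)
})

test_that("dominant driver ranks first and constant features score zero", {
  tb <- att_fixture(seed = 11)
  mod <- fit_stability_model(tb)
  att <- shapley_attribution(mod, tb, max_samples = 400, seed = 1)
  expect_identical(names(which.max(att$importance)), "radiation")
  # constant feature cannot be split on: zero importance
  x <- matrix(rnorm(3000), 1000, 3, dimnames = list(NULL, c("a", "b", "k")))
  x[, "k"] <- 5
  y <- x[, "a"] + rnorm(1000, 0, 0.1)
  suppressWarnings(tbk <- build_feature_table(as.data.frame(x), y, seed = 3))
  modk <- fit_stability_model(tbk, grid = data.frame(
    learning_rate = 0.1, max_depth = 4L, n_estimators = 100L), seed = 1)
  attk <- shapley_attribution(modk, tbk, seed = 1)
  expect_equal(unname(attk$importance["k"]), 0)
})

test_that("permuting feature columns permutes importances identically", {
  set.seed(12)
  x <- matrix(rnorm(2000 * 4), 2000, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- 1.5 * x[, "a"] - x[, "c"] + 0.5 * x[, "d"] + rnorm(2000, 0, 0.1)
  perm <- c(3, 1, 4, 2)
  grid <- data.frame(learning_rate = 0.1, max_depth = 4L, n_estimators = 150L)
  imps <- lapply(list(x, x[, perm]), function(xx) {
    tb <- build_feature_table(as.data.frame(xx), y, seed = 5)
    m <- fit_stability_model(tb, grid = grid, seed = 5)
    shapley_attribution(m, tb, max_samples = 500, seed = 5)$importance
  })
  # exact invariance is broken only by exactly-tied split gains at tiny
  # leaves (tie-break is by feature index); the effect is < 1% of a share
  expect_equal(imps[[1]][sort(names(imps[[1]]))],
               imps[[2]][sort(names(imps[[2]]))], tolerance = 0.02)
})

test_that("equal true weights give near-symmetric importances", {
  set.seed(13)
  n <- 4000
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- rowSums(x) + rnorm(n, 0, 0.2)
  tb <- build_feature_table(as.data.frame(x), y, seed = 6)
  mod <- fit_stability_model(tb, grid = data.frame(
    learning_rate = 0.1, max_depth = 4L, n_estimators = 200L), seed = 6)
  att <- shapley_attribution(mod, tb, max_samples = 1000, seed = 6)
  expect_lt(max(abs(att$importance - 25)) / 25, 0.15)
})

test_that("dependence curves capture monotone, bump and null shapes", {
  set.seed(14)
  n <- 3000
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f", "g", "h")))
  y <- 2 * x[, "f"] + exp(-x[, "g"]^2) * 2   # linear + bump; h unused
  tb <- build_feature_table(as.data.frame(x), y, seed = 7)
  mod <- fit_stability_model(tb, grid = data.frame(
    learning_rate = 0.1, max_depth = 4L, n_estimators = 300L), seed = 7)
  att <- shapley_attribution(mod, tb, max_samples = 1500, seed = 7)
  dep_f <- dependence_export(att, "f", bins = 10)
  expect_identical(attr(dep_f, "monotone"), "increasing")
  dep_g <- dependence_export(att, "g", bins = 10)
  imax <- which.max(dep_g$mean_shap)
  expect_true(imax > 1 && imax < nrow(dep_g))   # interior maximum
  dep_h <- dependence_export(att, "h", bins = 10)
  expect_lt(max(abs(dep_h$mean_shap)), 0.1)
  expect_error(dependence_export(att, "zzz"), "unknown")
  expect_error(dependence_export(att, "f", bins = 1), "bins")
})
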