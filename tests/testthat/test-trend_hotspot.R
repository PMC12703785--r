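test_that("theil_sen matches the all-pairs-median oracle", {
  t <- 1:10
  expect_equal(theil_sen(2 * t + 1), 2)
  expect_equal(theil_sen(c(1, 2, 4)), 1.5)   # pairwise slopes {1, 1.5, 2}
  expect_equal(theil_sen(rep(3, 8)), 0)
  expect_true(is.na(theil_sen(c(NA, 1))))
  set.seed(5)
  for (k in 1:100) {
    y <- rnorm(sample(3:25, 1))
    expect_equal(theil_sen(y), theil_sen_oracle(y), tolerance = 1e-12)
  }
})

test_that("theil_sen is shift invariant and scale equivariant", {
  set.seed(11)
  for (k in 1:30) {
    y <- rnorm(15)
    a <- rnorm(1); b <- runif(1, -3, 3)
    expect_equal(theil_sen(a + b * y), b * theil_sen(y), tolerance = 1e-10)
  }
})

test_that("mann_kendall_p behaves on monotone, reversed and short input", {
  expect_lt(mann_kendall_p(1:20 + 0.01 * rnorm(20)), 0.001)
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(mann_kendall_p(y), mann_kendall_p(rev(y)))  # antisymmetry
  expect_equal(mk_s_sign <- sign(vegstab:::mk_s(y)),
               -sign(vegstab:::mk_s(rev(y))))
  expect_true(is.na(mann_kendall_p(c(1, 2, 3))))
  expect_equal(mann_kendall_p(rep(1, 10)), 1)  # all ties
})

test_that("trend_map flags rising persistence and passes invalid through", {
  # persistence ramp: phi growing 0.2 -> 0.8 over time; windowed AR trends up
  set.seed(17)
  ny <- 40; npx <- 64
  phis <- seq(0.2, 0.8, length.out = ny)
  e <- matrix(0, npx, ny)
  e[, 1] <- rnorm(npx, 0, 0.05)
  for (tt in 2:ny)
    e[, tt] <- phis[tt] * e[, tt - 1] + rnorm(npx, 0, 0.05 * sqrt(1 - phis[tt]^2))
  st <- raster_stack(array(0.5 + e, c(8, 8, ny)), years = 1:ny)
  ws <- moving_window_metrics(st, 15)
  tm <- trend_map(ws, "ar", p_method = "mk")
  expect_gt(median(tm$slope, na.rm = TRUE), 0)
  # all-invalid input gives all-invalid output
  vals <- array(NA_real_, c(3, 3, 20))
  ws0 <- moving_window_metrics(raster_stack(vals, years = 1:20), 15)
  tm0 <- trend_map(ws0, "pv", p_method = "mk")
  expect_true(all(is.na(tm0$slope)))
  expect_true(all(tm0$direction == 0L))
})

test_that("composite_index applies exclusion, normalization and labels", {
  dar <- make_trend_map(matrix(c(2, 1, -1, 0), 2, 2), metric = "ar")
  dpv <- make_trend_map(matrix(c(4, -2, -2, 3), 2, 2), metric = "pv")
  cm <- composite_index(dar, dpv)
  # pixel (2,1): +1 vs -2 -> opposing, excluded
  expect_true(cm$excluded[2, 1])
  expect_true(is.na(cm$value[2, 1]))
  expect_equal(cm$label[2, 1], 0L)
  # pixel (1,1) holds both max |slopes| among retained -> exactly +2
  expect_equal(cm$value[1, 1], 2)
  expect_equal(cm$label[1, 1], 1L)   # hotspot
  # pixel (1,2): both negative -> coldspot
  expect_lt(cm$value[1, 2], 0)
  expect_equal(cm$label[1, 2], 2L)
  # pixel (2,2): zero slope is non-opposing, retained
  expect_false(cm$excluded[2, 2])
  expect_true(is.finite(cm$value[2, 2]))
  # all-excluded input warns, does not error
  expect_warning(
    composite_index(make_trend_map(matrix(1, 2, 2)),
                    make_trend_map(matrix(-1, 2, 2))),
    "excluded")
})

test_that("composite values stay in [-2, 2] across random sign patterns", {
  set.seed(23)
  for (k in 1:20) {
    a <- matrix(rnorm(100), 10, 10)
    v <- matrix(rnorm(100), 10, 10)
    cm <- composite_index(make_trend_map(a), make_trend_map(v))
    expect_true(all(abs(cm$value[!is.na(cm$value)]) <= 2 + 1e-12))
    hot <- cm$label == 1L
    expect_true(all(a[hot] >= 0 & v[hot] >= 0))
    cold <- cm$label == 2L
    expect_true(all(a[cold] <= 0 & v[cold] <= 0))
    expect_true(all(cm$excluded == (sign(a) * sign(v) < 0)))
  }
})

test_that("morans_i matches the double-loop oracle and ape on small grids", {
  set.seed(3)
  for (k in 1:5) {
    lay <- matrix(rnorm(64), 8, 8)
    got <- morans_i(lay, n_perm = 9)$I
    expect_equal(got, moran_oracle(lay), tolerance = 1e-12)
  }
  # independent implementation: ape::Moran.I with the same weight matrix
  lay <- matrix(rnorm(36), 6, 6)
  w <- matrix(0, 36, 36)
  rc <- expand.grid(r = 1:6, c = 1:6)
  for (i in 1:36) for (j in 1:36)
    if (sum(abs(rc[i, ] - rc[j, ])) == 1) w[i, j] <- 1
  w <- w / rowSums(w)
  expect_equal(morans_i(lay, n_perm = 9)$I,
               unname(ape::Moran.I(as.vector(lay), w, scaled = FALSE)$observed),
               tolerance = 1e-10)
})

test_that("morans_i sign and significance behave on known patterns", {
  # perfect checkerboard: strong negative autocorrelation
  chk <- matrix(rep_len(c(0, 1), 100), 10, 10)
  chk <- abs(outer(1:10, 1:10, "+") %% 2)
  mi <- morans_i(chk, n_perm = 99, seed = 2)
  expect_lt(mi$I, -0.9)
  # iid noise: I close to -1/(N-1)
  set.seed(4)
  ok <- replicate(20, {
    m <- morans_i(matrix(rnorm(400), 20, 20), n_perm = 9)
    abs(m$I - m$expected) < 0.05
  })
  expect_gte(mean(ok), 0.9)
  # smooth two-block gradient: clustered, significant
  grad <- outer(seq(0, 1, length.out = 12), seq(0, 1, length.out = 12), "+")
  mg <- morans_i(grad, n_perm = 199, seed = 5)
  expect_gt(mg$I, 0.5)
  expect_lt(mg$p_value, 0.01)
  expect_error(morans_i(matrix(1, 5, 5)), "constant")
})

test_that("ecosystem_state maps EF x ES onto the five states", {
  ef_slope <- matrix(c(0.01, -0.01, 0.01, 0.01), 2, 2)
  ef_p <- matrix(c(0.001, 0.001, 0.5, 0.001), 2, 2)
  ef <- make_trend_map(ef_slope, ef_p, metric = "annual")
  es_val <- matrix(c(-1.2, 1.0, -0.5, NA), 2, 2)
  es <- structure(list(value = es_val,
                       excluded = matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2),
                       label = matrix(0L, 2, 2), norm = c(ar = 1, pv = 1)),
                  class = "composite_map")
  sm <- ecosystem_state(ef, es)
  expect_equal(sm$code[1, 1], 1L)  # EF up, ES improving -> ideal
  expect_equal(sm$code[2, 1], 4L)  # EF down, ES degrading -> abysmal
  expect_equal(sm$code[1, 2], 5L)  # EF not significant -> unknown
  expect_equal(sm$code[2, 2], 5L)  # ES excluded -> unknown
  expect_error(ecosystem_state(ef, structure(list(value = matrix(0, 3, 3),
                                                  excluded = matrix(FALSE, 3, 3)),
                                             class = "composite_map")),
               "grids differ")
})
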