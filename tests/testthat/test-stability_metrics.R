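test_that("proportional variability matches hand-computed cases", {
  expect_identical(proportional_variability(c(5, 5, 5, 5)), 0)
  expect_equal(proportional_variability(c(1, 3)), 0.5)       # |1-3|/(1+3)
  # brute-force oracle: (1/3 + 1/2 + 1/5) / 3
  expect_equal(proportional_variability(c(1, 2, 3)), pv_oracle(c(1, 2, 3)))
  expect_equal(proportional_variability(c(1, 2, 3)), 0.3444444,
               tolerance = 1e-6)
  expect_true(is.na(proportional_variability(c(1, -1, 2))))  # pair sum <= 0
  expect_true(is.na(proportional_variability(3)))            # n < 2
})

test_that("PV equals the O(n^2) oracle and is scale invariant", {
  set.seed(7)
  for (rep in 1:50) {
    x <- runif(sample(3:40, 1), 0.1, 2)
    p <- proportional_variability(x)
    expect_equal(p, pv_oracle(x), tolerance = 1e-12)
    expect_equal(proportional_variability(x * runif(1, 0.01, 100)), p,
                 tolerance = 1e-12)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("lag-1 autocorrelation matches direct evaluation and is bounded", {
  x <- c(1, -1, 1, -1, 1, -1)
  expect_equal(lag1_autocorrelation(x), -5 / 6)   # numerator -5, denominator 6
  expect_equal(lag1_autocorrelation(x), ar_oracle(x))
  expect_true(is.na(lag1_autocorrelation(rep(2, 10))))  # flagged, not 0
  set.seed(1)
  reps <- replicate(100, abs(lag1_autocorrelation(rnorm(5000))) < 0.05)
  expect_gte(mean(reps), 0.95)
  for (k in 1:200) {
    a <- lag1_autocorrelation(rnorm(sample(3:50, 1)))
    expect_lte(abs(a), 1)
  }
})

test_that("stability_map recovers ordering in persistence and noise", {
  zm <- matrix(rep(1:2, each = 200), 20, 20)
  cfg <- sim_config(n_years = 40, n_rows = 20, n_cols = 20, seed = 5,
                    zone_map = zm,
                    zones = data.frame(zone = 1:2, phi = c(0.1, 0.7)))
  sm <- stability_map(simulate_stack(cfg))
  expect_lt(mean(sm$ar[zm == 1 & sm$valid]), mean(sm$ar[zm == 2 & sm$valid]))
  # doubling sigma_rel raises zone-mean PV
  zm2 <- matrix(rep(1:2, each = 200), 20, 20)
  cfg2 <- sim_config(n_years = 40, n_rows = 20, n_cols = 20, seed = 6,
                     zone_map = zm2,
                     zones = data.frame(zone = 1:2, sigma_rel = c(0.05, 0.1)))
  sm2 <- stability_map(simulate_stack(cfg2))
  expect_lt(mean(sm2$pv[zm2 == 1 & sm2$valid]),
            mean(sm2$pv[zm2 == 2 & sm2$valid]))
})

test_that("degenerate and masked pixels are flagged, not errors", {
  cfg <- sim_config(n_years = 10, n_rows = 3, n_cols = 3, sigma_rel = 0)
  sm <- stability_map(simulate_stack(cfg))
  expect_true(all(sm$degenerate))
  expect_true(all(sm$pv == 0))          # constant series: PV exactly 0
  expect_true(all(is.na(sm$ar)))        # AR undefined
  # fully masked stack: all-invalid map, no error
  vals <- array(NA_real_, c(2, 2, 5))
  st <- raster_stack(vals, years = 1:5)
  sm2 <- stability_map(st)
  expect_false(any(sm2$valid))
  expect_error(stability_map(raster_stack(array(1, c(2, 2, 2)), 1:2)), ">= 3")
})

test_that("moving windows have the right count, anchors and sensitivity", {
  cfg <- sim_config(n_years = 40, n_rows = 5, n_cols = 5, seed = 9)
  st <- simulate_stack(cfg)
  ws <- moving_window_metrics(st, W = 15)
  expect_equal(dim(ws$pv)[3], 26)              # 40 - 15 + 1
  expect_equal(length(ws$anchors), 26)
  expect_equal(ws$anchors[1], st$years[8])     # center of window 1..15
  expect_error(moving_window_metrics(st, W = 40), "W")
  expect_error(moving_window_metrics(st, W = 39), "W \\+ 2")
  # variance ramped up over time: window PV trends positive in the median
  set.seed(31)
  ny <- 40; npx <- 100
  sds <- seq(0.02, 0.12, length.out = ny)
  vals <- array(0.5 + rnorm(npx * ny, 0, rep(sds, each = npx)),
                c(10, 10, ny))
  ramp <- raster_stack(vals, years = 1:ny)
  wr <- moving_window_metrics(ramp, 15)
  slopes <- apply(wr$pv, c(1, 2), theil_sen)
  expect_gt(median(slopes), 0)
})

test_that("regime classification follows the median-quadrant rule", {
  pv <- matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2)
  ar <- matrix(c(0.1, 0.9, 0.1, 0.9), 2, 2)
  rg <- classify_regimes(make_stability_map(pv, ar))
  expect_equal(rg$code[1, 1], 1L)  # below both medians -> stable
  expect_equal(rg$code[2, 1], 2L)  # above both -> unstable
  expect_equal(rg$code[1, 2], 3L)  # high PV / low AR
  expect_equal(rg$code[2, 2], 4L)  # low PV / high AR
  # ties at the median are deterministically "low"
  pv2 <- matrix(c(0.2, 0.2, 0.2, 0.8), 2, 2)
  ar2 <- matrix(c(0.3, 0.3, 0.3, 0.8), 2, 2)
  rg2 <- classify_regimes(make_stability_map(pv2, ar2))
  expect_equal(rg2$code[1, 1], 1L)  # exactly at both medians -> stable
  # partition is exhaustive and disjoint over valid pixels
  set.seed(2)
  pv3 <- matrix(runif(400), 20, 20)
  ar3 <- matrix(runif(400, -1, 1), 20, 20)
  rg3 <- classify_regimes(make_stability_map(pv3, ar3))
  expect_true(all(rg3$code %in% 1:4))
  expect_equal(sum(table(rg3$code)), 400)
  expect_error(classify_regimes(make_stability_map(pv3 * NA, ar3)), "valid")
})
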