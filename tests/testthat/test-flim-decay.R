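make_cube <- function(arr, dt = 12.5 / dim(arr)[3], depth = 25) {
  DecayCube(arr, dt, depth)
}

test_that("spatial binning matches the moving-window definition", {
  # n = 0 is the identity
  cube <- make_cube(array(rpois(16 * 16 * 8, 5), c(16, 16, 8)))
  expect_identical(decayCounts(spatialBin(cube, 0L)), decayCounts(cube))

  # uniform cube: interior pixels hold 81 * c under the default n = 4
  u <- make_cube(array(3, c(16, 16, 8)))
  b <- spatialBin(u, 4L)
  expect_equal(decayCounts(b)[8, 8, ], rep(81 * 3, 8))

  # n = 1 spreads a single nonzero pixel decay to all 9 neighbours
  s <- array(0, c(3, 3, 4))
  s[2, 2, ] <- c(9, 5, 2, 1)
  sb <- spatialBin(make_cube(s), 1L)
  for (i in 1:3) for (j in 1:3)
    expect_equal(decayCounts(sb)[i, j, ], c(9, 5, 2, 1))

  # exact equality with the brute-force window-sum oracle (integer counts)
  set.seed(42)
  arr <- array(rpois(7 * 6 * 5, 4), c(7, 6, 5))
  expect_equal(decayCounts(spatialBin(make_cube(arr), 2L)),
               window_sum_oracle(arr, 2))

  expect_error(spatialBin(cube, -1), class = "flim_invalid_config")
})

test_that("noiseless bi-exponential traces are recovered almost exactly", {
  dt <- 12.5 / 256
  t <- (0:255) * dt
  trace <- 1000 * exp(-t / 0.3) + 500 * exp(-t / 2.5)
  fit <- fitBiexponential(trace, dt)
  expect_lt(abs(fit@a1 - 1000) / 1000, 1e-3)
  expect_lt(abs(fit@tau1_ns - 0.3) / 0.3, 1e-3)
  expect_lt(abs(fit@a2 - 500) / 500, 1e-3)
  expect_lt(abs(fit@tau2_ns - 2.5) / 2.5, 1e-3)
  expect_true(fit@converged)
})

test_that("the fitter agrees with a dense grid-search oracle", {
  dt <- 12.5 / 128
  t <- (0:127) * dt
  for (p in list(c(800, 0.4, 300, 2.2), c(1500, 0.25, 900, 1.8))) {
    trace <- p[1] * exp(-t / p[2]) + p[3] * exp(-t / p[4])
    oracle <- grid_biexp_oracle(trace, dt,
                                tau1_grid = seq(0.1, 0.6, by = 0.01),
                                tau2_grid = seq(1.2, 3.0, by = 0.02))
    fit <- fitBiexponential(trace, dt)
    expect_lt(abs(fit@tau1_ns - oracle$tau1), 0.011)
    expect_lt(abs(fit@tau2_ns - oracle$tau2), 0.021)
    expect_lte(fit@chi2_reduced * (128 - 4), oracle$sse + 1e-9)
  }
})

test_that("a single-exponential trace collapses to one component", {
  dt <- 12.5 / 256
  trace <- 800 * exp(-(0:255) * dt / 1.0)
  fit <- fitBiexponential(trace, dt)
  expect_equal(fit@a2, 0)
  expect_lt(abs(fit@tau1_ns - 1.0), 0.02)
  expect_equal(componentPercentages(fit)[["p1_percent"]], 100)
})

test_that("lifetimes are recovered within tolerance under Poisson noise", {
  dt <- 12.5 / 256
  t <- (0:255) * dt
  lam <- 1000 * exp(-t / 0.3) + 500 * exp(-t / 2.5)
  lam <- lam / sum(lam) * 1e4
  set.seed(99)
  errs <- replicate(60, {
    fit <- fitBiexponential(rpois(256, lam), dt)
    abs(fit@tau2_ns - 2.5) / 2.5
  })
  expect_lt(median(errs), 0.10)
})

test_that("components are always reported in ascending lifetime order", {
  dt <- 12.5 / 128
  t <- (0:127) * dt
  set.seed(17)
  for (i in 1:25) {
    t1 <- runif(1, 0.1, 1); t2 <- t1 * runif(1, 1.2, 8)
    a1 <- runif(1, 100, 2000); a2 <- runif(1, 100, 2000)
    trace <- rpois(128, pmax(a1 * exp(-t / t1) + a2 * exp(-t / t2), 0))
    fit <- fitBiexponential(trace, dt, min_photons = 0)
    expect_lte(fit@tau1_ns, fit@tau2_ns)
    expect_gte(fit@a1, 0); expect_gte(fit@a2, 0)
  }
})

test_that("below-threshold traces raise a below-threshold condition", {
  expect_error(fitBiexponential(rep(0.1, 64), 0.1, min_photons = 100),
               class = "flim_below_threshold")
})

test_that("mean lifetime and component percentages follow their definitions", {
  f <- function(a1, t1, a2, t2) new("BiexpFit", a1 = a1, a2 = a2,
    tau1_ns = t1, tau2_ns = t2, chi2_reduced = 1, n_photons = a1 + a2,
    converged = TRUE)
  expect_equal(meanLifetime(f(500, 1, 500, 3)), 2.0)
  expect_equal(meanLifetime(f(700, 1.3, 0, 1.3)), 1.3)
  expect_equal(meanLifetime(f(1000, 0.3, 500, 2.5)),
               (1000 * 0.3 + 500 * 2.5) / 1500)
  expect_equal(unname(componentPercentages(f(500, 1, 500, 3))), c(50, 50))
  expect_equal(unname(componentPercentages(f(700, 1, 0, 1))), c(100, 0))
  pc <- componentPercentages(f(1000, 0.3, 500, 2.5))
  expect_lt(abs(pc[["p1_percent"]] - 66.67), 0.01)
  expect_lt(abs(pc[["p2_percent"]] - 33.33), 0.01)
  # intensity-weighted alternative shifts weight to the long component
  pci <- componentPercentages(f(1000, 0.3, 500, 2.5),
                              intensity_weighted = TRUE)
  expect_gt(pci[["p2_percent"]], pc[["p2_percent"]])
  expect_error(meanLifetime(f(0, 1, 0, 2)), class = "flim_undefined_value")
  expect_error(componentPercentages(f(0, 1, 0, 2)),
               class = "flim_undefined_value")
})

test_that("whole-frame fitting recovers generative lifetimes", {
  # uniform noiseless cube: every binned trace is identical, so all valid
  # pixels must agree exactly
  dt <- 12.5 / 64
  trace <- 200 * exp(-(0:63) * dt / 0.4) + 120 * exp(-(0:63) * dt / 2.1)
  u <- DecayCube(aperm(array(trace, c(64, 24, 24)), c(2, 3, 1)), dt, 25)
  m <- fitFrame(u, n = 2L, stride = 2L)
  tau2s <- mapLayer(m, "tau2")[validityMask(m)]
  expect_gt(length(tau2s), 10)
  expect_lt(diff(range(tau2s)), 1e-6)

  # synthetic frame with known parameters: frame means within 5%
  p <- flat_params(photons = 500)
  cube <- generateDecayFrame(p, 25, frame_size = 64, n_time_bins = 128,
                             seed = 31)
  m <- fitFrame(cube, n = 4L, stride = 2L)
  st <- frameLifetimeStats(m)
  expect_lt(abs(st[["tau2_mean"]] - 2.0) / 2.0, 0.05)
  expect_lt(abs(st[["tau1_mean"]] - 0.3) / 0.3, 0.05)

  # zero-count cube: nothing to fit
  z <- DecayCube(array(0, c(16, 16, 32)), 0.1, 25)
  expect_error(fitFrame(z), class = "flim_empty_map")
})

test_that("frame lifetime statistics use the population SD over the mask", {
  mk <- function(vals, mask) {
    n <- length(vals)
    m <- matrix(mask, 1, n)
    v <- matrix(vals, 1, n); v[!m] <- NA_real_
    one <- matrix(ifelse(m, 1, NA_real_), 1, n)
    new("LifetimeMap", tau1 = v / 2, tau2 = v, a1 = one, a2 = one,
        mean_lifetime = v * 0.75, p1 = one * 50, p2 = one * 50,
        chi2 = one, n_photons = one * 100, mask = m, depth_um = 25,
        stride = 1L)
  }
  st <- frameLifetimeStats(mk(c(2, 4), c(TRUE, TRUE)))
  expect_equal(st[["tau2_mean"]], 3)
  expect_equal(st[["tau2_sd"]], 1)   # population divisor N
  # constant map: zero spread
  st2 <- frameLifetimeStats(mk(c(3, 3, 3), rep(TRUE, 3)))
  expect_equal(st2[["tau2_sd"]], 0)
  # masked outlier does not contribute
  st3 <- frameLifetimeStats(mk(c(2, 4, 400), c(TRUE, TRUE, FALSE)))
  expect_equal(st3[["tau2_mean"]], 3)
  expect_error(frameLifetimeStats(mk(c(2, 4), c(TRUE, FALSE))),
               class = "flim_insufficient_data")
})
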