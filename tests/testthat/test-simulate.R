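test_that("AR(1) driver has the stationary moments of its process", {
  x <- gen_alpha_ar1(10000, coef = 0.9, seed = 1)
  expect_lt(abs(acf(x, lag.max = 1, plot = FALSE)$acf[2] - 0.9), 0.03)
  expect_lt(abs(var(x) - 1 / (1 - 0.81)) / (1 / (1 - 0.81)), 0.15)
  # coef 0 degenerates to white noise
  y <- gen_alpha_ar1(10000, coef = 0, seed = 2)
  expect_lt(abs(acf(y, lag.max = 1, plot = FALSE)$acf[2]), 0.03)
  expect_error(gen_alpha_ar1(10, coef = 1), class = "cuspra_domain_error")
})

test_that("Gaussian driver and white-noise null have the stated moments", {
  b <- gen_beta_normal(10000, mean = -2, sd = 1, seed = 3)
  expect_lt(abs(mean(b) + 2), 0.05)
  r <- gen_random(10000, seed = 4)
  expect_lt(abs(mean(r)), 0.05)
  expect_lt(abs(sd(r) - 1), 0.05)
  expect_lt(abs(acf(r, lag.max = 1, plot = FALSE)$acf[2]), 0.03)
  expect_error(gen_beta_normal(10, 0, sd = 0), class = "cuspra_domain_error")
  # reproducibility under a fixed seed
  expect_identical(gen_beta_normal(50, 1, 2, seed = 9),
                   gen_beta_normal(50, 1, 2, seed = 9))
})

test_that("logistic map iterates exactly and finds its fixed point", {
  x <- gen_logistic_map(3, r = 3.9, x0 = 0.5)
  expect_equal(x[2], 0.975)
  expect_equal(x[3], 3.9 * 0.975 * 0.025)
  # r = 2 converges to 1 - 1/r
  y <- gen_logistic_map(60, r = 2, x0 = 0.3)
  expect_equal(y[60], 0.5, tolerance = 1e-8)
  expect_error(gen_logistic_map(10, x0 = 1.2), class = "cuspra_domain_error")
})

test_that("periodic series is an exact sine plus the requested noise", {
  x <- gen_periodic(10, period = 10, noise_sd = 0)
  expect_equal(x, sin(2 * pi * (0:9) / 10), tolerance = 1e-12)
  expect_equal(sum(x), 0, tolerance = 1e-12)
  long <- gen_periodic(50, period = 10, noise_sd = 0)
  expect_equal(long[1:10], long[11:20])
  noisy <- gen_periodic(10000, period = 10, noise_sd = 0.3, seed = 5)
  resid <- noisy - sin(2 * pi * (0:9999) / 10)
  expect_lt(abs(sd(resid) - 0.3), 0.02)
})

test_that("noise-free SDE relaxes to the stable equilibria", {
  sc <- sim_scenario(sigma_z = 0)
  # single well at beta = -2: decay toward 0
  z <- gen_cusp_state(rep(0, 50), rep(-2, 50), sc, z0 = 1)
  expect_true(all(diff(abs(z)) <= 0))
  expect_lt(abs(z[50]), 1e-10)
  # bistable at beta = 3: from z0 = 1 the upper branch attracts
  z2 <- gen_cusp_state(rep(0, 30), rep(3, 30), sc, z0 = 1)
  expect_equal(z2[30], sqrt(3), tolerance = 1e-6)
  # and the lower branch from a negative start
  z3 <- gen_cusp_state(rep(0, 30), rep(3, 30), sc, z0 = -1)
  expect_equal(z3[30], -sqrt(3), tolerance = 1e-6)
})

test_that("higher beta scenarios spend more time inside the cusp area", {
  set.seed(10)
  frac_for <- function(beta_mean, seed) {
    d <- sim_cusp_dataset(beta_mean = beta_mean, seed = seed)
    mean(cardan_discriminant(d$driver_a, d$driver_b) <= 0)
  }
  hi <- mean(sapply(1:8, function(i) frac_for(2, 100 + i)))
  lo <- mean(sapply(1:8, function(i) frac_for(-2, 200 + i)))
  expect_gt(hi, lo)
})

test_that("ensembles are reproducible and satisfy the dataset invariants", {
  sc <- sim_scenario(n_steps = 50)
  e1 <- build_ensemble("cusp", beta_means = c(-2, 2), n_replicates = 2,
                       scenario = sc, seed = 77)
  e2 <- build_ensemble("cusp", beta_means = c(-2, 2), n_replicates = 2,
                       scenario = sc, seed = 77)
  expect_identical(e1$data, e2$data)
  expect_equal(nrow(e1), 4)
  for (d in e1$data) {
    expect_s3_class(d, "cusp_data")
    expect_equal(nrow(d), 50)
  }
  # null kinds carry the same driver structure but a z-scored state
  en <- build_ensemble("periodic", beta_means = 0, n_replicates = 2,
                       scenario = sc, seed = 78)
  for (d in en$data) {
    expect_equal(mean(d$state), 0, tolerance = 1e-10)
    expect_equal(sd(d$state), 1, tolerance = 1e-10)
  }
})

test_that("stationary sampling stays near the stable branches", {
  set.seed(6)
  draws <- rcusp(4000, 0, 3)
  # nearly all mass near the two modes at +/- sqrt(3)
  near <- abs(abs(draws) - sqrt(3)) < 1.2
  expect_gt(mean(near), 0.9)
})
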