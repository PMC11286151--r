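test_that("aicc follows the small-sample correction formula", {
  expect_equal(aicc(0, 1, 100), 2 + 4 / 98)
  expect_equal(aicc(-10, 2, 50), 24 + 12 / 47)
  # converges to plain AIC as n grows
  expect_equal(aicc(-10, 3, 1e8), 26, tolerance = 1e-6)
  expect_error(aicc(0, 5, 6), class = "cuspra_domain_error")
})

test_that("cusp_data validates its invariants", {
  d <- strong_cusp_data()
  expect_s3_class(d, "cusp_data")
  short <- tibble::tibble(time = 1:5, state = rnorm(5),
                          driver_a = rnorm(5), driver_b = rnorm(5))
  expect_error(cusp_data(short), class = "cuspra_input_error")
  const <- tibble::tibble(time = 1:20, state = rnorm(20),
                          driver_a = rep(1, 20), driver_b = rnorm(20))
  expect_error(cusp_data(const), class = "cuspra_input_error")
  gap <- tibble::tibble(time = c(1:19, 25), state = rnorm(20),
                        driver_a = rnorm(20), driver_b = rnorm(20))
  expect_error(cusp_data(gap), class = "cuspra_input_error")
  na_row <- tibble::tibble(time = 1:20, state = c(NA, rnorm(19)),
                           driver_a = rnorm(20), driver_b = rnorm(20))
  expect_error(cusp_data(na_row), class = "cuspra_input_error")
})

test_that("fitted cusp model satisfies its structural postconditions", {
  d <- strong_cusp_data(seed = 42)
  f <- fit_cusp(d, seed = 1)
  expect_true(f$converged)
  # exact reconstruction of the canonical state
  expect_equal(f$z, f$coefficients[["w0"]] + f$coefficients[["w1"]] * d$state,
               tolerance = 1e-12)
  expect_lte(f$pseudo_r2, 1)
  expect_equal(f$frac_in_cusp, mean(f$delta <= 0))
  expect_gt(f$coefficients[["w1"]], 0)   # canonical sign convention
  # stationarity: analytic gradient is numerically zero at the optimum
  expect_lt(f$max_abs_grad, 1e-3 * (1 + abs(f$loglik)))
  # broom-style accessors
  td <- tidy(f)
  expect_equal(td$term,
               c("alpha0", "alpha1", "beta0", "beta1", "w0", "w1"))
  expect_true(all(is.finite(td$std.error)))
  expect_equal(nrow(glance(f)), 1)
  expect_equal(nrow(augment(f)), nrow(d))
})

test_that("cusp likelihood matches an independent adaptive quadrature", {
  d <- strong_cusp_data(seed = 3)
  f <- fit_cusp(d, seed = 1)
  ll <- sum(vapply(seq_len(f$n_obs), function(t) {
    a <- f$alpha[t]; b <- f$beta[t]; z <- f$z[t]
    peak <- a * z + b * z^2 / 2 - z^4 / 4
    N <- integrate(function(u) exp(a * u + b * u^2 / 2 - u^4 / 4 - peak),
                   -Inf, Inf, rel.tol = 1e-12)$value
    -log(N)
  }, numeric(1))) + f$n_obs * log(f$coefficients[["w1"]])
  expect_equal(f$loglik, ll, tolerance = 1e-6)
})

test_that("slopes of a known generating model are recovered", {
  # canonical-noise SDE data at the generating scale; modest replicate count
  sc <- sim_scenario(n_steps = 200)
  errs <- t(sapply(1:5, function(i) {
    d <- sim_cusp_dataset(scenario = sc, seed = 5000 + i)
    f <- fit_cusp(d, seed = i)
    f$coefficients_raw[c("alpha1", "beta1", "w1")] - 1
  }))
  expect_lt(median(abs(errs)), 0.25)
  expect_true(all(errs > -0.6 & errs < 0.6))
})

test_that("driver standardization is undone correctly in raw coefficients", {
  d <- strong_cusp_data(seed = 11)
  f <- fit_cusp(d, seed = 2)
  raw <- f$coefficients_raw
  alpha_from_raw <- raw[["alpha0"]] + raw[["alpha1"]] * d$driver_a
  expect_equal(as.numeric(alpha_from_raw), f$alpha, tolerance = 1e-10)
  beta_from_raw <- raw[["beta0"]] + raw[["beta1"]] * d$driver_b
  expect_equal(as.numeric(beta_from_raw), f$beta, tolerance = 1e-10)
})
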