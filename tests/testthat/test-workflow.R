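test_that("PCA reduction extracts a dominant gradient with fixed sign", {
  set.seed(14)
  n <- 40
  gradient <- seq(-2, 2, length.out = n)
  comm <- as.data.frame(sapply(1:8, function(j) {
    j * gradient + rnorm(n, 0, 0.3)
  }))
  red <- reduce_to_state(comm)
  expect_gt(abs(cor(red$state, gradient)), 0.98)
  expect_gte(red$loadings$loading[1], 0)
  expect_equal(sum(red$explained_variance), 1, tolerance = 1e-12)
  # two perfectly correlated variables: PC1 explains everything
  two <- data.frame(a = gradient, b = 3 * gradient)
  red2 <- suppressWarnings(reduce_to_state(two))
  expect_equal(red2$explained_variance[1], 1, tolerance = 1e-12)
  # an orthogonal rotation of the variables leaves the extracted gradient
  # essentially unchanged (up to sign; variables are rescaled internally,
  # so agreement is near-exact rather than bitwise)
  th <- pi / 7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pair <- cbind(gradient + rnorm(n, 0, 0.2), 2 * gradient + rnorm(n, 0, 0.2))
  s1 <- reduce_to_state(as.data.frame(pair))$state
  s2 <- reduce_to_state(as.data.frame(pair %*% rot))$state
  expect_gt(abs(cor(s1, s2)), 0.99)
  # constant columns are dropped with a warning
  expect_warning(reduce_to_state(data.frame(a = gradient, b = gradient * 2,
                                            c = rep(1, n))),
                 "constant")
})

test_that("pipeline runs end to end on cusp-like data and writes artifacts", {
  out_dir <- withr::local_tempdir()
  d <- strong_cusp_data(seed = 42)
  input <- file.path(out_dir, "input.csv")
  readr::write_csv(tibble::as_tibble(d), input)
  cfg <- cuspra_config(input, out_dir = file.path(out_dir, "res"), seed = 5)
  r <- run_pipeline(cfg)
  expect_equal(r$status, 0L)
  expect_true(r$gate$overall)
  expect_true(file.exists(r$paths$fit_report))
  expect_true(file.exists(r$paths$observations))
  expect_true(file.exists(r$paths$resilience))
  expect_true(file.exists(r$paths$interpretation))
  res <- readr::read_csv(r$paths$resilience, show_col_types = FALSE)
  expect_true(all(res$RA > 0 & res$RA < 1))
  report <- jsonlite::read_json(r$paths$fit_report)
  expect_true(report$gate$overall)

  # byte-identical outputs under the same config and seed
  cfg2 <- cuspra_config(input, out_dir = file.path(out_dir, "res2"), seed = 5)
  r2 <- run_pipeline(cfg2)
  expect_identical(readLines(r$paths$resilience), readLines(r2$paths$resilience))
  expect_identical(readLines(r$paths$fit_report), readLines(r2$paths$fit_report))
})

test_that("pipeline refuses to score resilience when the gate fails", {
  out_dir <- withr::local_tempdir()
  d <- noise_data(seed = 7)
  input <- file.path(out_dir, "noise.csv")
  readr::write_csv(tibble::as_tibble(d), input)
  cfg <- cuspra_config(input, out_dir = file.path(out_dir, "res"), seed = 5)
  expect_message(r <- run_pipeline(cfg), "gate failed")
  expect_equal(r$status, 3L)
  expect_false(r$gate$overall)
  expect_true(file.exists(r$paths$fit_report))
  expect_false(file.exists(r$paths$resilience))
  expect_false(file.exists(r$paths$resilience_summary))
})

test_that("pipeline validates configuration and input", {
  expect_error(cuspra_config("x.csv", state = NULL, state_block = NULL),
               class = "cuspra_config_error")
  cfg <- cuspra_config("definitely-missing.csv", out_dir = tempdir())
  expect_error(run_pipeline(cfg), class = "cuspra_input_error")
  # bad column mapping
  out_dir <- withr::local_tempdir()
  input <- file.path(out_dir, "input.csv")
  readr::write_csv(tibble::as_tibble(strong_cusp_data(seed = 1)), input)
  bad <- cuspra_config(input, state = "nope", out_dir = out_dir)
  expect_error(run_pipeline(bad), class = "cuspra_config_error")
})

test_that("pipeline reduces a multivariate block to PC1 before fitting", {
  out_dir <- withr::local_tempdir()
  d <- strong_cusp_data(seed = 42)
  set.seed(2)
  multi <- tibble::tibble(
    time = d$time,
    sp1 = d$state + rnorm(50, 0, 0.1),
    sp2 = -0.5 * d$state + rnorm(50, 0, 0.1),
    sp3 = 2 * d$state + rnorm(50, 0, 0.1),
    driver_a = d$driver_a, driver_b = d$driver_b
  )
  input <- file.path(out_dir, "multi.csv")
  readr::write_csv(multi, input)
  cfg <- cuspra_config(input, state = NULL,
                       state_block = c("sp1", "sp2", "sp3"),
                       out_dir = file.path(out_dir, "res"), seed = 5)
  r <- run_pipeline(cfg)
  report <- jsonlite::read_json(r$paths$fit_report)
  expect_gt(report$pca$explained_variance, 0.9)
  expect_true(r$status %in% c(0L, 3L))
})

test_that("plot builders return ggplot objects", {
  d <- strong_cusp_data(seed = 21)
  f <- fit_cusp(d, seed = 1)
  res <- cuspra(f)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_resilience_timeline(res), "ggplot")
  grid <- bifurcation_set_grid(beta_max = 3, n = 50)
  expect_equal(grid$alpha_high, -grid$alpha_low)
  expect_true(all(grid$alpha_high >= 0))
})
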