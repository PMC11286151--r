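make_gate_inputs <- function(pseudo_r2 = 0.5, delta_aicc = 10,
                             frac = 0.5, p = 0.001, converged = TRUE) {
  cusp <- structure(list(pseudo_r2 = pseudo_r2, aicc = 100, n_obs = 50,
                         frac_in_cusp = frac, w1_pvalue = p,
                         converged = converged),
                    class = "cusp_fit")
  lin <- structure(list(aicc = 100 + delta_aicc), class = "cusp_linear_fit")
  list(cusp = cusp, lin = lin)
}

test_that("gate applies the four criteria at their exact thresholds", {
  g <- with(make_gate_inputs(0.31, 2.5, 0.12, 0.01), gate(cusp, lin))
  expect_true(g$overall)
  # each single criterion failing flips the overall decision
  expect_false(with(make_gate_inputs(pseudo_r2 = 0.29), gate(cusp, lin))$overall)
  expect_false(with(make_gate_inputs(delta_aicc = 1.9), gate(cusp, lin))$overall)
  expect_false(with(make_gate_inputs(p = 0.06), gate(cusp, lin))$overall)
  # "more than 10%" is strict: exactly 10% fails
  g10 <- with(make_gate_inputs(frac = 0.10), gate(cusp, lin))
  expect_false(g10$cusp_area_pass)
  expect_false(g10$overall)
  # boundary that passes: AICc margin of exactly 2
  expect_true(with(make_gate_inputs(delta_aicc = 2), gate(cusp, lin))$aicc_pass)
  # non-convergence rejects with a reason
  gnc <- with(make_gate_inputs(converged = FALSE), gate(cusp, lin))
  expect_false(gnc$overall)
  expect_match(gnc$reason, "converge")
  # missing w1 p-value cannot pass the significance criterion
  gna <- with(make_gate_inputs(p = NA_real_), gate(cusp, lin))
  expect_false(gna$w1_pass)
})

test_that("improving any single gate input never flips a pass to a fail", {
  base <- list(pseudo_r2 = 0.35, delta_aicc = 3, frac = 0.15, p = 0.02)
  g0 <- with(do.call(make_gate_inputs, base), gate(cusp, lin))
  expect_true(g0$overall)
  better <- list(
    modifyList(base, list(pseudo_r2 = 0.9)),
    modifyList(base, list(delta_aicc = 50)),
    modifyList(base, list(frac = 0.9)),
    modifyList(base, list(p = 1e-10))
  )
  for (b in better) {
    expect_true(with(do.call(make_gate_inputs, b), gate(cusp, lin))$overall)
  }
})

test_that("hypothesis statistics handle degenerate inputs and conventions", {
  # constant state: no changes, zero rolling variance, flagged rho
  ra <- runif(20, 0.2, 0.8)
  h2 <- h2_statistic(ra, rep(1, 20))
  expect_equal(h2$rho, 0)
  expect_match(h2$note, "degenerate")
  h3 <- h3_statistic(ra, rep(1, 20))
  expect_true(all(h3$pairs$roll_var == 0))
  # forward-difference pairing drops the last observation
  st <- cumsum(rnorm(20))
  h2b <- h2_statistic(ra, st)
  expect_equal(nrow(h2b$pairs), 19)
  expect_equal(h2b$pairs$abs_dz, abs(diff(st)))
  # centred window of 5 on T = 50 leaves 46 valid midpoints
  h3b <- h3_statistic(runif(50), rnorm(50), window = 5)
  expect_equal(nrow(h3b$pairs), 46)
  expect_error(h3_statistic(runif(5), rnorm(5), window = 7),
               class = "cuspra_domain_error")
  # single-scenario H1 input has no defined correlation
  h1 <- h1_statistic(tibble::tibble(beta_mean = rep(1, 5), min_RA = runif(5)))
  expect_true(is.na(h1$rho))
  expect_match(h1$note, "single scenario")
})

test_that("h1 recovers a planted monotone scenario ordering", {
  set.seed(8)
  tbl <- tibble::tibble(
    beta_mean = rep(-2:2, each = 10),
    min_RA = plogis(-rep(-2:2, each = 10) + rnorm(50, 0, 0.3))
  )
  h1 <- h1_statistic(tbl)
  expect_lt(h1$rho, -0.8)
  expect_equal(nrow(h1$by_scenario), 5)
})

test_that("confusion experiment accounts for every series", {
  sc <- sim_scenario(n_steps = 50)
  ce <- confusion_experiment(n_per_kind = 5, beta_means = c(-2, 2),
                             scenario = sc, seed = 12,
                             kinds = c("random"))
  expect_s3_class(ce, "cuspra_confusion")
  expect_equal(ce$n_cusp, 5)
  expect_equal(ce$n_null, 5)
  expect_equal(nrow(ce$results), 10)
  expect_true(all(ce$results$overall %in% c(TRUE, FALSE)))
  expect_equal(sum(ce$by_kind$n), 10)
  # rates are consistent with the per-series table
  expect_equal(ce$fp_rate,
               mean(ce$results$overall[ce$results$kind != "cusp"]))
  expect_equal(ce$fn_rate,
               mean(!ce$results$overall[ce$results$kind == "cusp"]))
  # deterministic under the master seed
  ce2 <- confusion_experiment(n_per_kind = 5, beta_means = c(-2, 2),
                              scenario = sc, seed = 12, kinds = c("random"))
  expect_equal(ce$results, ce2$results)
})
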