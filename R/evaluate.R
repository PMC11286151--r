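#' Four-criterion adequacy gate for a cusp fit
#'
#' Decides whether the stochastic cusp model is an adequate description of
#' the data, i.e. whether a resilience assessment is warranted. All four
#' criteria must hold:
#' \enumerate{
#'   \item pseudo-R-squared above `r2_min` (default 0.3);
#'   \item cusp AICc below the linear model's AICc by at least
#'     `aicc_margin` units (default 2);
#'   \item strictly more than `cusp_frac_min` (default 10\%) of
#'     observations inside the cusp area (Cardan's discriminant at or below
#'     zero);
#'   \item the state-variable coefficient \eqn{w_1} significant at `level`
#'     (default 0.05, two-sided Wald test).
#' }
#' A non-converged cusp fit fails the gate outright, with the reason
#' recorded.
#'
#' @param cusp A [fit_cusp()] object.
#' @param linear A [fit_linear()] object on the same data.
#' @param logistic Optional [fit_logistic()] object; reported for
#'   information only, it does not enter the decision.
#' @param level Significance level for the state-coefficient test.
#' @param r2_min,aicc_margin,cusp_frac_min Criterion thresholds.
#' @return A one-row tibble of class `cuspra_gate` with the four criterion
#'   inputs, the four pass flags, `overall`, and a `reason` string for
#'   failures.
#' @export
gate <- function(cusp, linear, logistic = NULL, level = 0.05,
                 r2_min = 0.3, aicc_margin = 2, cusp_frac_min = 0.10) {
  stopifnot(inherits(cusp, "cusp_fit"), inherits(linear, "cusp_linear_fit"))
  delta_aicc <- linear$aicc - cusp$aicc
  pseudo_r2_pass <- isTRUE(cusp$pseudo_r2 > r2_min)
  aicc_pass <- isTRUE(delta_aicc >= aicc_margin)
  cusp_area_pass <- isTRUE(cusp$frac_in_cusp > cusp_frac_min)
  w1_pass <- isTRUE(!is.na(cusp$w1_pvalue) && cusp$w1_pvalue < level)
  overall <- cusp$converged && pseudo_r2_pass && aicc_pass &&
    cusp_area_pass && w1_pass
  reason <- if (!cusp$converged) {
    "cusp fit did not converge"
  } else if (overall) {
    NA_character_
  } else {
    failed <- c("pseudo-R2", "delta-AICc", "cusp-area fraction",
                "w1 significance")[!c(pseudo_r2_pass, aicc_pass,
                                      cusp_area_pass, w1_pass)]
    paste("failed:", paste(failed, collapse = ", "))
  }
  out <- tibble::tibble(
    pseudo_r2 = cusp$pseudo_r2,
    delta_aicc = delta_aicc,
    frac_in_cusp = cusp$frac_in_cusp,
    w1_pvalue = cusp$w1_pvalue,
    logistic_aicc = if (is.null(logistic)) NA_real_ else logistic$aicc,
    converged = cusp$converged,
    pseudo_r2_pass = pseudo_r2_pass,
    aicc_pass = aicc_pass,
    cusp_area_pass = cusp_area_pass,
    w1_pass = w1_pass,
    overall = overall,
    reason = reason
  )
  class(out) <- c("cuspra_gate", class(out))
  out
}

fit_and_gate <- function(data, seed = NULL, fit_logistic_too = FALSE, ...) {
  tryCatch({
    cusp <- fit_cusp(data, seed = seed)
    lin <- fit_linear(data)
    logi <- if (fit_logistic_too) fit_logistic(data, seed = seed) else NULL
    gate(cusp, lin, logi, ...)
  }, error = function(e) {
    tibble::tibble(
      pseudo_r2 = NA_real_, delta_aicc = NA_real_, frac_in_cusp = NA_real_,
      w1_pvalue = NA_real_, logistic_aicc = NA_real_, converged = FALSE,
      pseudo_r2_pass = FALSE, aicc_pass = FALSE, cusp_area_pass = FALSE,
      w1_pass = FALSE, overall = FALSE,
      reason = paste("fit error:", conditionMessage(e))
    )
  })
}

#' False-positive / false-negative classification experiment
#'
#' Replicates the simulation study validating the adequacy gate: ensembles
#' of cusp-generated and null (chaotic, periodic, random) series are fitted
#' and gated. The false-positive rate is the fraction of null series that
#' pass all four criteria; the false-negative rate is the fraction of
#' cusp-generated series that fail at least one. Fit failures count as gate
#' rejections and are tallied, never dropped.
#'
#' @param n_per_kind Series per kind (default 100). Null kinds get
#'   `n_per_kind` replicates spread evenly over the scenario grid (the
#'   drivers are simulated identically for all kinds); the cusp kind gets
#'   `n_per_kind / length(beta_means)` replicates per scenario level.
#' @param beta_means Scenario grid of bifurcation-driver means.
#' @param scenario A [sim_scenario()] carrying the remaining settings.
#' @param seed Master seed; all ensembles and fits derive from it.
#' @param kinds Null kinds to include.
#' @return A list of class `cuspra_confusion`: `fp_rate`, `fn_rate`,
#'   `by_kind` (pass counts per kind), `by_scenario` (cusp rejections per
#'   scenario level), `results` (per-series gate table) and bookkeeping.
#' @export
confusion_experiment <- function(n_per_kind = 100, beta_means = -2:2,
                                 scenario = sim_scenario(), seed = NULL,
                                 kinds = c("chaotic", "periodic", "random")) {
  if (!is.null(seed)) set.seed(seed)
  reps_per_level <- ceiling(n_per_kind / length(beta_means))
  all_kinds <- c("cusp", kinds)
  ens <- purrr::map(all_kinds, function(k) {
    build_ensemble(k, beta_means = beta_means, n_replicates = reps_per_level,
                   scenario = scenario)
  })
  ens <- dplyr::bind_rows(ens) |>
    dplyr::group_by(.data$kind) |>
    dplyr::slice_head(n = n_per_kind) |>
    dplyr::ungroup()
  gates <- purrr::map2(ens$data, ens$rep_seed,
                       function(d, s) fit_and_gate(d, seed = s))
  results <- dplyr::bind_cols(
    dplyr::select(ens, "kind", "beta_mean", "replicate"),
    dplyr::bind_rows(lapply(gates, as.data.frame))
  )
  by_kind <- results |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(n = dplyr::n(), n_pass = sum(.data$overall),
                     pass_rate = mean(.data$overall), .groups = "drop")
  by_scenario <- results |>
    dplyr::filter(.data$kind == "cusp") |>
    dplyr::group_by(.data$beta_mean) |>
    dplyr::summarise(n = dplyr::n(), n_reject = sum(!.data$overall),
                     fn_rate = mean(!.data$overall), .groups = "drop")
  null_res <- dplyr::filter(results, .data$kind != "cusp")
  cusp_res <- dplyr::filter(results, .data$kind == "cusp")
  structure(list(
    fp_rate = mean(null_res$overall),
    fn_rate = mean(!cusp_res$overall),
    n_null = nrow(null_res),
    n_cusp = nrow(cusp_res),
    by_kind = by_kind,
    by_scenario = by_scenario,
    results = results,
    seed = seed
  ), class = "cuspra_confusion")
}

#' @export
print.cuspra_confusion <- function(x, ...) {
  cat("Four-criterion gate classification experiment\n")
  cat(sprintf("  false-positive rate: %.1f%% (%d null series)\n",
              100 * x$fp_rate, x$n_null))
  cat(sprintf("  false-negative rate: %.1f%% (%d cusp series)\n",
              100 * x$fn_rate, x$n_cusp))
  print(x$by_kind)
  invisible(x)
}

#' @describeIn confusion_experiment Per-kind pass rates as a tibble.
#' @param x A `cuspra_confusion` object.
#' @param ... Unused.
#' @export
tidy.cuspra_confusion <- function(x, ...) x$by_kind

#' @describeIn confusion_experiment One-row summary (FP and FN rates).
#' @export
glance.cuspra_confusion <- function(x, ...) {
  tibble::tibble(fp_rate = x$fp_rate, fn_rate = x$fn_rate,
                 n_null = x$n_null, n_cusp = x$n_cusp)
}

#' Resilience response to the scenario level of nonlinearity
#'
#' First validation hypothesis: the minimum resilience of a simulated
#' series should fall as the scenario mean of the bifurcation driver rises
#' (more of the series spent near or inside the fold). Takes a per-replicate
#' table of minimum RA values and returns the per-scenario distributions and
#' the Spearman rank correlation of minimum RA against the scenario mean
#' (expected strongly negative).
#'
#' @param min_ra A data frame with columns `beta_mean` and `min_RA`, one
#'   row per replicate (see [hypothesis_experiment()]).
#' @return A list with `by_scenario` (median/quartiles of minimum RA per
#'   scenario), `rho` (Spearman correlation; `NA` with a note when fewer
#'   than two scenario levels are present) and `n`.
#' @export
h1_statistic <- function(min_ra) {
  stopifnot(all(c("beta_mean", "min_RA") %in% names(min_ra)))
  by_scenario <- min_ra |>
    dplyr::group_by(.data$beta_mean) |>
    dplyr::summarise(n = dplyr::n(),
                     median_min_RA = stats::median(.data$min_RA),
                     q25 = quantile(.data$min_RA, 0.25),
                     q75 = quantile(.data$min_RA, 0.75),
                     .groups = "drop")
  if (dplyr::n_distinct(min_ra$beta_mean) < 2) {
    return(list(by_scenario = by_scenario, rho = NA_real_,
                note = "rank correlation undefined for a single scenario",
                n = nrow(min_ra)))
  }
  rho <- stats::cor(min_ra$beta_mean, min_ra$min_RA, method = "spearman")
  list(by_scenario = by_scenario, rho = rho, note = NULL, n = nrow(min_ra))
}

#' Resilience versus successive state changes
#'
#' Second validation hypothesis (critical slowing down): observations with
#' low resilience should show larger jumps. Pairs each RA value with the
#' forward absolute state difference \eqn{|z_{t+1} - z_t|} and reports the
#' Spearman correlation, expected negative on cusp ensembles.
#'
#' @param ra Resilience series (numeric, or a [cuspra()] tibble).
#' @param state Observed state series of the same length.
#' @return A list with `pairs` (tibble of `RA`, `abs_dz`) and `rho`
#'   (Spearman; 0 with a note when the state never changes).
#' @export
h2_statistic <- function(ra, state) {
  if (inherits(ra, "cuspra_resilience")) ra <- ra$RA
  stopifnot(length(ra) == length(state), length(ra) >= 3)
  T_obs <- length(state)
  pairs <- tibble::tibble(
    RA = ra[seq_len(T_obs - 1)],
    abs_dz = abs(diff(state))
  )
  if (sd(pairs$abs_dz) == 0 || sd(pairs$RA) == 0) {
    return(list(pairs = pairs, rho = 0,
                note = "degenerate input: no variation in one margin"))
  }
  rho <- stats::cor(pairs$RA, pairs$abs_dz, method = "spearman")
  list(pairs = pairs, rho = rho, note = NULL)
}

#' Resilience versus rolling state variance
#'
#' Third validation hypothesis (critical slowing down): low-resilience
#' phases should show anomalously large variance. Computes the state
#' variance in a centred window (default width 5) and pairs it with RA at
#' the window midpoint; reports the Spearman correlation, expected negative
#' on cusp ensembles.
#'
#' @inheritParams h2_statistic
#' @param window Odd window width in time steps.
#' @return A list with `pairs` (tibble of `time`, `RA`, `roll_var`) and
#'   `rho`.
#' @export
h3_statistic <- function(ra, state, window = 5) {
  if (inherits(ra, "cuspra_resilience")) ra <- ra$RA
  stopifnot(length(ra) == length(state))
  T_obs <- length(state)
  if (window > T_obs) {
    abort("`window` exceeds the series length", class = "cuspra_domain_error")
  }
  if (window %% 2 == 0) window <- window + 1
  half <- (window - 1) / 2
  mids <- (half + 1):(T_obs - half)
  roll_var <- vapply(mids, function(t) var(state[(t - half):(t + half)]),
                     numeric(1))
  pairs <- tibble::tibble(time = mids, RA = ra[mids], roll_var = roll_var)
  if (sd(pairs$roll_var) == 0 || sd(pairs$RA) == 0) {
    return(list(pairs = pairs, rho = 0,
                note = "degenerate input: no variation in one margin"))
  }
  rho <- stats::cor(pairs$RA, pairs$roll_var, method = "spearman")
  list(pairs = pairs, rho = rho, note = NULL)
}

#' Hypothesis experiment on cusp scenario ensembles
#'
#' Simulates cusp ensembles over the scenario grid, fits the cusp model to
#' each replicate, computes the resilience series, and evaluates the three
#' validation hypotheses: (H1) minimum RA falls with the scenario mean of
#' the bifurcation driver; (H2) RA is negatively rank-correlated with the
#' size of successive state changes; (H3) RA is negatively rank-correlated
#' with rolling state variance. H2 and H3 pool observation pairs over all
#' replicates. Resilience is computed for every replicate whose fit
#' converged, regardless of its gate outcome.
#'
#' @inheritParams confusion_experiment
#' @param n_replicates Replicates per scenario level (default 10).
#' @param window Rolling-variance window for H3.
#' @return A list of class `cuspra_hypotheses` with elements `h1`, `h2`,
#'   `h3` (see the individual statistics), `min_ra` (per-replicate table)
#'   and `n_fitted`.
#' @export
hypothesis_experiment <- function(beta_means = -2:2, n_replicates = 10,
                                  scenario = sim_scenario(), seed = NULL,
                                  window = 5) {
  if (!is.null(seed)) set.seed(seed)
  ens <- build_ensemble("cusp", beta_means = beta_means,
                        n_replicates = n_replicates, scenario = scenario)
  per_rep <- purrr::pmap(ens, function(kind, beta_mean, replicate, rep_seed,
                                       data) {
    fit <- tryCatch(fit_cusp(data, seed = rep_seed), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NULL)
    res <- cuspra(fit)
    h2 <- h2_statistic(res, data$state)
    h3 <- h3_statistic(res, data$state, window = window)
    list(min_ra = tibble::tibble(beta_mean = beta_mean,
                                 replicate = replicate,
                                 min_RA = min(res$RA)),
         h2_pairs = h2$pairs, h3_pairs = h3$pairs)
  })
  per_rep <- per_rep[!vapply(per_rep, is.null, logical(1))]
  if (length(per_rep) == 0) {
    abort("no cusp fit converged in the hypothesis experiment",
          class = "cuspra_fit_error")
  }
  min_ra <- dplyr::bind_rows(lapply(per_rep, `[[`, "min_ra"))
  h2_pairs <- dplyr::bind_rows(lapply(per_rep, `[[`, "h2_pairs"))
  h3_pairs <- dplyr::bind_rows(lapply(per_rep, `[[`, "h3_pairs"))
  h1 <- h1_statistic(min_ra)
  h2 <- list(pairs = h2_pairs,
             rho = stats::cor(h2_pairs$RA, h2_pairs$abs_dz,
                              method = "spearman"))
  h3 <- list(pairs = h3_pairs,
             rho = stats::cor(h3_pairs$RA, h3_pairs$roll_var,
                              method = "spearman"))
  structure(list(h1 = h1, h2 = h2, h3 = h3, min_ra = min_ra,
                 n_fitted = length(per_rep), seed = seed),
            class = "cuspra_hypotheses")
}

#' @export
print.cuspra_hypotheses <- function(x, ...) {
  cat("Resilience-indicator hypothesis experiment\n")
  cat(sprintf("  replicates with converged fits: %d\n", x$n_fitted))
  cat(sprintf("  H1 rho(min RA, scenario beta mean): %.3f\n", x$h1$rho))
  cat(sprintf("  H2 rho(RA, |state change|):        %.3f\n", x$h2$rho))
  cat(sprintf("  H3 rho(RA, rolling variance):      %.3f\n", x$h3$rho))
  invisible(x)
}
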