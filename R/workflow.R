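#' Reduce a multivariate community matrix to a single state variable
#'
#' Standard PCA plumbing for the first protocol step when the system is
#' observed as a multivariate block (e.g. species abundances by year): the
#' first principal-component score series of the centred and scaled
#' variables becomes the state variable. Constant columns are removed with
#' a warning. The sign convention fixes the loading of the first retained
#' variable to be non-negative, so scores are reproducible across
#' orthogonal re-expressions of the input.
#'
#' @param data A data frame of observations (rows) by variables (columns),
#'   all numeric, no missing values, at least two variables.
#' @return A list of class `cuspra_pca`: `state` (PC1 scores),
#'   `explained_variance` (proportion per component), `loadings` (tibble of
#'   PC1 loadings) and `dropped` (names of removed constant columns).
#' @export
reduce_to_state <- function(data) {
  stopifnot(is.data.frame(data))
  mat <- as.matrix(data)
  if (!is.numeric(mat)) {
    abort("all columns must be numeric", class = "cuspra_input_error")
  }
  if (anyNA(mat)) {
    abort("missing values are not allowed in the multivariate block",
          class = "cuspra_input_error")
  }
  sds <- apply(mat, 2, sd)
  dropped <- colnames(mat)[sds == 0]
  if (length(dropped) > 0) {
    warn(paste("dropping constant column(s):", paste(dropped, collapse = ", ")))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  if (ncol(mat) < 2) {
    abort("need at least two non-constant variables for PCA",
          class = "cuspra_input_error")
  }
  pc <- prcomp(mat, center = TRUE, scale. = TRUE)
  flip <- if (pc$rotation[1, 1] < 0) -1 else 1
  structure(list(
    state = flip * as.numeric(pc$x[, 1]),
    explained_variance = pc$sdev^2 / sum(pc$sdev^2),
    loadings = tibble::tibble(variable = rownames(pc$rotation),
                              loading = flip * pc$rotation[, 1]),
    dropped = dropped
  ), class = "cuspra_pca")
}

#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: the input table, the column
#' mapping (either a single state column or a multivariate block to reduce
#' with PCA), gate thresholds, the horizontal weight and the output
#' directory. Exactly one of `state` and `state_block` must be given.
#'
#' @param input Path to a CSV/TSV file with a header row.
#' @param time,driver_a,driver_b Column names.
#' @param state Column name of the state variable, or `NULL` when
#'   `state_block` is used.
#' @param state_block Character vector of column names forming the
#'   multivariate block to reduce to PC1, or `NULL`.
#' @param out_dir Output directory (created if absent).
#' @param h_weight Horizontal weight for the resilience index.
#' @param level,r2_min,aicc_margin,cusp_frac_min Gate thresholds (see
#'   [gate()]).
#' @param swap_test Also fit the model with the two drivers' roles swapped
#'   and report both AICc values.
#' @param zscore_state,log_state Optional state transforms applied before
#'   fitting (off by default).
#' @param seed Seed for the fit restarts.
#' @return A list of class `cuspra_config`.
#' @export
cuspra_config <- function(input, time = "time", state = "state",
                          driver_a = "driver_a", driver_b = "driver_b",
                          state_block = NULL, out_dir = ".",
                          h_weight = 2, level = 0.05, r2_min = 0.3,
                          aicc_margin = 2, cusp_frac_min = 0.10,
                          swap_test = FALSE, zscore_state = FALSE,
                          log_state = FALSE, seed = 1L) {
  if (is.null(state) == is.null(state_block)) {
    abort("specify exactly one of `state` and `state_block`",
          class = "cuspra_config_error")
  }
  structure(list(input = input, time = time, state = state,
                 driver_a = driver_a, driver_b = driver_b,
                 state_block = state_block, out_dir = out_dir,
                 h_weight = h_weight, level = level, r2_min = r2_min,
                 aicc_margin = aicc_margin, cusp_frac_min = cusp_frac_min,
                 swap_test = swap_test, zscore_state = zscore_state,
                 log_state = log_state, seed = as.integer(seed)),
            class = "cuspra_config")
}

#' Run the full resilience-assessment pipeline
#'
#' Executes the four protocol steps on a file input: (i) read the table
#' and, for multivariate blocks, reduce to a PC1 state variable; (ii) fit
#' the stochastic cusp model plus the linear and logistic alternatives;
#' (iii) apply the four-criterion adequacy gate; (iv) when the gate passes,
#' compute and write the resilience series. Written artifacts (under
#' `config$out_dir`): `fit_report.json` (coefficients, likelihoods, AICc
#' table, gate inputs), `observations.csv` (per-observation canonical
#' values and discriminant), and on gate pass `resilience.csv`,
#' `resilience_summary.json` and `interpretation.txt`. When the gate fails
#' the resilience files are deliberately not produced (the system's
#' dynamics are not cusp-like, so the indicator would be meaningless) and
#' the gate diagnostics are written instead.
#'
#' @param config A [cuspra_config()].
#' @return Invisibly, a list with `status` (0 = gate passed and resilience
#'   written, 3 = gate failed), `gate`, `fit`, `resilience` (or `NULL`) and
#'   `paths`. Input and configuration problems raise errors of class
#'   `cuspra_input_error` / `cuspra_config_error`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cuspra_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  raw <- if (!file.exists(config$input)) {
    abort(paste0("cannot read input file: ", config$input),
          class = "cuspra_input_error")
  } else {
    delim <- if (grepl("\\.(tsv|txt)$", config$input, ignore.case = TRUE))
      "\t" else ","
    readr::read_delim(config$input, delim = delim, show_col_types = FALSE,
                      progress = FALSE)
  }

  pca <- NULL
  if (!is.null(config$state_block)) {
    missing_cols <- setdiff(config$state_block, names(raw))
    if (length(missing_cols) > 0) {
      abort(paste("state block column(s) not found:",
                  paste(missing_cols, collapse = ", ")),
            class = "cuspra_config_error")
    }
    pca <- reduce_to_state(raw[config$state_block])
    raw$.state <- pca$state
    state_col <- ".state"
  } else {
    state_col <- config$state
  }
  needed <- c(config$time, state_col, config$driver_a, config$driver_b)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste("column(s) not found in input:",
                paste(missing_cols, collapse = ", ")),
          class = "cuspra_config_error")
  }
  dat <- cusp_data(tibble::tibble(
    time = raw[[config$time]], state = raw[[state_col]],
    driver_a = raw[[config$driver_a]], driver_b = raw[[config$driver_b]]
  ))
  if (config$log_state) {
    if (any(dat$state <= 0)) {
      abort("log transform requires a strictly positive state",
            class = "cuspra_config_error")
    }
    dat$state <- log(dat$state)
  }
  if (config$zscore_state) dat$state <- as.numeric(scale(dat$state))

  set.seed(config$seed)
  fit <- fit_cusp(dat, seed = config$seed)
  lin <- fit_linear(dat)
  logi <- fit_logistic(dat, seed = config$seed)
  g <- gate(fit, lin, logi, level = config$level, r2_min = config$r2_min,
            aicc_margin = config$aicc_margin,
            cusp_frac_min = config$cusp_frac_min)

  swap <- NULL
  if (config$swap_test) {
    swapped <- dat
    swapped$driver_a <- dat$driver_b
    swapped$driver_b <- dat$driver_a
    sfit <- tryCatch(fit_cusp(swapped, seed = config$seed),
                     error = function(e) NULL)
    swap <- list(original_aicc = fit$aicc,
                 swapped_aicc = if (is.null(sfit)) NA_real_ else sfit$aicc)
  }

  paths <- list(
    fit_report = file.path(config$out_dir, "fit_report.json"),
    observations = file.path(config$out_dir, "observations.csv"),
    resilience = file.path(config$out_dir, "resilience.csv"),
    resilience_summary = file.path(config$out_dir, "resilience_summary.json"),
    interpretation = file.path(config$out_dir, "interpretation.txt")
  )

  report <- list(
    coefficients = as.list(fit$coefficients),
    coefficients_raw = as.list(fit$coefficients_raw),
    loglik = fit$loglik,
    aicc = list(cusp = fit$aicc, linear = lin$aicc, logistic = logi$aicc),
    gate = as.list(dplyr::select(g, -"reason")),
    gate_reason = if (is.na(g$reason)) NULL else g$reason,
    pca = if (is.null(pca)) NULL else
      list(explained_variance = pca$explained_variance[1],
           loadings = as.list(setNames(pca$loadings$loading,
                                       pca$loadings$variable))),
    swap_test = swap,
    seed = config$seed
  )
  jsonlite::write_json(report, paths$fit_report, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  readr::write_csv(augment(fit), paths$observations)

  if (!g$overall) {
    unlink(c(paths$resilience, paths$resilience_summary,
             paths$interpretation))
    message("adequacy gate failed (", g$reason,
            "); this system's dynamics cannot be summarised by the cusp ",
            "resilience indicator, so no resilience series was written")
    return(invisible(list(status = 3L, gate = g, fit = fit,
                          resilience = NULL, paths = paths)))
  }

  res <- cuspra(fit, h_weight = config$h_weight)
  readr::write_csv(tibble::as_tibble(res), paths$resilience)
  jsonlite::write_json(as.list(glance(res)), paths$resilience_summary,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(interpretation_text(res), paths$interpretation)
  invisible(list(status = 0L, gate = g, fit = fit, resilience = res,
                 paths = paths))
}

interpretation_text <- function(res) {
  g <- glance(res)
  lines <- c(
    sprintf("Resilience assessment over %d time steps.", g$nobs),
    sprintf("Minimum RA %.3f, median RA %.3f, maximum RA %.3f.",
            g$min_RA, g$median_RA, g$max_RA),
    sprintf("%d of %d observations lie inside the cusp (multiple-equilibria) area.",
            g$n_inside_cusp, g$nobs)
  )
  last <- res$RA[nrow(res)]
  lines <- c(lines, if (last < 0.3) {
    "Most recent state: LOW resilience - the system sits close to a tipping point; small changes in the drivers can trigger a discontinuous shift."
  } else if (last > 0.7) {
    "Most recent state: HIGH resilience - the system responds approximately linearly and is far from a tipping point."
  } else {
    "Most recent state: INTERMEDIATE resilience - the system is outside the immediate tipping region but not safely linear."
  })
  lines
}
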