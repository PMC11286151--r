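#' Corrected Akaike Information Criterion
#'
#' \eqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)}; the small-sample correction
#' vanishes as \eqn{n \to \infty}.
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Number of estimated parameters \eqn{k}.
#' @param n_obs Number of observations \eqn{n}; must exceed `n_params + 1`.
#' @return The AICc value.
#' @examples
#' aicc(0, 1, 100)
#' @export
aicc <- function(loglik, n_params, n_obs) {
  stopifnot(is.finite(loglik), n_params >= 0)
  if (n_obs <= n_params + 1) {
    abort("`n_obs` must exceed `n_params` + 1 for the AICc correction",
          class = "cuspra_domain_error")
  }
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) / (n_obs - n_params - 1)
}

#' Fit the stochastic cusp model to a state/driver time series
#'
#' Maximum-likelihood fit of the stationary cusp density with linear
#' submodels for the two control factors,
#' \deqn{\alpha_t = \alpha_0 + \alpha_1 a_t, \quad
#'       \beta_t = \beta_0 + \beta_1 b_t, \quad
#'       z_t = w_0 + w_1 y_t,}
#' where \eqn{y_t} is the observed state and \eqn{a_t, b_t} the two drivers
#' (z-scored internally before fitting; the scaling is recorded and undone
#' in the reported raw-scale coefficients). The log-likelihood is
#' \eqn{\sum_t \log f(z_t \mid \alpha_t, \beta_t) + T \log|w_1|}, the last
#' term being the Jacobian of the canonical state transform. The likelihood
#' surface is multimodal, so the deterministic regression-based start is
#' supplemented with random restarts and the best optimum is kept. The sign
#' indeterminacy \eqn{(w, \alpha) \to (-w, -\alpha)} is resolved by forcing
#' \eqn{w_1 > 0}.
#'
#' @param data A data frame or [cusp_data()] table with columns `time`,
#'   `state`, `driver_a` (asymmetry driver) and `driver_b` (bifurcation
#'   driver).
#' @param n_starts Total number of optimisation starts (1 deterministic +
#'   `n_starts - 1` jittered).
#' @param seed Optional integer seed for the restart jitter.
#' @param grad_tol Largest absolute log-likelihood gradient component
#'   tolerated at the reported optimum before the fit is flagged
#'   non-converged.
#' @return An object of class `cusp_fit`: a list with the six canonical
#'   coefficients, raw-driver-scale coefficients, per-observation canonical
#'   series (`alpha`, `beta`, `z`, `delta`), `loglik`, `aicc`, `pseudo_r2`,
#'   `frac_in_cusp`, `w1_pvalue` and a `converged` flag. Use [tidy()],
#'   [glance()] and [augment()] to extract tibbles.
#' @seealso [fit_linear()], [fit_logistic()], [gate()], [cuspra()]
#' @export
fit_cusp <- function(data, n_starts = 5, seed = NULL, grad_tol = 1e-3) {
  data <- as_cusp_data(data)
  y <- data$state
  T_obs <- nrow(data)
  sc_a <- c(mean = mean(data$driver_a), sd = sd(data$driver_a))
  sc_b <- c(mean = mean(data$driver_b), sd = sd(data$driver_b))
  xa <- (data$driver_a - sc_a[["mean"]]) / sc_a[["sd"]]
  xb <- (data$driver_b - sc_b[["mean"]]) / sc_b[["sd"]]

  # fixed quadrature grid wide enough for any control magnitudes the
  # optimizer visits from these starts
  grid <- quad_nodes(amax = 500, bmax = 60, h = 0.05)

  last <- new.env(parent = emptyenv())
  objective <- function(par) {
    res <- cusp_negloglik(par, y, xa, xb, grid$nodes, grid$h)
    last$par <- par
    last$res <- res
    res
  }
  fn <- function(par) objective(par)$value
  gr <- function(par) {
    if (!is.null(last$par) && identical(par, last$par)) last$res$gradient
    else objective(par)$gradient
  }

  starts <- fit_cusp_starts(y, xa, xb, n_starts, seed)
  best <- NULL
  for (par0 in starts) {
    opt <- tryCatch(
      optim(par0, fn, gr, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    abort("cusp likelihood optimisation failed from every start",
          class = "cuspra_fit_error")
  }

  par <- best$par
  if (par[6] < 0) par <- par * c(-1, -1, 1, 1, -1, -1)  # canonical w1 > 0
  names(par) <- c("alpha0", "alpha1", "beta0", "beta1", "w0", "w1")

  g <- gr(par)
  converged <- best$convergence == 0 && max(abs(g)) < grad_tol * (1 + abs(best$value))

  alpha_t <- par[["alpha0"]] + par[["alpha1"]] * xa
  beta_t <- par[["beta0"]] + par[["beta1"]] * xb
  z_t <- par[["w0"]] + par[["w1"]] * y
  delta_t <- cardan_discriminant(alpha_t, beta_t)
  loglik <- -best$value
  k <- 6L

  modes <- nearest_mode(z_t, alpha_t, beta_t)
  pseudo_r2 <- 1 - var(z_t - modes) / var(z_t)

  # Wald covariance from the observed information
  vc <- tryCatch({
    H <- optimHess(par, fn, gr)
    solve(H)
  }, error = function(e) NULL)
  se <- if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
    sqrt(diag(vc))
  } else {
    rep(NA_real_, 6)
  }
  names(se) <- names(par)
  w1_pvalue <- if (is.na(se[["w1"]])) NA_real_ else
    2 * pnorm(-abs(par[["w1"]] / se[["w1"]]))

  raw <- c(
    alpha0 = par[["alpha0"]] - par[["alpha1"]] * sc_a[["mean"]] / sc_a[["sd"]],
    alpha1 = par[["alpha1"]] / sc_a[["sd"]],
    beta0 = par[["beta0"]] - par[["beta1"]] * sc_b[["mean"]] / sc_b[["sd"]],
    beta1 = par[["beta1"]] / sc_b[["sd"]],
    w0 = par[["w0"]],
    w1 = par[["w1"]]
  )

  structure(list(
    coefficients = par,
    coefficients_raw = raw,
    std_errors = se,
    vcov = vc,
    driver_scaling = list(driver_a = sc_a, driver_b = sc_b),
    data = data,
    alpha = as.numeric(alpha_t),
    beta = as.numeric(beta_t),
    z = as.numeric(z_t),
    delta = as.numeric(delta_t),
    loglik = loglik,
    n_params = k,
    n_obs = T_obs,
    aicc = aicc(loglik, k, T_obs),
    pseudo_r2 = as.numeric(pseudo_r2),
    frac_in_cusp = mean(delta_t <= 0),
    w1_pvalue = as.numeric(w1_pvalue),
    converged = converged,
    max_abs_grad = max(abs(g))
  ), class = "cusp_fit")
}

fit_cusp_starts <- function(y, xa, xb, n_starts, seed) {
  if (!is.null(seed)) set.seed(seed)
  z0 <- as.numeric(scale(y))
  w1 <- 1 / sd(y)
  w0 <- -mean(y) / sd(y)
  a <- coef(lm(z0 ~ xa))
  b1 <- coef(lm(I(z0^2) ~ xb))[2]
  det_start <- c(a[1], a[2], 0, b1, w0, w1)
  starts <- list(det_start,
                 det_start + c(0, 0, 1.5, 0, 0, 0),   # bimodal-leaning
                 det_start + c(0, 0, -1.5, 0, 0, 0))  # linear-leaning
  n_extra <- max(0, n_starts - length(starts))
  scales <- c(0.5, 0.5, 0.75, 0.5, 0.5, 0.4 * w1)
  extra <- replicate(n_extra, det_start + rnorm(6) * scales, simplify = FALSE)
  c(starts[seq_len(min(n_starts, length(starts)))], extra)
}

#' @export
print.cusp_fit <- function(x, ...) {
  cat("Stochastic cusp model fit (stationary-density MLE)\n")
  cat(sprintf("  observations: %d   converged: %s\n", x$n_obs, x$converged))
  cat("  canonical coefficients (z-scored drivers):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  logLik %.3f   AICc %.3f   pseudo-R2 %.3f\n",
              x$loglik, x$aicc, x$pseudo_r2))
  cat(sprintf("  fraction of points in cusp area: %.3f   w1 p-value: %.4g\n",
              x$frac_in_cusp, x$w1_pvalue))
  invisible(x)
}

#' @describeIn fit_cusp Coefficient table (canonical and raw-driver scale)
#'   with Wald standard errors and p-values.
#' @param x,object A `cusp_fit`.
#' @param ... Unused.
#' @export
tidy.cusp_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$std_errors
  stat <- est / se
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    estimate_raw = unname(x$coefficients_raw),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * pnorm(-abs(unname(stat)))
  )
}

#' @describeIn fit_cusp One-row model summary.
#' @export
glance.cusp_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    AICc = x$aicc,
    pseudo_r2 = x$pseudo_r2,
    frac_in_cusp = x$frac_in_cusp,
    w1_pvalue = x$w1_pvalue,
    converged = x$converged,
    nobs = x$n_obs,
    n_params = x$n_params
  )
}

#' @describeIn fit_cusp Per-observation table: data plus fitted canonical
#'   values (`alpha`, `beta`, `z`) and Cardan's discriminant (`delta`).
#' @export
augment.cusp_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$data),
    tibble::tibble(alpha = x$alpha, beta = x$beta, z = x$z, delta = x$delta,
                   inside_cusp = x$delta <= 0)
  )
}
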