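#' Linear alternative model
#'
#' Ordinary least-squares fit of the state on both drivers,
#' \eqn{y_t = g_0 + g_1 a_t + g_2 b_t + \epsilon}, with Gaussian errors.
#' This is the null alternative in the adequacy gate: the cusp model must
#' beat its AICc by a margin before a resilience assessment is warranted.
#' Drivers are z-scored, matching the cusp fit, so AICc values are
#' comparable (the state is left on its observed scale in both models).
#'
#' @inheritParams fit_cusp
#' @return An object of class `cusp_linear_fit` with elements
#'   `coefficients` (g0, g1, g2), `sigma` (residual scale, MLE),
#'   `r_squared`, `loglik`, `aicc` (parameter count 4: three coefficients
#'   plus the residual scale) and a `collinear` flag.
#' @export
fit_linear <- function(data) {
  data <- as_cusp_data(data)
  xa <- as.numeric(scale(data$driver_a))
  xb <- as.numeric(scale(data$driver_b))
  y <- data$state
  n <- length(y)
  fit <- lm(y ~ xa + xb)
  cf <- coef(fit)
  collinear <- anyNA(cf) || abs(cor(xa, xb)) > 0.999
  cf[is.na(cf)] <- 0
  res <- y - (cf[1] + cf[2] * xa + cf[3] * xb)
  sigma_mle <- sqrt(mean(res^2))
  loglik <- sum(stats::dnorm(res, 0, sigma_mle, log = TRUE))
  k <- 4L
  structure(list(
    coefficients = setNames(cf, c("g0", "g1", "g2")),
    sigma = sigma_mle,
    r_squared = summary(fit)$r.squared,
    loglik = loglik,
    n_params = k,
    n_obs = n,
    aicc = aicc(loglik, k, n),
    collinear = collinear,
    lm_fit = fit
  ), class = "cusp_linear_fit")
}

#' @export
print.cusp_linear_fit <- function(x, ...) {
  cat("Linear alternative (OLS, Gaussian MLE)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  R2 %.3f   logLik %.3f   AICc %.3f\n",
              x$r_squared, x$loglik, x$aicc))
  invisible(x)
}

#' @describeIn fit_linear One-row summary.
#' @param x A fitted alternative model.
#' @param ... Unused.
#' @export
glance.cusp_linear_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AICc = x$aicc, r.squared = x$r_squared,
                 sigma = x$sigma, collinear = x$collinear, nobs = x$n_obs)
}

#' Logistic alternative model
#'
#' Nonlinear but continuous alternative: the canonical state follows a
#' logistic response to the control factors,
#' \deqn{z_t = \frac{1}{1 + e^{-\alpha_t/\beta_t^2}} + \epsilon,}
#' with the same linear submodels \eqn{\alpha_t, \beta_t} in the two
#' drivers as the cusp fit. On the observed scale this is
#' \eqn{y_t = u_0 + u_1\,\mathrm{logit}^{-1}(\alpha_t/\beta_t^2) + \epsilon}
#' (\eqn{u_0, u_1} reparametrise the canonical state transform), fitted by
#' Gaussian maximum likelihood with multi-start BFGS. \eqn{\beta_t^2} is
#' floored at `beta_floor` so the exponent stays finite when a submodel
#' crosses zero. The gate compares the cusp against the linear model only;
#' this fit is reported for information.
#'
#' @inheritParams fit_cusp
#' @param n_starts Number of optimisation starts.
#' @param beta_floor Lower bound applied to \eqn{\beta_t^2}.
#' @param seed Optional seed for the restart jitter.
#' @return An object of class `cusp_logistic_fit` with the six canonical
#'   coefficients, `sigma`, `loglik`, `aicc` (parameter count 7), and
#'   `converged`/`degenerate` flags.
#' @export
fit_logistic <- function(data, n_starts = 6, beta_floor = 1e-3, seed = NULL) {
  if (is.data.frame(data) && "state" %in% names(data) &&
      sd(data$state) == 0) {
    return(structure(list(coefficients = NULL, loglik = NA_real_,
                          aicc = NA_real_, converged = FALSE,
                          degenerate = TRUE, n_obs = nrow(data),
                          n_params = 7L),
                     class = "cusp_logistic_fit"))
  }
  data <- as_cusp_data(data)
  xa <- as.numeric(scale(data$driver_a))
  xb <- as.numeric(scale(data$driver_b))
  y <- data$state
  n <- length(y)
  predict_mu <- function(par) {
    al <- par[1] + par[2] * xa
    be2 <- pmax((par[3] + par[4] * xb)^2, beta_floor)
    par[5] + par[6] * plogis(al / be2)
  }
  sse <- function(par) {
    mu <- predict_mu(par)
    if (any(!is.finite(mu))) return(1e10)
    sum((y - mu)^2)
  }
  if (!is.null(seed)) set.seed(seed)
  a <- coef(lm(scale(y) ~ xa))
  det_start <- c(a[1], a[2], 1, 0.5, min(y), diff(range(y)))
  starts <- c(list(det_start),
              replicate(max(0, n_starts - 1),
                        det_start * runif(6, 0.5, 1.5) + rnorm(6, 0, 0.3),
                        simplify = FALSE))
  best <- NULL
  for (par0 in starts) {
    opt <- tryCatch(
      optim(par0, sse, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(structure(list(coefficients = NULL, loglik = NA_real_,
                          aicc = NA_real_, converged = FALSE,
                          degenerate = FALSE, n_obs = n, n_params = 7L),
                     class = "cusp_logistic_fit"))
  }
  par <- setNames(best$par, c("alpha0", "alpha1", "beta0", "beta1", "u0", "u1"))
  sigma_mle <- sqrt(best$value / n)
  loglik <- sum(stats::dnorm(y - predict_mu(par), 0, sigma_mle, log = TRUE))
  k <- 7L
  structure(list(
    coefficients = par,
    sigma = sigma_mle,
    fitted = predict_mu(par),
    loglik = loglik,
    n_params = k,
    n_obs = n,
    aicc = aicc(loglik, k, n),
    converged = best$convergence == 0,
    degenerate = FALSE,
    beta_floor = beta_floor
  ), class = "cusp_logistic_fit")
}

#' @export
print.cusp_logistic_fit <- function(x, ...) {
  cat("Logistic alternative (Gaussian MLE)\n")
  if (x$degenerate) {
    cat("  degenerate input (constant state)\n")
    return(invisible(x))
  }
  print(round(x$coefficients, 4))
  cat(sprintf("  logLik %.3f   AICc %.3f   converged: %s\n",
              x$loglik, x$aicc, x$converged))
  invisible(x)
}

#' @describeIn fit_logistic One-row summary.
#' @param x A fitted alternative model.
#' @param ... Unused.
#' @export
glance.cusp_logistic_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AICc = x$aicc,
                 sigma = if (is.null(x$sigma)) NA_real_ else x$sigma,
                 converged = x$converged, degenerate = x$degenerate,
                 nobs = x$n_obs)
}
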