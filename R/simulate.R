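#' Simulation scenario settings
#'
#' Bundle of generator settings for the validation ensembles: series length,
#' driver dynamics (AR(1) asymmetry driver, Gaussian bifurcation driver with
#' a scenario-controlled mean), and the Euler-Maruyama discretisation of the
#' cusp SDE used to produce the state variable.
#'
#' @param n_steps Observations per series (default 50).
#' @param ar1_coef Lag-1 coefficient of the asymmetry driver (default 0.9).
#' @param beta_mean Mean of the Gaussian bifurcation driver; the validation
#'   grid spans -2 (mostly linear) to 2 (mostly discontinuous).
#' @param beta_sd Standard deviation of the bifurcation driver (default 1).
#' @param n_replicates Replicates per scenario (default 10).
#' @param sde_dt Euler-Maruyama substep size.
#' @param sde_burnin Substeps integrated between successive observations.
#' @param sigma_z Diffusion scale of the cusp SDE. The default `sqrt(2)` is
#'   the canonical noise level: it makes the SDE's stationary law exactly
#'   the unit-scale cusp density that the fitting machinery estimates, so
#'   generating coefficients are recovered on their own scale (any other
#'   value is absorbed into the fitted canonical scaling).
#' @param method `"sde"` integrates the SDE continuously through time
#'   (retaining hysteresis); `"stationary"` draws each observation
#'   independently from the stationary density of its control point.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_steps = 50, ar1_coef = 0.9, beta_mean = 0,
                         beta_sd = 1, n_replicates = 10, sde_dt = 0.01,
                         sde_burnin = 100, sigma_z = sqrt(2),
                         method = c("sde", "stationary")) {
  method <- match.arg(method)
  stopifnot(n_steps >= 2, abs(ar1_coef) < 1, beta_sd > 0,
            n_replicates >= 1, sde_dt > 0, sde_burnin >= 1, sigma_z >= 0)
  structure(list(n_steps = n_steps, ar1_coef = ar1_coef,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 n_replicates = n_replicates, sde_dt = sde_dt,
                 sde_burnin = sde_burnin, sigma_z = sigma_z,
                 method = method),
            class = "sim_scenario")
}

#' Stationary AR(1) asymmetry-driver series
#'
#' AR(1) process with unit innovation variance, initialised from its
#' stationary distribution (variance \eqn{1/(1-\phi^2)}), emulating a
#' strongly autocorrelated anthropogenic driver such as fishing pressure.
#'
#' @param n Series length.
#' @param coef AR(1) coefficient, `|coef| < 1`.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_alpha_ar1 <- function(n, coef = 0.9, seed = NULL) {
  if (abs(coef) >= 1) {
    abort("|coef| must be < 1 for a stationary AR(1)",
          class = "cuspra_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, 1 / sqrt(1 - coef^2))
  innov <- rnorm(n - 1)
  for (t in seq_len(n - 1)) x[t + 1] <- coef * x[t] + innov[t]
  x
}

#' Gaussian bifurcation-driver series
#'
#' i.i.d. normal draws emulating a climate driver (e.g. temperature) whose
#' mean sets the scenario's level of nonlinearity.
#'
#' @param n Series length.
#' @param mean,sd Normal parameters; `sd > 0`.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_beta_normal <- function(n, mean = 0, sd = 1, seed = NULL) {
  if (sd <= 0) abort("`sd` must be > 0", class = "cuspra_domain_error")
  if (!is.null(seed)) set.seed(seed)
  rnorm(n, mean, sd)
}

#' State variable from the cusp stochastic differential equation
#'
#' Integrates \eqn{dz = (-z^3 + \beta_t z + \alpha_t)\,dt + \sigma_z dW_t}
#' with the Euler-Maruyama scheme: between successive observations the
#' latent state evolves for `sde_burnin` substeps of size `sde_dt` under the
#' control values of the arriving observation, and the end point is
#' recorded. Continuing the latent state through time preserves hysteresis
#' (the state tracks its current branch until the fold is crossed).
#' `method = "stationary"` instead draws each observation independently
#' from the stationary density at \eqn{(\alpha_t, \beta_t)}.
#'
#' The integration restarts with a halved substep (up to four times) if the
#' trajectory leaves `|z| > 1000`.
#'
#' @param alpha,beta Control-factor series of equal length.
#' @param scenario A [sim_scenario()] (fields `sde_dt`, `sde_burnin`,
#'   `sigma_z`, `method` are used).
#' @param z0 Starting state; defaults to the stable equilibrium of the
#'   first control point nearest zero.
#' @param seed Optional integer seed.
#' @return Numeric vector of sampled states, same length as `alpha`.
#' @export
gen_cusp_state <- function(alpha, beta, scenario = sim_scenario(),
                           z0 = NULL, seed = NULL) {
  stopifnot(length(alpha) == length(beta))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(z0)) {
    m <- density_modes(alpha[1], beta[1])
    z0 <- m[which.min(abs(m))]
  }
  if (scenario$method == "stationary") {
    return(vapply(seq_along(alpha), function(t) {
      rcusp(1, alpha[t], beta[t])
    }, numeric(1)))
  }
  for (attempt in 0:4) {
    dt <- scenario$sde_dt / 2^attempt
    nsub <- scenario$sde_burnin * 2^attempt
    z <- euler_maruyama(alpha, beta, z0, dt, nsub, scenario$sigma_z)
    if (all(is.finite(z)) && max(abs(z)) <= 1000) return(z)
  }
  abort("cusp SDE integration blew up even after step-size halving",
        class = "cuspra_domain_error")
}

euler_maruyama <- function(alpha, beta, z0, dt, nsub, sigma_z) {
  n <- length(alpha)
  out <- numeric(n)
  z <- z0
  sq <- sigma_z * sqrt(dt)
  noise <- if (sigma_z > 0) matrix(rnorm(n * nsub), nsub, n) else
    matrix(0, nsub, n)
  for (t in seq_len(n)) {
    a <- alpha[t]
    b <- beta[t]
    for (k in seq_len(nsub)) {
      z <- z + (-z^3 + b * z + a) * dt + sq * noise[k, t]
      if (!is.finite(z) || abs(z) > 1000) {
        out[t:n] <- Inf
        return(out)
      }
    }
    out[t] <- z
  }
  out
}

#' Random draws from the stationary cusp density
#'
#' Inverse-CDF sampling on the quadrature grid of [cusp_density()].
#'
#' @param n Number of draws.
#' @param alpha,beta Scalar control-factor values.
#' @return Numeric vector of length `n`.
#' @export
rcusp <- function(n, alpha, beta) {
  grid <- quad_nodes(abs(alpha), abs(beta))
  e <- alpha * grid$nodes + beta * grid$nodes^2 / 2 - grid$nodes^4 / 4
  w <- exp(e - max(e))
  cdf <- cumsum(w) / sum(w)
  stats::approx(cdf, grid$nodes, runif(n), ties = "ordered", rule = 2)$y
}

#' Chaotic logistic-map series
#'
#' Iterates \eqn{x_{t+1} = r x_t (1 - x_t)}; at the default `r = 3.9` the
#' orbit is chaotic on (0, 1). Used as a deterministic-chaos null for the
#' adequacy gate.
#'
#' @param n Series length.
#' @param r Control parameter (default 3.9).
#' @param x0 Starting value in (0, 1); drawn uniformly from (0.1, 0.9) when
#'   `NULL`.
#' @param seed Optional integer seed (used for the random `x0`).
#' @return Numeric vector in (0, 1).
#' @export
gen_logistic_map <- function(n, r = 3.9, x0 = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- runif(1, 0.1, 0.9)
  if (x0 <= 0 || x0 >= 1) {
    abort("`x0` must lie strictly inside (0, 1)", class = "cuspra_domain_error")
  }
  x <- numeric(n)
  x[1] <- x0
  for (t in seq_len(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  x
}

#' Periodic series with additive noise
#'
#' \eqn{\sin(2\pi t / \mathrm{period}) + N(0, \mathrm{noise\_sd}^2)} for
#' \eqn{t = 0, \dots, n - 1}. Used as a periodic null for the adequacy gate.
#'
#' @param n Series length.
#' @param period Cycle length in time steps (default 10).
#' @param noise_sd Noise standard deviation (default 0.3).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_periodic <- function(n, period = 10, noise_sd = 0.3, seed = NULL) {
  stopifnot(period >= 2, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n) - 1
  sin(2 * pi * t / period) + rnorm(n, 0, noise_sd)
}

#' Gaussian white-noise series
#'
#' i.i.d. standard normal draws; the random null for the adequacy gate.
#'
#' @param n Series length.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_random <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  rnorm(n)
}

#' Single simulated cusp dataset
#'
#' Convenience wrapper pairing an AR(1) asymmetry driver and a Gaussian
#' bifurcation driver with a state generated from the cusp SDE under those
#' controls. The canonical control factors equal
#' `alpha0 + alpha1 * driver_a` and `beta0 + beta1 * driver_b`, so the
#' default coefficients make the drivers themselves the control factors.
#'
#' @param n_steps,beta_mean,scenario Scenario settings (any of the first
#'   two override the scenario's fields).
#' @param coefs Named numeric vector of generating coefficients
#'   (`alpha0`, `alpha1`, `beta0`, `beta1`, `w0`, `w1`); the state stored in
#'   the dataset is `(z - w0)/w1` for latent canonical `z`.
#' @param seed Optional integer seed.
#' @return A `cusp_data` tibble.
#' @export
sim_cusp_dataset <- function(n_steps = NULL, beta_mean = NULL,
                             scenario = sim_scenario(),
                             coefs = c(alpha0 = 0, alpha1 = 1, beta0 = 0,
                                       beta1 = 1, w0 = 0, w1 = 1),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(n_steps)) scenario$n_steps <- n_steps
  if (!is.null(beta_mean)) scenario$beta_mean <- beta_mean
  n <- scenario$n_steps
  da <- gen_alpha_ar1(n, scenario$ar1_coef)
  db <- gen_beta_normal(n, scenario$beta_mean, scenario$beta_sd)
  alpha <- coefs[["alpha0"]] + coefs[["alpha1"]] * da
  beta <- coefs[["beta0"]] + coefs[["beta1"]] * db
  z <- gen_cusp_state(alpha, beta, scenario)
  state <- (z - coefs[["w0"]]) / coefs[["w1"]]
  cusp_data(tibble::tibble(time = seq_len(n), state = state,
                           driver_a = da, driver_b = db))
}

#' Ensemble of simulated validation datasets
#'
#' Builds the replicate datasets used in the classification and hypothesis
#' experiments. Every dataset pairs a freshly simulated AR(1) asymmetry
#' driver and Gaussian bifurcation driver with a state series of the
#' requested kind: `"cusp"` states come from the cusp SDE driven by those
#' controls; `"chaotic"` (logistic map, r = 3.9), `"periodic"` (sine,
#' period 10, noise sd 0.3) and `"random"` (standard normal) states are
#' generated independently of the drivers and z-scored so all kinds enter
#' the gate on a comparable scale. Replicate seeds are spawned from the
#' master seed by one `sample.int(2^31 - 2)` draw per replicate.
#'
#' @param kind One of `"cusp"`, `"chaotic"`, `"periodic"`, `"random"`.
#' @param beta_means Scenario grid of bifurcation-driver means.
#' @param n_replicates Replicates per scenario level.
#' @param scenario A [sim_scenario()] carrying the remaining settings.
#' @param seed Optional master seed; fixes the whole ensemble.
#' @return A tibble with columns `kind`, `beta_mean`, `replicate`,
#'   `rep_seed` and a `data` list-column of `cusp_data` tibbles.
#' @export
build_ensemble <- function(kind = c("cusp", "chaotic", "periodic", "random"),
                           beta_means = -2:2, n_replicates = 10,
                           scenario = sim_scenario(), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  design <- tidyr::expand_grid(beta_mean = beta_means,
                               replicate = seq_len(n_replicates))
  design$rep_seed <- sample.int(2^31 - 2, nrow(design))
  design$data <- purrr::pmap(design, function(beta_mean, replicate, rep_seed) {
    set.seed(rep_seed)
    sc <- scenario
    sc$beta_mean <- beta_mean
    n <- sc$n_steps
    da <- gen_alpha_ar1(n, sc$ar1_coef)
    db <- gen_beta_normal(n, sc$beta_mean, sc$beta_sd)
    state <- switch(kind,
      cusp = gen_cusp_state(da, db, sc),
      chaotic = as.numeric(scale(gen_logistic_map(n))),
      periodic = as.numeric(scale(gen_periodic(n))),
      random = as.numeric(scale(gen_random(n)))
    )
    cusp_data(tibble::tibble(time = seq_len(n), state = state,
                             driver_a = da, driver_b = db))
  })
  tibble::add_column(design, kind = kind, .before = 1)
}
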