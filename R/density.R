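#' Stationary density of the canonical cusp process
#'
#' Density of the stationary distribution of the cusp stochastic
#' differential equation in canonical coordinates,
#' \deqn{f(z \mid \alpha, \beta) \propto \exp(\alpha z + \beta z^2/2 - z^4/4),}
#' normalised by numerical quadrature. \eqn{\alpha} (the asymmetry factor)
#' shifts probability mass between the low and high state; \eqn{\beta} (the
#' bifurcation factor) morphs the density from unimodal to bimodal.
#'
#' @param z Numeric vector of canonical state values.
#' @param alpha,beta Control-factor values (scalars, or vectors recycled
#'   against `z`).
#' @param log Return the log-density?
#' @return Numeric vector of (log-)density values.
#' @examples
#' cusp_density(0, alpha = 0, beta = 0)
#' integrate(cusp_density, -Inf, Inf, alpha = 1, beta = -2)
#' @export
cusp_density <- function(z, alpha, beta, log = FALSE) {
  if (!all(is.finite(alpha)) || !all(is.finite(beta))) {
    abort("`alpha` and `beta` must be finite", class = "cuspra_domain_error")
  }
  n <- max(length(z), length(alpha), length(beta))
  z <- rep_len(as.numeric(z), n)
  alpha <- rep_len(as.numeric(alpha), n)
  beta <- rep_len(as.numeric(beta), n)
  logN <- cusp_log_normalizer(alpha, beta)
  out <- alpha * z + beta * z^2 / 2 - z^4 / 4 - logN
  out[!is.finite(z)] <- -Inf
  if (log) out else exp(out)
}

# log of the quadrature normalizer, vectorized over (alpha, beta);
# the node span grows with the control magnitudes so the quartic tail is
# always negligible at the endpoints
cusp_log_normalizer <- function(alpha, beta) {
  grid <- quad_nodes(max(abs(alpha)), max(abs(beta)))
  cusp_quad_moments(alpha, beta, grid$nodes, grid$h)$logN
}

quad_nodes <- function(amax, bmax, h = 0.01) {
  L <- max(8, sqrt(2 * bmax) + 3, (4 * amax)^(1 / 3) + 3)
  n <- ceiling(L / h)
  list(nodes = seq(-n, n) * h, h = h)
}

#' Cardan's discriminant of the cusp equilibrium cubic
#'
#' \eqn{\delta = 27\alpha^2 - 4\beta^3}. Values \eqn{\delta \le 0} place the
#' control point inside the cusp (multiple-equilibria) area, where the state
#' follows discontinuous dynamics; \eqn{\delta > 0} corresponds to a single
#' equilibrium and continuous dynamics. The boundary \eqn{\delta = 0} is
#' counted as inside.
#'
#' @param alpha,beta Control-factor values (vectorised).
#' @return Numeric vector of discriminant values.
#' @examples
#' cardan_discriminant(0, 1)   # -4, inside the cusp area
#' cardan_discriminant(1, 0)   # 27, outside
#' @export
cardan_discriminant <- function(alpha, beta) {
  27 * alpha^2 - 4 * beta^3
}

#' Equilibria of the cusp deterministic skeleton
#'
#' Real roots of \eqn{-z^3 + \beta z + \alpha = 0}, the fixed points of the
#' drift of the cusp SDE. There are three roots (two stable, one unstable)
#' exactly when Cardan's discriminant is negative, and one when it is
#' positive; the boundary collapses two of them into a repeated root.
#'
#' @param alpha,beta Scalar control-factor values.
#' @return Sorted numeric vector of distinct real roots (length 1 to 3).
#' @examples
#' equilibria(0, 3)   # -sqrt(3), 0, sqrt(3)
#' equilibria(1, 0)   # 1
#' @export
equilibria <- function(alpha, beta) {
  stopifnot(length(alpha) == 1, length(beta) == 1,
            is.finite(alpha), is.finite(beta))
  # depressed cubic t^3 + p t + q with p = -beta, q = -alpha
  p <- -beta
  q <- -alpha
  delta <- cardan_discriminant(alpha, beta)
  if (delta < 0) {
    # three distinct real roots (trigonometric form; p < 0 is guaranteed)
    r <- 2 * sqrt(-p / 3)
    arg <- (3 * q) / (2 * p) * sqrt(-3 / p)
    arg <- min(1, max(-1, arg))
    theta <- acos(arg)
    roots <- r * cos(theta / 3 - 2 * pi * (0:2) / 3)
  } else if (delta > 0) {
    d <- sqrt(q^2 / 4 + p^3 / 27)
    roots <- cbrt(-q / 2 + d) + cbrt(-q / 2 - d)
  } else {
    if (p == 0) {
      roots <- 0
    } else {
      roots <- c(3 * q / p, -3 * q / (2 * p))
    }
  }
  sort(unique(roots))
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Modes of the stationary cusp density
#'
#' Local maxima of [cusp_density()], i.e. the stable equilibria of the
#' drift (roots of \eqn{-z^3 + \beta z + \alpha} at which the potential
#' curves upward, \eqn{3z^2 > \beta}). Used by the pseudo-R-squared, which
#' measures errors to the mode nearest each observation.
#'
#' @inheritParams equilibria
#' @return Sorted numeric vector of one or two modes.
#' @export
density_modes <- function(alpha, beta) {
  eq <- equilibria(alpha, beta)
  stable <- eq[3 * eq^2 - beta > 0]
  if (length(stable) == 0) stable <- eq[which.max(3 * eq^2 - beta)]
  stable
}

# mode of f(.|alpha, beta) nearest to each z; ties go to the lower mode
nearest_mode <- function(z, alpha, beta) {
  vapply(seq_along(z), function(t) {
    m <- density_modes(alpha[t], beta[t])
    d <- abs(z[t] - m)
    tied <- d <= min(d) * (1 + 1e-9) + 1e-12
    min(m[tied])
  }, numeric(1))
}
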