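#' Boundary of the cusp bifurcation set
#'
#' For a given bifurcation factor \eqn{\beta}, the asymmetry value at which
#' the fold opens: \eqn{\alpha_{bif} = 2(\beta/3)^{3/2}} for \eqn{\beta > 0}
#' and 0 otherwise (no fold exists at or below \eqn{\beta = 0}; the limit
#' from both sides agrees at 0).
#'
#' @param beta Bifurcation-factor values (vectorised).
#' @return Non-negative numeric vector.
#' @examples
#' bifurcation_boundary(3)    # 2
#' bifurcation_boundary(-1)   # 0
#' @export
bifurcation_boundary <- function(beta) {
  ifelse(beta > 0, 2 * (beta / 3)^1.5, 0)
}

#' Horizontal resilience component
#'
#' Signed distance of the asymmetry factor from the bifurcation set,
#' \eqn{H = |\alpha| - \alpha_{bif}(\beta)}: negative inside the
#' multiple-equilibria area (low resilience), positive outside.
#'
#' @param alpha,beta Control-factor values (vectorised).
#' @return Numeric vector.
#' @export
horizontal_component <- function(alpha, beta) {
  abs(alpha) - bifurcation_boundary(beta)
}

#' Vertical resilience component
#'
#' Distance to linearity, \eqn{V = -\beta}: positive where the response is
#' linear/continuous (\eqn{\beta < 0}), negative where it is folded.
#'
#' @param beta Bifurcation-factor values (vectorised).
#' @return Numeric vector.
#' @export
vertical_component <- function(beta) {
  -beta
}

#' Resilience index and indicator at a control-plane point
#'
#' Weighted average of the horizontal and vertical components,
#' \eqn{Ri = (h_w H + V)/(h_w + 1)} (the horizontal component is
#' double-weighted by default, stressing the asymmetry driver's role), then
#' squashed to the unit interval with
#' \eqn{RA = (\tanh(Ri) + 1)/2}. \eqn{RA} near 0 means the system sits in
#' or near the multiple-equilibria area and is close to a tipping point;
#' near 1 means it responds linearly far from the fold.
#'
#' @param alpha,beta Control-factor values (vectorised).
#' @param h_weight Weight on the horizontal component; the published
#'   default is 2.
#' @return A tibble with columns `Ri` and `RA`.
#' @examples
#' resilience_index(0, 0)        # Ri 0, RA 0.5
#' resilience_index(0, 3)        # Ri -7/3
#' @export
resilience_index <- function(alpha, beta, h_weight = 2) {
  stopifnot(is.numeric(h_weight), length(h_weight) == 1, h_weight > 0)
  if (!all(is.finite(alpha)) || !all(is.finite(beta))) {
    abort("`alpha` and `beta` must be finite", class = "cuspra_domain_error")
  }
  H <- horizontal_component(alpha, beta)
  V <- vertical_component(beta)
  Ri <- (h_weight * H + V) / (h_weight + 1)
  tibble::tibble(Ri = Ri, RA = (tanh(Ri) + 1) / 2)
}

#' Resilience assessment of a fitted cusp model
#'
#' Applies [resilience_index()] to every observation's fitted control-plane
#' position \eqn{(\alpha_t, \beta_t)}. The indicator depends only on the
#' control factors, not on the state value itself. The fit must have
#' converged, and should have passed the adequacy [gate()] before its
#' resilience series is interpreted.
#'
#' @param fit A converged [fit_cusp()] object.
#' @param h_weight Weight on the horizontal component (default 2).
#' @return A tibble of class `cuspra_resilience` with one row per
#'   observation: `time`, `alpha`, `beta`, `H`, `V`, `Ri`, `RA` and
#'   `inside_cusp` (Cardan's discriminant at or below zero).
#' @examples
#' \donttest{
#' dat <- sim_cusp_dataset(beta_mean = 2, seed = 1)
#' fit <- fit_cusp(dat, seed = 1)
#' res <- cuspra(fit)
#' summary(res$RA)
#' }
#' @export
cuspra <- function(fit, h_weight = 2) {
  stopifnot(inherits(fit, "cusp_fit"))
  if (!isTRUE(fit$converged)) {
    abort("refusing to compute resilience from a non-converged cusp fit",
          class = "cuspra_fit_error")
  }
  ri <- resilience_index(fit$alpha, fit$beta, h_weight = h_weight)
  out <- tibble::tibble(
    time = fit$data$time,
    alpha = fit$alpha,
    beta = fit$beta,
    H = horizontal_component(fit$alpha, fit$beta),
    V = vertical_component(fit$beta),
    Ri = ri$Ri,
    RA = ri$RA,
    inside_cusp = fit$delta <= 0
  )
  class(out) <- c("cuspra_resilience", class(out))
  attr(out, "h_weight") <- h_weight
  attr(out, "state") <- fit$data$state
  out
}

#' @describeIn cuspra One-row summary of a resilience series (minimum and
#'   median RA, time steps inside the cusp area).
#' @param x A `cuspra_resilience` tibble.
#' @param ... Unused.
#' @export
glance.cuspra_resilience <- function(x, ...) {
  tibble::tibble(
    min_RA = min(x$RA),
    median_RA = stats::median(x$RA),
    max_RA = max(x$RA),
    n_inside_cusp = sum(x$inside_cusp),
    frac_inside_cusp = mean(x$inside_cusp),
    nobs = nrow(x)
  )
}
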