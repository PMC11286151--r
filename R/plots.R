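#' Control-plane coordinates of the bifurcation set
#'
#' Samples the cusp-area boundary \eqn{|\alpha| = 2(\beta/3)^{3/2}} on a
#' grid of \eqn{\beta} values, ready for shading the instability region in
#' external plots.
#'
#' @param beta_max Largest \eqn{\beta} sampled.
#' @param n Number of grid points.
#' @return A tibble with columns `beta`, `alpha_low`, `alpha_high`.
#' @export
bifurcation_set_grid <- function(beta_max = 5, n = 200) {
  beta <- seq(0, beta_max, length.out = n)
  ab <- bifurcation_boundary(beta)
  tibble::tibble(beta = beta, alpha_low = -ab, alpha_high = ab)
}

#' Control-plane plot of a resilience series
#'
#' Plots each observation at its fitted control-plane position
#' \eqn{(\alpha_t, \beta_t)}, coloured by the resilience indicator, over
#' the shaded cusp (multiple-equilibria) area.
#'
#' @param object A [cuspra()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cuspra_resilience <- function(object, ...) {
  bmax <- max(3, max(object$beta) * 1.1)
  cusp_area <- bifurcation_set_grid(beta_max = bmax)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$alpha, y = .data$beta)) +
    ggplot2::geom_polygon(
      data = tibble::tibble(
        alpha = c(cusp_area$alpha_low, rev(cusp_area$alpha_high)),
        beta = c(cusp_area$beta, rev(cusp_area$beta))
      ),
      ggplot2::aes(x = .data$alpha, y = .data$beta),
      inherit.aes = FALSE, fill = "lightblue", alpha = 0.5
    ) +
    ggplot2::geom_path(colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$RA), size = 2) +
    ggplot2::scale_colour_gradient(low = "deeppink3", high = "seagreen",
                                   limits = c(0, 1)) +
    ggplot2::labs(x = expression(alpha ~ "(asymmetry factor)"),
                  y = expression(beta ~ "(bifurcation factor)"),
                  colour = "RA") +
    ggplot2::theme_minimal()
}

#' Resilience time line
#'
#' RA against time, with points inside the cusp area highlighted.
#'
#' @param res A [cuspra()] result.
#' @return A ggplot object.
#' @export
plot_resilience_timeline <- function(res) {
  stopifnot(inherits(res, "cuspra_resilience"))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$time, y = .data$RA)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$RA,
                                     shape = .data$inside_cusp), size = 2) +
    ggplot2::scale_colour_gradient(low = "deeppink3", high = "seagreen",
                                   limits = c(0, 1)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "resilience (RA)",
                  shape = "inside cusp area") +
    ggplot2::theme_minimal()
}

#' Control-plane plot of a cusp fit
#'
#' @param object A [fit_cusp()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cusp_fit <- function(object, ...) {
  res <- cuspra(object)
  autoplot(res)
}

#' Minimum resilience by scenario level
#'
#' Box plot of the per-replicate minimum RA against the scenario mean of
#' the bifurcation driver, from a [hypothesis_experiment()].
#'
#' @param object A `cuspra_hypotheses` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cuspra_hypotheses <- function(object, ...) {
  ggplot2::ggplot(object$min_ra,
                  ggplot2::aes(x = factor(.data$beta_mean), y = .data$min_RA)) +
    ggplot2::geom_boxplot(fill = "seagreen", alpha = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = expression("scenario mean of" ~ beta),
                  y = "minimum RA per replicate") +
    ggplot2::theme_minimal()
}
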