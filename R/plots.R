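#' Plot a swelling trajectory
#'
#' Shows the dimensionless axis deformations `zeta = a(t)/a(0) - 1` and
#' `xi = c(t)/c(0) - 1` against time.
#'
#' @param object A `swelling_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swelling_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time_s", "zeta", "xi"),
    c("zeta", "xi"),
    names_to = "axis", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value, colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "time (s)", y = "relative axis deformation",
      colour = NULL,
      title = "Swelling dynamics",
      subtitle = "zeta: equatorial axis, xi: polar axis"
    ) +
    ggplot2::theme_minimal()
}

#' Plot saturated volume and area across a concentration sweep
#'
#' @param sweep Output of [sweep_swelling()].
#' @return A ggplot object with saturated volume and surface area versus the
#'   initial internal concentration.
#' @export
plot_sweep <- function(sweep) {
  df <- tidyr::pivot_longer(
    dplyr::select(sweep, "conc_mM", "V_sat_um3", "S_sat_um2"),
    c("V_sat_um3", "S_sat_um2"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$conc_mM, .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "initial internal concentration (mM)", y = NULL,
      title = "Saturated cell volume and surface area"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the shape-equation residual of a bending solution
#'
#' Re-evaluates the Euler--Lagrange residual of the fitted solution over its
#' shape and plots it against the polar angle.
#'
#' @param object A `bending_solution`.
#' @param n_samples Sampling resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bending_solution <- function(object, n_samples = 200, ...) {
  fld <- curvature_field(object$shape, n_samples)
  res <- el_residual(fld, object$params, lam = object$lam, dp = object$dp)
  ggplot2::ggplot(res, ggplot2::aes(.data$theta, .data$residual)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = "polar angle (rad)", y = "shape-equation residual (Pa)",
      title = sprintf(
        "dp = %.4g Pa, lambda = %.4g N/m (RMS %.3g Pa)",
        object$dp, object$lam, object$residual_rms
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
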