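#' Tidy a linear-response fit
#'
#' @param x An `alpha_fit` from [fit_alpha()].
#' @param ... Unused.
#' @return A tibble with one row per fitted quantity (`alpha`, `rate`,
#'   `amplitude`), its estimate and unit.
#' @export
tidy.alpha_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "rate", "amplitude"),
    estimate = c(x$alpha, x$rate, x$amplitude),
    unit = c("Pa/um^3", "1/s", "um^3")
  )
}

#' @rdname tidy.alpha_fit
#' @return For `glance()`: a one-row summary including the risetime.
#' @export
glance.alpha_fit <- function(x, ...) {
  tibble::tibble(
    alpha_Pa_um3 = x$alpha,
    rate_s = x$rate,
    risetime_s = 1 / x$rate,
    amplitude_um3 = x$amplitude,
    n_window = x$n_window
  )
}

#' Tidy an inverse bending solution
#'
#' @param x A `bending_solution` from [solve_inverse_bending()].
#' @param ... Unused.
#' @return One row per fitted quantity (`dp`, `lambda`).
#' @export
tidy.bending_solution <- function(x, ...) {
  tibble::tibble(
    term = c("dp", "lambda"),
    estimate = c(x$dp, x$lam),
    unit = c("Pa", "N/m"),
    fixed = c(FALSE, x$lam_fixed)
  )
}

#' @rdname tidy.bending_solution
#' @export
glance.bending_solution <- function(x, ...) {
  tibble::tibble(
    dp_Pa = x$dp,
    lambda_N_m = x$lam,
    residual_rms_Pa = x$residual_rms,
    condition_number = x$condition_number,
    degenerate = x$degenerate,
    n_samples = x$n_samples
  )
}

#' Tidy a bending-constant fit
#'
#' @param x A `bending_fit` from [fit_bending_constants()].
#' @param ... Unused.
#' @return One row per fitted modulus, in erg.
#' @export
tidy.bending_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_c", "k_d"),
    estimate = c(x$params$k_c, x$params$k_d) / .ERG,
    unit = "erg"
  )
}

#' @rdname tidy.bending_fit
#' @export
glance.bending_fit <- function(x, ...) {
  tibble::tibble(
    k_c_erg = x$params$k_c / .ERG,
    k_d_erg = x$params$k_d / .ERG,
    objective = x$objective,
    n_shapes = x$n_shapes,
    convergence = x$convergence
  )
}
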