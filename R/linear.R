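#' Linearized swelling model
#'
#' In the small-strain regime the stretching pressure is proportional to the
#' volume change, `dP_IMM ~ alpha * dV`, and the swelling ODE reduces to
#' `d(dV)/dt = S_bar p_w_bar (dP_os - alpha dV)` with the closed-form solution
#' `dV(t) = (dP_os / alpha) (1 - exp(-alpha S_bar p_w_bar t))`.
#' The rate constant `alpha * S_bar * p_w_bar` (the inverse risetime) is
#' independent of the osmotic drive; only the saturation amplitude
#' `dP_os / alpha` depends on it.
#'
#' @param alpha Coupling coefficient between stretching pressure and volume
#'   change, Pa/um^3 (> 0).
#' @param S_bar Average membrane area over the rise, um^2.
#' @param p_w_bar Average water permeability, m s^-1 Pa^-1.
#' @param dP_os Driving osmotic pressure, Pa.
#' @return An object of class `linearized_model`.
#' @export
linearized_model <- function(alpha, S_bar, p_w_bar, dP_os) {
  stopifnot(alpha > 0, S_bar > 0, p_w_bar > 0)
  structure(
    list(alpha = alpha, S_bar = S_bar, p_w_bar = p_w_bar, dP_os = dP_os),
    class = "linearized_model"
  )
}

#' @export
print.linearized_model <- function(x, ...) {
  cat(sprintf(
    "<linearized_model> alpha = %.4g Pa/um^3, rate = %.4g s^-1 (risetime %.4g s), dV_sat = %.4g um^3\n",
    x$alpha, linearized_rate(x), 1 / linearized_rate(x), x$dP_os / x$alpha
  ))
  invisible(x)
}

#' Rate constant of the linearized model
#'
#' `alpha * S_bar * p_w_bar` in s^-1 (units reconciled internally:
#' Pa/um^3 * um^2 * m/s/Pa = 1e6 s^-1 per unit product).
#'
#' @param model A [linearized_model()].
#' @return Rate, s^-1.  The risetime is its inverse.
#' @export
linearized_rate <- function(model) {
  stopifnot(inherits(model, "linearized_model"))
  (model$alpha / .UM3) * (model$S_bar * .UM2) * model$p_w_bar
}

#' Closed-form volume change of the linearized model
#'
#' @param model A [linearized_model()].
#' @param t Time(s), s (>= 0).
#' @return Volume change `dV`, um^3 (vectorised over `t`).
#' @examples
#' m <- linearized_model(alpha = 2400, S_bar = 456, p_w_bar = 1e-13, dP_os = 5000)
#' linearized_solution(m, c(0, 1 / linearized_rate(m)))
#' @export
linearized_solution <- function(model, t) {
  stopifnot(inherits(model, "linearized_model"), all(t >= 0))
  (model$dP_os / model$alpha) * (1 - exp(-linearized_rate(model) * t))
}

#' Linearize a swelling configuration
#'
#' Builds the small-strain analytic model from a full configuration:
#' `alpha` by numerical differentiation of the stretching pressure with
#' respect to volume at the initial state (under the config's partition
#' rule), `S_bar` as the initial area, `p_w_bar` as the config permeability
#' and `dP_os` as the initial osmotic pressure.
#'
#' @inheritParams simulate_swelling
#' @param rel_h Relative volume step for the derivative (default 1e-3).
#' @return A [linearized_model()].
#' @export
linearize_config <- function(config, rel_h = 1e-3) {
  stopifnot(inherits(config, "swelling_config"))
  v0 <- ellipsoid_volume(config$shape)
  h <- rel_h * v0
  dpi <- .swelling_terms(config, v0 + h)$dP_imm
  alpha <- dpi / h # dP_imm(v0) = 0 at zero deformation
  tm0 <- .swelling_terms(config, v0)
  linearized_model(alpha, tm0$S, config$p_w, tm0$dP_os)
}

#' Extract the linear-response coupling and rate from a trajectory
#'
#' Two fits on a simulated (or observed) trajectory: a least-squares fit of
#' `dP_IMM` against `dV` through the origin over the small-strain window
#' `|dV|/V0 < 5%` (yielding `alpha`), and an exponential rise
#' `dV(t) = A (1 - exp(-rate t))` fit over the whole trajectory (yielding the
#' inverse risetime `rate`).  For data generated by the linearized model the
#' two are linked by `rate = alpha * S_bar * p_w_bar`.
#'
#' @param traj A `swelling_trajectory` (needs >= 10 points in the
#'   small-strain window).
#' @return An object of class `alpha_fit` with elements `alpha` (Pa/um^3),
#'   `rate` (s^-1), `amplitude` (um^3), `n_window`, and the underlying fits.
#'   Supports [tidy()] and [glance()].
#' @export
fit_alpha <- function(traj) {
  stopifnot(inherits(traj, "swelling_trajectory"))
  v0 <- traj$V_um3[1]
  dV <- traj$V_um3 - v0
  win <- which(abs(dV) / v0 < 0.05 & dV != 0)
  if (length(win) < 10) {
    abort("need at least 10 pre-saturation points with |dV|/V0 < 5% to fit alpha")
  }
  lin <- lm(dP_imm_Pa ~ 0 + dV, data = tibble::tibble(
    dP_imm_Pa = traj$dP_imm_Pa[win], dV = dV[win]
  ))
  alpha <- unname(coef(lin)[1])

  df <- tibble::tibble(t = traj$time_s, dV = dV)
  amp0 <- max(dV)
  rate0 <- {
    i63 <- which(dV >= 0.632 * amp0)[1]
    if (is.na(i63) || df$t[i63] <= 0) 1 / max(df$t[df$t > 0][1], 1e-6) else 1 / df$t[i63]
  }
  exp_fit <- minpack.lm::nlsLM(dV ~ A * (1 - exp(-k * t)),
    data = df,
    start = list(A = amp0, k = rate0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(exp_fit)
  structure(
    list(
      alpha = alpha, rate = unname(est["k"]), amplitude = unname(est["A"]),
      n_window = length(win), lm_fit = lin, exp_fit = exp_fit
    ),
    class = "alpha_fit"
  )
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf(
    "<alpha_fit> alpha = %.5g Pa/um^3; rate = %.5g s^-1 (risetime %.4g s); amplitude = %.5g um^3 [%d window points]\n",
    x$alpha, x$rate, 1 / x$rate, x$amplitude, x$n_window
  ))
  invisible(x)
}
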