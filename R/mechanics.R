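#' Membrane rigidity tensor parameters
#'
#' The stretching stiffness of the closed membrane is a diagonal second-rank
#' tensor with equal in-plane components (`g'_xx = g'_yy = g0`) and an axial
#' component `g_zz`.  Each component decays from its zero-strain value through
#' a phenomenological disruption law
#'
#'   `g0  = g00    * (1 - beta0 * dr^n1 / (1 + beta0 * dr^n1))`
#'   `gzz = gzz0   * (1 - betaz * dz^n1 / (1 + betaz * dz^n1))`
#'
#' so that rigidity approaches zero asymptotically at large deformation,
#' modelling membrane disruption in the irreversible (pathological) swelling
#' regime.  `dr` and `dz` are the absolute semi-axis deformations in um.
#'
#' @param g00 In-plane rigidity at zero strain.  Interpreted in `units`.
#' @param gzz0 Axial rigidity at zero strain.  Interpreted in `units`.
#' @param beta0,betaz Disruption coefficients, um^-n1 (>= 0).  Zero switches
#'   disruption off (purely reversible membrane).
#' @param n1 Disruption exponent (integer >= 1).  With even `n1` the law is
#'   symmetric under strain sign flip; for odd `n1` the absolute deformation
#'   is used inside the disruption ratio so rigidity stays positive either way.
#' @param units Unit of `g00`/`gzz0`: `"dyn/nm"` (default; 1 dyn/nm = 1e4 N/m)
#'   or `"N/m"`.
#' @return An object of class `rigidity_params` with fields `g00`, `gzz0`
#'   (N/m), `beta0`, `betaz` (um^-n1) and `n1`.
#' @examples
#' rigidity_params() # inner-mitochondrial-membrane preset
#' @export
rigidity_params <- function(g00 = 0.0101, gzz0 = 0.008,
                            beta0 = 1.8e4, betaz = 1.6e4, n1 = 4,
                            units = c("dyn/nm", "N/m")) {
  units <- match.arg(units)
  fac <- if (units == "dyn/nm") .DYN_PER_NM_TO_N_PER_M else 1
  stopifnot(
    is.numeric(g00), g00 > 0, is.numeric(gzz0), gzz0 > 0,
    is.numeric(beta0), beta0 >= 0, is.numeric(betaz), betaz >= 0,
    is.numeric(n1), n1 >= 1, n1 == round(n1)
  )
  structure(
    list(
      g00 = g00 * fac, gzz0 = gzz0 * fac,
      beta0 = beta0, betaz = betaz, n1 = as.integer(n1)
    ),
    class = "rigidity_params"
  )
}

#' @export
print.rigidity_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<rigidity_params> g00 = %.4g N/m (%.4g dyn/nm), gzz0 = %.4g N/m ",
      "(%.4g dyn/nm)\n  beta0 = %.4g, betaz = %.4g um^-%d, n1 = %d\n"
    ),
    x$g00, x$g00 / .DYN_PER_NM_TO_N_PER_M,
    x$gzz0, x$gzz0 / .DYN_PER_NM_TO_N_PER_M,
    x$beta0, x$betaz, x$n1, x$n1
  ))
  invisible(x)
}

## disruption factor 1 - b|d|^n/(1+b|d|^n) = 1/(1 + b|d|^n), vectorised
.disrupt <- function(beta, d, n1) 1 / (1 + beta * abs(d)^n1)

#' Rigidity tensor components at a given deformation
#'
#' Evaluates the disruption law for the in-plane and axial stiffness at
#' equatorial deformation `dr = a(t) - a(0)` and polar deformation
#' `dz = c(t) - c(0)`.
#'
#' @param params A [rigidity_params()].
#' @param dr,dz Deformations, um (vectorised; negative values = shrinkage).
#' @return A tibble with columns `dr`, `dz`, `g0`, `gzz` (N/m).
#' @examples
#' rigidity_components(rigidity_params(), dr = 0, dz = 0.1)
#' @export
rigidity_components <- function(params, dr, dz) {
  stopifnot(inherits(params, "rigidity_params"))
  n <- max(length(dr), length(dz))
  dr <- rep_len(dr, n)
  dz <- rep_len(dz, n)
  if (!all(is.finite(dr)) || !all(is.finite(dz))) {
    abort("deformations must be finite")
  }
  tibble::tibble(
    dr = dr, dz = dz,
    g0 = params$g00 * .disrupt(params$beta0, dr, params$n1),
    gzz = params$gzz0 * .disrupt(params$betaz, dz, params$n1)
  )
}

#' Solution state on both sides of the membrane
#'
#' Per-species internal and external concentrations plus temperature.  The
#' species lists must match by name: the osmotic pressure is a sum over the
#' same species inside and outside.
#'
#' @param c_in Named numeric vector of internal concentrations, mM.
#' @param c_out Named numeric vector of external concentrations, mM, with the
#'   same names as `c_in` (order-insensitive).
#' @param temperature Absolute temperature, K (default 310).
#' @return An object of class `medium_state`.
#' @examples
#' medium_state(c(Na = 50, Cl = 50), c(Na = 1, Cl = 1))
#' @export
medium_state <- function(c_in, c_out, temperature = 310) {
  if (is.null(names(c_in)) || is.null(names(c_out)) ||
    any(names(c_in) == "") || any(names(c_out) == "")) {
    abort("`c_in` and `c_out` must be named numeric vectors (species names).")
  }
  if (!setequal(names(c_in), names(c_out)) ||
    length(c_in) != length(c_out)) {
    abort("species lists inside and outside the membrane must match.")
  }
  ord <- sort(names(c_in))
  c_in <- c_in[ord]
  c_out <- c_out[ord]
  stopifnot(all(c_in >= 0), all(c_out >= 0), temperature > 0)
  structure(
    list(c_in = c_in, c_out = c_out, temperature = temperature),
    class = "medium_state"
  )
}

#' @export
print.medium_state <- function(x, ...) {
  cat(sprintf("<medium_state> T = %g K\n", x$temperature))
  for (sp in names(x$c_in)) {
    cat(sprintf("  %s: %g mM in / %g mM out\n", sp, x$c_in[[sp]], x$c_out[[sp]]))
  }
  invisible(x)
}

#' Osmotic pressure across the membrane
#'
#' Van 't Hoff relation `dP_os = R * T * sum_i (C_i_in - C_i_out)` with
#' concentrations in mol/m^3 (1 mM = 1 mol/m^3).  Positive when the interior
#' is hypertonic, i.e. when the osmotic gradient drives water in.
#'
#' @param medium A [medium_state()].
#' @return Pressure, Pa.
#' @examples
#' osmotic_pressure(medium_state(c(Na = 50, Cl = 50), c(Na = 1, Cl = 1)))
#' @export
osmotic_pressure <- function(medium) {
  stopifnot(inherits(medium, "medium_state"))
  .R_GAS * medium$temperature * sum(medium$c_in - medium$c_out)
}

#' Stretching-induced internal pressure
#'
#' Inward pressure generated by membrane stretch,
#' `dP_IMM = (2 * g0 * dr + gzz * dz) / S`, with the rigidity components from
#' the disruption law.  Evaluated in SI (dyn/nm -> N/m, um -> m, um^2 -> m^2);
#' the result is in Pa and opposes swelling when deformations are positive.
#'
#' @inheritParams rigidity_components
#' @param area Current membrane surface area, um^2 (> 0).
#' @return Pressure, Pa (vectorised over `dr`, `dz`, `area`).
#' @examples
#' p <- rigidity_params()
#' stretching_pressure(p, dr = 0.1, dz = 0.03,
#'                     area = ellipsoid_area(ellipsoid_shape(8.1, 2.03)))
#' @export
stretching_pressure <- function(params, dr, dz, area) {
  if (any(!is.finite(area)) || any(area <= 0)) {
    abort("`area` must be positive (um^2).")
  }
  g <- rigidity_components(params, dr, dz)
  (2 * g$g0 * g$dr * .UM + g$gzz * g$dz * .UM) / (area * .UM2)
}
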