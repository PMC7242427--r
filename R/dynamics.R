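#' Simulation configuration for swelling dynamics
#'
#' Bundles geometry, solution state, membrane rigidity, water permeability and
#' solver settings.  Volume is the single ODE state: internal concentrations
#' follow exactly from solute conservation `C_i(t) V(t) = C_i(0) V(0)` (the
#' closed-form solution of the dilution equation), and the shape is resolved
#' at every volume by [partition_deformation()].
#'
#' @param shape Initial [ellipsoid_shape()].
#' @param medium A [medium_state()].
#' @param rigidity A [rigidity_params()].
#' @param p_w Water permeability per unit area per unit pressure,
#'   m s^-1 Pa^-1.  The default 1e-13 is a physically plausible hydraulic
#'   conductivity giving tens-of-seconds risetimes at erythrocyte scale.
#' @param t_span Simulated time span, s.
#' @param rtol,atol Relative/absolute solver tolerances, each in (0, 1e-2].
#' @param partition_rule How one volume maps to two shape degrees of freedom:
#'   `"energy-min"` (default), `"self-similar"`, or `"fixed-ratio:<x>"`.
#'   See [partition_deformation()].
#' @param saturation_threshold Relative volume rate `|dV/dt|/V` (s^-1) below
#'   which, sustained over 3 consecutive output points after swelling has
#'   started, the trajectory is truncated as saturated.
#' @param n_out Number of points on the fixed output grid.
#' @param label Optional scenario label carried into outputs.
#' @return An object of class `swelling_config`.
#' @examples
#' cfg <- swelling_config(
#'   ellipsoid_shape(8, 2),
#'   medium_state(c(Na = 50, Cl = 50), c(Na = 1, Cl = 1)),
#'   rigidity_params()
#' )
#' @export
swelling_config <- function(shape, medium, rigidity,
                            p_w = 1e-13, t_span = 600,
                            rtol = 1e-8, atol = 1e-10,
                            partition_rule = "energy-min",
                            saturation_threshold = 1e-8,
                            n_out = 501, label = NULL) {
  shape <- .as_shape(shape)
  stopifnot(
    inherits(medium, "medium_state"), inherits(rigidity, "rigidity_params"),
    is.numeric(p_w), p_w > 0, is.numeric(t_span), t_span > 0,
    rtol > 0, rtol <= 1e-2, atol > 0, atol <= 1e-2,
    saturation_threshold > 0, n_out >= 20
  )
  .check_partition_rule(partition_rule)
  structure(
    list(
      shape = shape, medium = medium, rigidity = rigidity,
      p_w = p_w, t_span = t_span, rtol = rtol, atol = atol,
      partition_rule = partition_rule,
      saturation_threshold = saturation_threshold,
      n_out = as.integer(n_out), label = label
    ),
    class = "swelling_config"
  )
}

#' @export
print.swelling_config <- function(x, ...) {
  cat(sprintf(
    "<swelling_config>%s a = %g, c = %g um; p_w = %g m/s/Pa; t_span = %g s; rule = %s\n",
    if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
    x$shape$a, x$shape$c, x$p_w, x$t_span, x$partition_rule
  ))
  print(x$medium)
  invisible(x)
}

.check_partition_rule <- function(rule) {
  ok <- rule %in% c("energy-min", "self-similar") ||
    grepl("^fixed-ratio:[0-9.eE+-]+$", rule)
  if (!ok) {
    abort(sprintf(
      "unknown partition rule '%s' (use 'energy-min', 'self-similar' or 'fixed-ratio:<x>')",
      rule
    ))
  }
  invisible(rule)
}

## elastic stretching work W(dr, dz) = int_0^dr 2 g0(r) r dr + int_0^dz gzz(z) z dz
## Closed forms: beta = 0 -> quadratic; n1 = 4 -> arctan; otherwise quadrature.
.work_axis <- function(pref, beta, n1, d) {
  if (beta == 0) {
    return(pref * d^2 / 2)
  }
  if (n1 == 4L) {
    return(pref / (2 * sqrt(beta)) * atan(sqrt(beta) * d^2))
  }
  sign(d) * integrate(
    function(u) pref * u / (1 + beta * u^n1),
    0, abs(d),
    rel.tol = 1e-12
  )$value
}

.stretch_work <- function(rig, dr, dz) {
  .work_axis(2 * rig$g00, rig$beta0, rig$n1, dr) +
    .work_axis(rig$gzz0, rig$betaz, rig$n1, dz)
}

#' Partition a volume change between the two ellipsoid axes
#'
#' The swelling model evolves a single volume; the shape has two degrees of
#' freedom (`dr`, `dz`).  This operation closes the system.  Rules:
#'
#' * `"energy-min"`: minimise the elastic stretching work
#'   `W = int 2 g0(r) r dr + int gzz(z) z dz` subject to the exact volume
#'   constraint (1-D constrained search over `dz`, with `dr` eliminated
#'   through the closed-form volume).  In the small-strain limit this gives
#'   `dr/dz -> c * gzz0 / (a * g00)`.
#' * `"self-similar"`: uniform scaling, `dr/a0 = dz/c0` (so `zeta = xi`).
#' * `"fixed-ratio:x"`: `dr = x * dz`.
#'
#' @param shape0 Reference [ellipsoid_shape()].
#' @param rigidity A [rigidity_params()] (used by `"energy-min"` only).
#' @param v_target Target volume, um^3 (> 0).
#' @param rule Partition rule identifier (see above).
#' @return One-row tibble with `dr`, `dz` (um), the deformed semi-axes
#'   `a`, `c` (um) and the achieved volume `V` (um^3, equal to `v_target`
#'   to relative 1e-10).
#' @examples
#' partition_deformation(ellipsoid_shape(8, 2), rigidity_params(), 600)
#' @export
partition_deformation <- function(shape0, rigidity, v_target,
                                  rule = "energy-min") {
  shape0 <- .as_shape(shape0)
  .check_partition_rule(rule)
  if (!is.numeric(v_target) || !is.finite(v_target) || v_target <= 0) {
    abort("`v_target` must be a positive volume (um^3): not attainable with real deformations.")
  }
  a0 <- shape0$a
  c0 <- shape0$c
  v0 <- .ell_vol(a0, c0)

  if (rule == "self-similar") {
    s <- (v_target / v0)^(1 / 3)
    dr <- a0 * (s - 1)
    dz <- c0 * (s - 1)
  } else if (startsWith(rule, "fixed-ratio:")) {
    x <- as.numeric(sub("^fixed-ratio:", "", rule))
    if (!is.finite(x)) abort("invalid fixed-ratio value")
    f <- function(dz) .ell_vol(a0 + x * dz, c0 + dz) - v_target
    lo <- -0.95 * c0
    if (x > 0) lo <- max(lo, -0.95 * a0 / x)
    hi <- max(c0, 4 * c0 * (v_target / v0)^(1 / 3))
    while (f(hi) < 0) hi <- hi * 2
    if (f(lo) > 0) abort("`v_target` not attainable under this fixed-ratio rule")
    dz <- uniroot(f, c(lo, hi), tol = 1e-14)$root
    dr <- x * dz
  } else { # energy-min
    stopifnot(inherits(rigidity, "rigidity_params"))
    a_of <- function(dz) sqrt(3 * v_target / (4 * pi * (c0 + dz)))
    obj <- function(dz) .stretch_work(rigidity, a_of(dz) - a0, dz)
    lo <- -0.95 * c0
    hi <- max(c0, 4 * c0 * (v_target / v0)^(1 / 3))
    ## coarse scan guards against local minima once disruption softens an axis
    grid <- seq(lo, hi, length.out = 129)
    vals <- vapply(grid, obj, numeric(1))
    i <- which.min(vals)
    bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
    dz <- optimize(obj, bracket, tol = 1e-12)$minimum
    dr <- a_of(dz) - a0
  }

  a <- a0 + dr
  c <- c0 + dz
  tibble::tibble(dr = dr, dz = dz, a = a, c = c, V = .ell_vol(a, c))
}

## internal: everything the ODE right-hand side needs, as a function of V
.swelling_terms <- function(config, V) {
  part <- partition_deformation(
    config$shape, config$rigidity, V, config$partition_rule
  )
  S <- .ell_area(part$a, part$c)
  v0 <- .ell_vol(config$shape$a, config$shape$c)
  c_in <- config$medium$c_in * v0 / V # conservation, exact
  dP_os <- .R_GAS * config$medium$temperature * sum(c_in - config$medium$c_out)
  dP_imm <- stretching_pressure(config$rigidity, part$dr, part$dz, S)
  list(
    part = part, S = S, c_in = c_in,
    dP_os = dP_os, dP_imm = dP_imm,
    dVdt = S * .UM2 * config$p_w * (dP_os - dP_imm) / .UM3 # um^3/s
  )
}

#' Simulate swelling dynamics
#'
#' Integrates `dV/dt = S(t) p_w (dP_os - dP_IMM)` with the volume as the only
#' ODE state (stiff-capable adaptive `lsoda`), internal concentrations in
#' closed form from solute conservation, and the shape resolved per step by
#' [partition_deformation()].  The trajectory is reported on a fixed output
#' grid and truncated once the relative volume rate stays below the
#' saturation threshold for 3 consecutive output points (after swelling has
#' actually started).
#'
#' @param config A [swelling_config()].
#' @return A tibble of class `swelling_trajectory` with columns `time_s`,
#'   `a_um`, `c_um`, `V_um3`, `S_um2`, `dr_um`, `dz_um`, `zeta`, `xi`,
#'   one `C_<species>_mM` column per species (alphabetical), `dP_os_Pa`,
#'   `dP_imm_Pa`.  The configuration is attached as attribute `config`.
#' @examples
#' cfg <- swelling_config(
#'   ellipsoid_shape(8, 2),
#'   medium_state(c(Na = 10, Cl = 10), c(Na = 1, Cl = 1)),
#'   rigidity_params(beta0 = 0, betaz = 0),
#'   partition_rule = "self-similar", t_span = 120
#' )
#' traj <- simulate_swelling(cfg)
#' @export
simulate_swelling <- function(config) {
  stopifnot(inherits(config, "swelling_config"))
  v0 <- ellipsoid_volume(config$shape)
  times <- seq(0, config$t_span, length.out = config$n_out)

  rhs <- function(t, y, parms) {
    if (y[1] <= 0) abort("solver produced a non-positive volume")
    list(.swelling_terms(config, y[1])$dVdt)
  }
  sol <- deSolve::ode(
    y = c(V = v0), times = times, func = rhs, parms = NULL,
    method = "lsoda", rtol = config$rtol, atol = config$atol
  )
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    abort(sprintf(
      "ODE solver failed (istate = %d) after %d steps at t = %g s; try looser tolerances",
      diag[1], diag[3], max(sol[, 1])
    ))
  }
  .assemble_trajectory(config, sol[, 1], sol[, 2], classical = FALSE)
}

## shared trajectory assembly + saturation truncation
.assemble_trajectory <- function(config, time, V, classical, eta_w = NULL) {
  rows <- purrr::map(V, function(v) {
    tm <- .swelling_terms(config, v)
    base <- tibble::tibble(
      a_um = tm$part$a, c_um = tm$part$c, V_um3 = v, S_um2 = tm$S,
      dr_um = tm$part$dr, dz_um = tm$part$dz,
      zeta = tm$part$a / config$shape$a - 1,
      xi = tm$part$c / config$shape$c - 1
    )
    conc <- tibble::as_tibble(as.list(setNames(
      tm$c_in, paste0("C_", names(tm$c_in), "_mM")
    )))
    press <- tibble::tibble(dP_os_Pa = tm$dP_os, dP_imm_Pa = tm$dP_imm)
    out <- dplyr::bind_cols(base, conc, press)
    if (classical) {
      pref <- tm$S * .UM2 * eta_w * .R_GAS * config$medium$temperature / .UM3
      out$J_w_in_um3_s <- pref * sum(tm$c_in)
      out$J_w_out_um3_s <- pref * sum(config$medium$c_out)
      out$dVdt_um3_s <- out$J_w_in_um3_s - out$J_w_out_um3_s
    } else {
      out$dVdt_um3_s <- tm$dVdt
    }
    out
  })
  traj <- dplyr::bind_cols(tibble::tibble(time_s = time), dplyr::bind_rows(rows))

  ## saturation truncation: relative |dV/dt| below threshold, sustained for 3
  ## output points, once the rate has previously exceeded the threshold
  rel_rate <- abs(traj$dVdt_um3_s) / traj$V_um3
  thr <- config$saturation_threshold
  started <- cumsum(rel_rate > thr) > 0
  below <- rel_rate < thr & started
  run3 <- below & dplyr::lag(below, 1, FALSE) & dplyr::lag(below, 2, FALSE)
  if (any(run3)) traj <- traj[seq_len(which(run3)[1]), ]

  traj$dVdt_um3_s <- NULL
  attr(traj, "config") <- config
  class(traj) <- c("swelling_trajectory", class(traj))
  traj
}

#' Saturated (equilibrium) swelling state
#'
#' Solves the water-flux balance `dP_os(V) = dP_IMM(V)` for the volume by
#' bracketed root finding, with concentrations from conservation and
#' deformations from [partition_deformation()].  The first root above the
#' initial volume is the state the dynamics actually reach.
#'
#' When the membrane disruption law makes `dP_IMM` non-monotone and the
#' osmotic drive exceeds the maximum restoring pressure, the only balance
#' point sits on the decaying (disrupted) branch very near the classical
#' osmotic-equilibrium volume: this is the irreversible (pathological)
#' swelling regime, reported via `reversible = FALSE` and a note -- not as an
#' exception.
#'
#' @param config A [swelling_config()] with an initially hypertonic (or
#'   isotonic) interior.
#' @return One-row tibble: `V_sat_um3`, `a_um`, `c_um`, `dr_um`, `dz_um`,
#'   `S_um2`, `dP_os_Pa`, `dP_imm_Pa`, `reversible`, `note`.
#' @export
saturation_state <- function(config) {
  stopifnot(inherits(config, "swelling_config"))
  v0 <- ellipsoid_volume(config$shape)
  tot_in <- sum(config$medium$c_in)
  tot_out <- sum(config$medium$c_out)
  if (abs(tot_in - tot_out) < 1e-12 * max(tot_in, 1)) {
    tm <- .swelling_terms(config, v0)
    return(tibble::tibble(
      V_sat_um3 = v0, a_um = config$shape$a, c_um = config$shape$c,
      dr_um = 0, dz_um = 0, S_um2 = tm$S,
      dP_os_Pa = tm$dP_os, dP_imm_Pa = tm$dP_imm,
      reversible = TRUE, note = "isotonic: no net water flux"
    ))
  }
  if (tot_in < tot_out) {
    abort("interior is hypotonic; saturation_state() expects an initially hypertonic interior")
  }
  f <- function(v) {
    tm <- .swelling_terms(config, v)
    tm$dP_os - tm$dP_imm
  }
  v_cl <- v0 * tot_in / tot_out # classical equilibrium: upper bound (dP_os < 0 beyond)
  grid <- seq(v0 * (1 + 1e-10), v_cl, length.out = 512)
  fv <- vapply(grid, f, numeric(1))
  chg <- which(fv[-length(fv)] > 0 & fv[-1] <= 0)
  bracket <- if (length(chg) > 0) {
    c(grid[chg[1]], grid[chg[1] + 1])
  } else {
    c(grid[length(grid)], v_cl * (1 + 1e-9)) # root pinned just below/at v_cl
  }
  root <- uniroot(f, bracket, tol = max(1e-13 * v_cl, 1e-10))$root

  tm <- .swelling_terms(config, root)
  ## reversible <=> equilibrium on the rising (intact-membrane) branch of dP_IMM
  h <- 1e-5 * root
  slope <- (.swelling_terms(config, root + h)$dP_imm -
    .swelling_terms(config, root - h)$dP_imm) / (2 * h)
  reversible <- slope > 0
  tibble::tibble(
    V_sat_um3 = root, a_um = tm$part$a, c_um = tm$part$c,
    dr_um = tm$part$dr, dz_um = tm$part$dz, S_um2 = tm$S,
    dP_os_Pa = tm$dP_os, dP_imm_Pa = tm$dP_imm,
    reversible = reversible,
    note = if (reversible) {
      "reversible equilibrium (stretching balances osmotic drive)"
    } else {
      "no reversible equilibrium: osmotic drive exceeds the disrupted membrane's restoring pressure"
    }
  )
}

#' Classical osmotic-only swelling baseline
#'
#' Integrates the membrane-mechanics-free model
#' `dV/dt = S(t) eta_w R T sum_i (C_i_in - C_i_out)`, with concentrations
#' from conservation.  The trajectory additionally reports the inward and
#' outward water fluxes `J_w_in = S eta_w R T sum C_in` and
#' `J_w_out = S eta_w R T sum C_out`; saturation (`J_w_in = J_w_out`)
#' occurs exactly at `sum C_in = sum C_out`, i.e. at
#' `V_sat = V0 * sum C_in(0) / sum C_out` -- see
#' [classical_saturation_volume()].
#'
#' @inheritParams simulate_swelling
#' @param eta_w Membrane permeability coefficient for water, m s^-1 Pa^-1
#'   (defaults to the config's `p_w`).
#' @return A `swelling_trajectory` tibble with extra columns
#'   `J_w_in_um3_s`, `J_w_out_um3_s`.  `dP_imm_Pa` is still reported for
#'   reference but does not enter the dynamics.
#' @export
classical_swelling <- function(config, eta_w = NULL) {
  stopifnot(inherits(config, "swelling_config"))
  eta_w <- eta_w %||% config$p_w
  stopifnot(eta_w > 0)
  v0 <- ellipsoid_volume(config$shape)
  times <- seq(0, config$t_span, length.out = config$n_out)
  rhs <- function(t, y, parms) {
    if (y[1] <= 0) abort("solver produced a non-positive volume")
    tm <- .swelling_terms(config, y[1])
    list(tm$S * .UM2 * eta_w * tm$dP_os / .UM3)
  }
  sol <- deSolve::ode(
    y = c(V = v0), times = times, func = rhs, parms = NULL,
    method = "lsoda", rtol = config$rtol, atol = config$atol
  )
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    abort(sprintf("ODE solver failed (istate = %d)", diag[1]))
  }
  .assemble_trajectory(config, sol[, 1], sol[, 2], classical = TRUE, eta_w = eta_w)
}

#' Classical osmotic equilibrium volume
#'
#' The osmotic-only model saturates when total internal and external
#' concentrations are equal: `V_sat = V0 * sum C_in(0) / sum C_out`.
#'
#' @inheritParams simulate_swelling
#' @return Volume, um^3.
#' @export
classical_saturation_volume <- function(config) {
  stopifnot(inherits(config, "swelling_config"))
  ellipsoid_volume(config$shape) *
    sum(config$medium$c_in) / sum(config$medium$c_out)
}

#' Sweep swelling over initial internal concentrations
#'
#' Runs [simulate_swelling()] for a series of initial internal
#' concentrations (applied to every species in the medium) and summarises
#' saturation and kinetics per run.  The risetime is the interpolated time
#' at which the volume change reaches `1 - exp(-1)` (63.2%) of its saturated
#' amplitude.
#'
#' @inheritParams simulate_swelling
#' @param concentrations Internal concentrations to sweep, mM.
#' @return A tibble with one row per concentration: `conc_mM`,
#'   `V_sat_um3`, `S_sat_um2`, `amplitude_um3`, `risetime_s`,
#'   `reversible`, and a `trajectory` list-column.
#' @export
sweep_swelling <- function(config, concentrations = c(10, 20, 30, 40, 50)) {
  stopifnot(inherits(config, "swelling_config"))
  purrr::map_dfr(concentrations, function(c0) {
    med <- config$medium
    med$c_in[] <- c0
    cfg <- config
    cfg$medium <- med
    cfg$label <- sprintf("%g mM", c0)
    traj <- simulate_swelling(cfg)
    sat <- saturation_state(cfg)
    dv <- traj$V_um3 - traj$V_um3[1]
    amp <- sat$V_sat_um3 - traj$V_um3[1]
    rt <- if (amp > 0 && max(dv) >= 0.632 * amp) {
      approx(dv, traj$time_s, xout = 0.632 * amp, ties = "ordered")$y
    } else {
      NA_real_
    }
    tibble::tibble(
      conc_mM = c0,
      V_sat_um3 = sat$V_sat_um3,
      S_sat_um2 = sat$S_um2,
      amplitude_um3 = amp,
      risetime_s = rt,
      reversible = sat$reversible,
      trajectory = list(traj)
    )
  })
}
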