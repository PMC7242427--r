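#' Bending (curvature-elastic) parameters
#'
#' The membrane's curvature energy density is taken as
#' `f_c = (k_c / 2) (2H + c0)^2 + k_d K` -- the total-curvature convention
#' whose Euler--Lagrange equation is the standard axisymmetric shape equation
#' used by [el_residual()].  The spontaneous curvature `c0` defaults to zero
#' (symmetric planar bilayer).
#'
#' @param k_c Bending modulus (> 0), in `units`.
#' @param k_d Gaussian (saddle) modulus, in `units`.  For a closed genus-0
#'   surface its energy contribution is the topological constant
#'   `4 pi k_d` (Gauss--Bonnet) and it does not enter the shape equation.
#' @param c0 Spontaneous curvature, um^-1 (default 0).
#' @param units `"erg"` (default) or `"J"`.
#' @return An object of class `bending_params` with `k_c`, `k_d` in J and
#'   `c0` in um^-1.
#' @examples
#' bending_params(k_c = 1.38e-5, k_d = 0.71e-5) # erg
#' @export
bending_params <- function(k_c, k_d = 0, c0 = 0, units = c("erg", "J")) {
  units <- match.arg(units)
  fac <- if (units == "erg") .ERG else 1
  stopifnot(is.numeric(k_c), k_c > 0, is.numeric(k_d), is.numeric(c0))
  structure(
    list(k_c = k_c * fac, k_d = k_d * fac, c0 = c0),
    class = "bending_params"
  )
}

#' @export
print.bending_params <- function(x, ...) {
  cat(sprintf(
    "<bending_params> k_c = %.4g erg, k_d = %.4g erg, c0 = %g um^-1\n",
    x$k_c / .ERG, x$k_d / .ERG, x$c0
  ))
  invisible(x)
}

#' Helfrich free energy of a sampled surface
#'
#' `F = sum (f_c + lambda) dA + dp * V` with
#' `f_c = (k_c/2)(2H + c0)^2 + k_d K`.  For a sphere with `c0 = 0`,
#' `lambda = 0`, `dp = 0` this is the scale-invariant
#' `8 pi k_c + 4 pi k_d`.
#'
#' @param field A [curvature_field()].
#' @param params A [bending_params()].
#' @param lam Lagrange multiplier (surface tension), N/m.
#' @param dp Bending-induced pressure, Pa.
#' @param volume Enclosed volume, um^3; taken from the field's shape when
#'   omitted.
#' @return Free energy, erg.
#' @examples
#' fld <- curvature_field(ellipsoid_shape(3, 3), 100)
#' helfrich_energy(fld, bending_params(1, 0.5)) / (8 * pi + 2 * pi) # 1 erg units
#' @export
helfrich_energy <- function(field, params, lam = 0, dp = 0, volume = NULL) {
  stopifnot(inherits(field, "curvature_field"), inherits(params, "bending_params"))
  volume <- volume %||% ellipsoid_volume(attr(field, "shape"))
  ## curvatures um^-1 -> m^-1, areas um^2 -> m^2
  H <- field$H / .UM
  K <- field$K / .UM2
  dA <- field$dA * .UM2
  c0 <- params$c0 / .UM
  f_c <- params$k_c / 2 * (2 * H + c0)^2 + params$k_d * K
  F_J <- sum((f_c + lam) * dA) + dp * volume * .UM3
  F_J / .ERG
}

#' Euler--Lagrange shape-equation residual
#'
#' Evaluates, pointwise over the field, the left side of the axisymmetric
#' shape equation
#' `dp - 2 lam H + k_c (2H + c0)(2H^2 - c0 H - 2K) + 2 k_c lap(H) = 0`.
#' A sphere of radius R with `c0 = 0` solves it exactly when the Laplace law
#' `dp = 2 lam / R` holds (there `2H^2 - 2K = 0` and `lap H = 0`).
#'
#' @inheritParams helfrich_energy
#' @return A tibble with columns `theta`, `residual` (Pa) and `dA` (um^2).
#' @export
el_residual <- function(field, params, lam = 0, dp = 0) {
  stopifnot(inherits(field, "curvature_field"), inherits(params, "bending_params"))
  H <- field$H / .UM
  K <- field$K / .UM2
  lapH <- field$lap_H / .UM3
  c0 <- params$c0 / .UM
  res <- dp - 2 * lam * H +
    params$k_c * (2 * H + c0) * (2 * H^2 - c0 * H - 2 * K) +
    2 * params$k_c * lapH
  tibble::tibble(theta = field$theta, residual = res, dA = field$dA)
}

## the curvature-only part of the residual (coefficient-free pieces), SI
.el_geom_term <- function(field, params) {
  H <- field$H / .UM
  K <- field$K / .UM2
  lapH <- field$lap_H / .UM3
  c0 <- params$c0 / .UM
  params$k_c * (2 * H + c0) * (2 * H^2 - c0 * H - 2 * K) + 2 * params$k_c * lapH
}

#' Inverse bending problem: fit pressure and tension to a prescribed shape
#'
#' `dp` and `lambda` enter the shape equation linearly, so for a given shape
#' and bending constants the best-fitting pair solves the (area-weighted)
#' linear least-squares problem `min sum dA * residual^2`.  The two columns
#' of the design matrix are `1` and `-2H`; on a sphere `H` is constant and
#' they are collinear -- only the combination `dp - 2 lam / R` is then
#' identifiable, which is flagged as degenerate (use `lam_fixed` there).
#'
#' @inheritParams helfrich_energy
#' @param weighting `"area"` (default, weights `dA`) or `"uniform"` (equal
#'   weight per theta node).
#' @param lam_fixed If supplied (N/m), `lambda` is held at this value and
#'   only `dp` is fitted -- the non-degenerate formulation for spheres.
#' @return An object of class `bending_solution`: `dp` (Pa), `lam` (N/m),
#'   `residual_rms` (area-weighted RMS, Pa), `condition_number`,
#'   `degenerate` flag, `n_samples`.  Supports [tidy()]/[glance()].
#' @examples
#' fld <- curvature_field(ellipsoid_shape(8, 2), 200)
#' solve_inverse_bending(fld, bending_params(1.38e-5, 0.71e-5))
#' @export
solve_inverse_bending <- function(field, params,
                                  weighting = c("area", "uniform"),
                                  lam_fixed = NULL) {
  stopifnot(inherits(field, "curvature_field"), inherits(params, "bending_params"))
  weighting <- match.arg(weighting)
  H <- field$H / .UM
  g <- .el_geom_term(field, params)
  w <- if (weighting == "area") field$dA * .UM2 else rep(1, nrow(field))
  sw <- sqrt(w)

  if (is.null(lam_fixed)) {
    X <- cbind(dp = rep(1, length(H)), lam = -2 * H)
    fit <- qr(X * sw)
    cond <- kappa(fit, exact = TRUE)
    degenerate <- cond > 1e10
    if (degenerate) {
      warn(paste0(
        "near-spherical shape: columns (1, -2H) are collinear ",
        sprintf("(condition number %.3g); ", cond),
        "only dp - 2*lam*H is identifiable -- consider `lam_fixed`"
      ))
    }
    beta <- qr.coef(fit, -g * sw)
    dp <- unname(beta["dp"])
    lam <- unname(beta["lam"])
  } else {
    ## residual = dp - 2 lam_fixed H + g; one linear unknown
    y <- -(g - 2 * lam_fixed * H)
    dp <- sum(w * y) / sum(w)
    lam <- lam_fixed
    cond <- 1
    degenerate <- FALSE
  }
  res <- dp - 2 * lam * H + g
  wA <- field$dA * .UM2
  structure(
    list(
      dp = dp, lam = lam,
      residual_rms = sqrt(sum(wA * res^2) / sum(wA)),
      condition_number = cond, degenerate = degenerate,
      n_samples = nrow(field), weighting = weighting,
      lam_fixed = !is.null(lam_fixed), params = params,
      shape = attr(field, "shape")
    ),
    class = "bending_solution"
  )
}

#' @export
print.bending_solution <- function(x, ...) {
  cat(sprintf(
    "<bending_solution> dp = %.6g Pa, lambda = %.6g N/m\n  residual RMS = %.4g Pa, condition number = %.4g%s [n = %d, %s weights]\n",
    x$dp, x$lam, x$residual_rms, x$condition_number,
    if (x$degenerate) " (DEGENERATE)" else "", x$n_samples, x$weighting
  ))
  invisible(x)
}

#' Bending modulus of a homogeneous sheet from its stretching rigidity
#'
#' Thin-plate relation `k_c = g h^2 / (12 (1 - nu^2))` linking the membrane's
#' stretching rigidity to an effective bending modulus for a homogeneous
#' sheet of thickness `h` and Poisson ratio `nu`.  Exposed as a configurable
#' formula: it supplies the deterministic starting point for
#' [fit_bending_constants()].
#'
#' @param g Stretching rigidity, dyn/nm.
#' @param h Sheet thickness, nm (> 0).
#' @param nu Poisson ratio in `[0, 0.5]`.
#' @return Bending modulus `k_c`, erg.
#' @examples
#' bending_from_stretching(0.0101, h = 4, nu = 0.5) # ~1.80e-9 erg
#' @export
bending_from_stretching <- function(g, h, nu = 0.5) {
  stopifnot(h > 0, nu >= 0, nu <= 0.5)
  g_si <- g * .DYN_PER_NM_TO_N_PER_M
  h_si <- h * 1e-9
  (g_si * h_si^2 / (12 * (1 - nu^2))) / .ERG
}

#' Fit bending constants to observed shape-equation data
#'
#' Recovers `(k_c, k_d)` from a set of shapes with observed Euler--Lagrange
#' residual fields and observed Helfrich energies.  For each trial `k_c` the
#' per-shape `(dp, lambda)` are profiled out by [solve_inverse_bending()];
#' the objective is the normalised misfit between modelled and observed
#' residual fields (which determines `k_c`) plus the relative misfit of
#' the energies (which pins `k_d`, since for closed genus-0 surfaces the
#' Gaussian term contributes only `4 pi k_d` and drops out of the shape
#' equation entirely).  Minimised by a deterministic derivative-free
#' Nelder--Mead simplex in log-parameter space, started from `params0`
#' (e.g. the sheet relation [bending_from_stretching()]).
#'
#' @param fields List of [curvature_field()]s (>= 2 distinct shapes).
#' @param params0 Starting [bending_params()].
#' @param observed List with elements `residuals` (list of numeric vectors,
#'   one per field, Pa at the field's nodes) and `energies` (numeric, erg,
#'   one per field).  E.g. generated by [el_residual()] and
#'   [helfrich_energy()].
#' @param reltol Convergence tolerance on the objective (default 1e-10).
#' @return An object of class `bending_fit`: fitted [bending_params()],
#'   per-shape solutions, objective trace (best-so-far, non-increasing),
#'   convergence info.  Supports [tidy()]/[glance()].
#' @export
fit_bending_constants <- function(fields, params0, observed, reltol = 1e-10) {
  stopifnot(is.list(fields), length(fields) >= 2)
  stopifnot(inherits(params0, "bending_params"))
  if (!is.list(observed) || is.null(observed$residuals) || is.null(observed$energies)) {
    abort("`observed` must be a list with elements `residuals` and `energies`")
  }
  stopifnot(
    length(observed$residuals) == length(fields),
    length(observed$energies) == length(fields)
  )
  c0 <- params0$c0
  res_norm <- sum(purrr::map2_dbl(fields, observed$residuals, function(f, r) {
    sum(f$dA * .UM2 * r^2)
  }))
  if (res_norm <= 0) res_norm <- 1
  en_norm <- sum(observed$energies^2)
  if (en_norm <= 0) en_norm <- 1

  trace_env <- new.env()
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)

  objective <- function(logpar) {
    kc <- exp(logpar[1])
    kd <- exp(logpar[2])
    pars <- structure(list(k_c = kc, k_d = kd, c0 = c0), class = "bending_params")
    sols <- purrr::map(fields, solve_inverse_bending, params = pars)
    res_mis <- sum(purrr::pmap_dbl(
      list(fields, sols, observed$residuals),
      function(f, s, r_obs) {
        r_mod <- s$dp - 2 * s$lam * f$H / .UM + .el_geom_term(f, pars)
        sum(f$dA * .UM2 * (r_mod - r_obs)^2)
      }
    ))
    en_mis <- sum(purrr::pmap_dbl(
      list(fields, sols, observed$energies),
      function(f, s, e_obs) {
        (helfrich_energy(f, pars, s$lam, s$dp) - e_obs)^2
      }
    ))
    val <- res_mis / res_norm + en_mis / en_norm
    trace_env$best <- min(trace_env$best, val)
    trace_env$trace <- c(trace_env$trace, trace_env$best)
    val
  }

  ## Deterministic warm start.  The profiled residual model is exactly linear
  ## in k_c (solutions and geometric term all scale with it), so the misfit
  ## minimiser has the closed form <r1, r_obs> / <r1, r1> with r1 the model
  ## residual at unit k_c; given k_c, the energy misfit is linear in k_d.
  ## The simplex then polishes both from this projection (falling back to
  ## params0, e.g. the homogeneous-sheet relation, if it degenerates).
  unit_pars <- structure(list(k_c = 1, k_d = 0, c0 = c0), class = "bending_params")
  sols1 <- purrr::map(fields, solve_inverse_bending, params = unit_pars)
  num <- den <- 0
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    r1 <- sols1[[i]]$dp - 2 * sols1[[i]]$lam * f$H / .UM + .el_geom_term(f, unit_pars)
    num <- num + sum(f$dA * .UM2 * r1 * observed$residuals[[i]])
    den <- den + sum(f$dA * .UM2 * r1^2)
  }
  kc_ls <- if (den > 0 && num > 0) num / den else params0$k_c
  pars_ls <- structure(list(k_c = kc_ls, k_d = 0, c0 = c0), class = "bending_params")
  sols_ls <- purrr::map(fields, solve_inverse_bending, params = pars_ls)
  e0 <- purrr::pmap_dbl(list(fields, sols_ls), function(f, s) {
    helfrich_energy(f, pars_ls, s$lam, s$dp)
  })
  kd_ls <- mean(observed$energies - e0) * .ERG / (4 * pi)
  if (!is.finite(kd_ls) || kd_ls <= 0) kd_ls <- max(params0$k_d, kc_ls / 2)

  start <- log(c(max(kc_ls, 1e-25), kd_ls))
  opt <- suppressWarnings(optim(start, objective,
    method = "Nelder-Mead",
    control = list(reltol = reltol, maxit = 2000)
  ))
  if (opt$convergence != 0) {
    gr <- max(abs(
      (vapply(seq_along(opt$par), function(i) {
        e <- opt$par
        e[i] <- e[i] + 1e-6
        objective(e)
      }, numeric(1)) - opt$value) / 1e-6
    ))
    warn(sprintf(
      "optimizer did not fully converge (code %d); final gradient norm ~ %.3g",
      opt$convergence, gr
    ))
  }
  fitted <- structure(
    list(k_c = exp(opt$par[1]), k_d = exp(opt$par[2]), c0 = c0),
    class = "bending_params"
  )
  structure(
    list(
      params = fitted,
      solutions = purrr::map(fields, solve_inverse_bending, params = fitted),
      objective = opt$value,
      objective_trace = trace_env$trace,
      convergence = opt$convergence,
      n_shapes = length(fields)
    ),
    class = "bending_fit"
  )
}

#' @export
print.bending_fit <- function(x, ...) {
  cat(sprintf(
    "<bending_fit> k_c = %.5g erg, k_d = %.5g erg over %d shapes (objective %.4g)\n",
    x$params$k_c / .ERG, x$params$k_d / .ERG, x$n_shapes, x$objective
  ))
  invisible(x)
}
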