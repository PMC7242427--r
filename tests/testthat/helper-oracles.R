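# Independent numerical oracles, kept deliberately separate from the package's
# closed-form implementations.

# Mean/Gaussian curvature of the spheroid x = (a sin(th) cos(ph),
# a sin(th) sin(ph), c cos(th)) via finite-difference first and second
# fundamental forms (shape operator), central differences.
fd_shape_operator <- function(a, cc, theta, h = 1e-5) {
  X <- function(th, ph) c(a * sin(th) * cos(ph), a * sin(th) * sin(ph), cc * cos(th))
  ph <- 0.3 # generic azimuth; axisymmetry makes the result independent of it
  d1 <- function(f, t, p, it, ip) {
    (f(t + it * h, p + ip * h) - f(t - it * h, p - ip * h)) / (2 * h)
  }
  d2 <- function(f, t, p, it, ip) {
    (f(t + it * h, p + ip * h) - 2 * f(t, p) + f(t - it * h, p - ip * h)) / h^2
  }
  Xt <- d1(X, theta, ph, 1, 0)
  Xp <- d1(X, theta, ph, 0, 1)
  Xtt <- d2(X, theta, ph, 1, 0)
  Xpp <- d2(X, theta, ph, 0, 1)
  Xtp <- (X(theta + h, ph + h) - X(theta + h, ph - h) -
    X(theta - h, ph + h) + X(theta - h, ph - h)) / (4 * h^2)
  E <- sum(Xt * Xt)
  Ff <- sum(Xt * Xp)
  G <- sum(Xp * Xp)
  n <- c(
    Xt[2] * Xp[3] - Xt[3] * Xp[2],
    Xt[3] * Xp[1] - Xt[1] * Xp[3],
    Xt[1] * Xp[2] - Xt[2] * Xp[1]
  )
  n <- n / sqrt(sum(n^2))
  ## orient outward: radial component positive
  P <- X(theta, ph)
  if (sum(n * P) < 0) n <- -n
  ## second fundamental form against the *inward* normal so that a convex
  ## surface gets positive curvatures (matching the package's H = 1/R sphere
  ## convention with outward normals)
  L <- -sum(Xtt * n)
  M <- -sum(Xtp * n)
  N <- -sum(Xpp * n)
  denom <- E * G - Ff^2
  list(
    H = (E * N - 2 * Ff * M + G * L) / (2 * denom),
    K = (L * N - M^2) / denom
  )
}

# Surface area of the spheroid by adaptive 1-D quadrature of the
# surface-of-revolution integrand (independent of Gauss-Legendre weights).
area_by_integrate <- function(a, cc) {
  2 * pi * a * stats::integrate(
    function(th) sin(th) * sqrt(a^2 * cos(th)^2 + cc^2 * sin(th)^2),
    0, pi,
    rel.tol = 1e-12
  )$value
}

# Laplace-Beltrami of an axisymmetric scalar on the spheroid by nested central
# differences of the closed-form integrand (independent of the package's
# analytic derivative chain).
lap_by_fd <- function(a, cc, theta, f, h = 1e-4) {
  w <- function(th) sqrt(a^2 * cos(th)^2 + cc^2 * sin(th)^2)
  P <- function(th) {
    (a * sin(th) / w(th)) * (f(th + 1e-6) - f(th - 1e-6)) / 2e-6
  }
  (P(theta + h) - P(theta - h)) / (2 * h) / (w(theta) * a * sin(theta))
}

# The reference equilibrium-shape family (0-50 mM), used across tests.
table2_shapes <- function() {
  tibble::tibble(
    conc = c(0, 10, 20, 30, 40, 50),
    a = c(8.00, 8.20, 8.32, 8.39, 8.47, 8.53),
    c = c(2.00, 2.06, 2.10, 2.13, 2.15, 2.17)
  )
}

# Reversible-regime configuration (disruption off) used by dynamics tests.
reversible_config <- function(conc = 50, ...) {
  swelling_config(
    ellipsoid_shape(8, 2),
    medium_state(c(Na = conc, Cl = conc), c(Na = 1, Cl = 1)),
    rigidity_params(beta0 = 0, betaz = 0),
    partition_rule = "self-similar",
    ...
  )
}

# Synthetic trajectory following the linearized closed form exactly; used for
# parameter-recovery tests.
linearized_trajectory <- function(model, t_end = 60, n = 200, v0 = 536.1651) {
  t <- seq(0, t_end, length.out = n)
  dv <- linearized_solution(model, t)
  traj <- tibble::tibble(
    time_s = t, V_um3 = v0 + dv, dP_imm_Pa = model$alpha * dv,
    dP_os_Pa = model$dP_os, a_um = NA_real_, c_um = NA_real_,
    S_um2 = model$S_bar, dr_um = NA_real_, dz_um = NA_real_,
    zeta = NA_real_, xi = NA_real_
  )
  class(traj) <- c("swelling_trajectory", class(traj))
  traj
}
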