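#' Oblate axisymmetric ellipsoid shape
#'
#' Constructs the cell geometry used throughout the package: a spheroid with
#' equal equatorial semi-axes `a = b` (along x and y) and polar semi-axis `c`
#' (along z), all in micrometres.  An erythrocyte at rest is well approximated
#' by `a = 8`, `c = 2`.
#'
#' The oblate orientation `a >= c` is the intended regime; a prolate shape
#' (`c > a`) is permitted -- swelling can change the aspect ratio -- but is
#' flagged with a warning.
#'
#' @param a Equatorial semi-axis, um.  Must be positive.
#' @param c Polar semi-axis, um.  Must be positive.
#' @return An object of class `ellipsoid_shape`: a list with elements `a`
#'   and `c` (um).
#' @examples
#' ellipsoid_shape(8, 2)
#' @export
ellipsoid_shape <- function(a, c) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    abort("`a` must be a single positive number (um).")
  }
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    abort("`c` must be a single positive number (um).")
  }
  if (c > a * (1 + 1e-12)) {
    warn(sprintf(
      "shape is prolate (c = %.4g > a = %.4g); oblate geometry was intended",
      c, a
    ))
  }
  structure(list(a = a, c = c), class = "ellipsoid_shape")
}

#' @export
print.ellipsoid_shape <- function(x, ...) {
  cat(sprintf(
    "<ellipsoid_shape> a = b = %.6g um, c = %.6g um (V = %.6g um^3, S = %.6g um^2)\n",
    x$a, x$c, ellipsoid_volume(x), ellipsoid_area(x)
  ))
  invisible(x)
}

.as_shape <- function(shape) {
  if (inherits(shape, "ellipsoid_shape")) return(shape)
  if (is.numeric(shape) && length(shape) == 2L) {
    return(ellipsoid_shape(shape[[1]], shape[[2]]))
  }
  abort("`shape` must be an `ellipsoid_shape` or a numeric vector c(a, c).")
}

## bare closed forms, vectorised, no validation (internal hot path)
.ell_vol <- function(a, c) 4 / 3 * pi * a^2 * c

.ell_area <- function(a, c) {
  ## oblate closed form 2*pi*a^2*(1 + ((1-e^2)/e) * artanh(e)), e^2 = 1-c^2/a^2.
  ## Near a = c the eccentricity formula is 0/0; switch to the sphere/series
  ## limit, which is continuous to O(e^4).
  out <- numeric(length(a))
  e2 <- 1 - (c / a)^2
  near <- abs(1 - c / a) < 1e-8 | e2 <= 0
  if (any(near)) {
    ## series: S = 4*pi*a^2*(1 - e^2/3 + O(e^4))
    out[near] <- 4 * pi * a[near]^2 * (1 - e2[near] / 3)
  }
  if (any(!near)) {
    e <- sqrt(e2[!near])
    out[!near] <- 2 * pi * a[!near]^2 * (1 + ((1 - e2[!near]) / e) * atanh(e))
  }
  out
}

#' Volume of an oblate axisymmetric ellipsoid
#'
#' Closed form `(4/3) * pi * a^2 * c`.
#'
#' @param shape An [ellipsoid_shape()] (or numeric `c(a, c)` in um).
#' @return Volume, um^3.
#' @examples
#' ellipsoid_volume(ellipsoid_shape(8, 2)) # 536.165 um^3
#' @export
ellipsoid_volume <- function(shape) {
  shape <- .as_shape(shape)
  .ell_vol(shape$a, shape$c)
}

#' Surface area of an oblate axisymmetric ellipsoid
#'
#' Closed form for `a > c`; continuous sphere/series limit as `c -> a`.
#'
#' @inheritParams ellipsoid_volume
#' @return Surface area, um^2.
#' @examples
#' ellipsoid_area(ellipsoid_shape(8, 2)) # ~455.68 um^2
#' @export
ellipsoid_area <- function(shape) {
  shape <- .as_shape(shape)
  .ell_area(shape$a, shape$c)
}

#' Curvature field of a spheroid of revolution
#'
#' Samples the surface at Gauss--Legendre nodes in the polar angle
#' `theta in (0, pi)` (axisymmetry reduces every surface integral to 1-D with
#' spectral accuracy) and evaluates the closed-form principal curvatures, the
#' mean and Gaussian curvatures, the surface Laplace--Beltrami operator applied
#' to H (fully analytic), and the area weights.
#'
#' Sign convention: outward unit normal, `H = (kappa1 + kappa2)/2 > 0` and
#' `K > 0` for convex shapes; a sphere of radius R has `H = 1/R`,
#' `K = 1/R^2`.
#'
#' With `r(theta) = a sin(theta)`, `z(theta) = c cos(theta)` and
#' `w = sqrt(a^2 cos^2 + c^2 sin^2)`, the meridional and azimuthal principal
#' curvatures are `a c / w^3` and `c / (a w)`; the area element integrated over
#' the azimuth is `2 pi a sin(theta) w dtheta`; and for an axisymmetric scalar
#' `f(theta)` the Laplace--Beltrami operator is
#' `(1 / (w r)) d/dtheta [ (r / w) df/dtheta ]`.
#'
#' @inheritParams ellipsoid_volume
#' @param n_samples Number of quadrature nodes (>= 8).  200 gives
#'   area and Gauss--Bonnet closure to well below 1e-8 relative.
#' @return A tibble of class `curvature_field` with one row per node:
#'   `theta` (rad), position `r`, `z` (um), outward normal components
#'   `n_r`, `n_z`, principal curvatures `kappa1`, `kappa2` (um^-1),
#'   `H` (um^-1), `K` (um^-2), `lap_H` (um^-3) and area weight `dA` (um^2).
#'   The generating shape is attached as attribute `shape`.
#' @examples
#' fld <- curvature_field(ellipsoid_shape(8, 2), 200)
#' sum(fld$K * fld$dA) / (4 * pi) # Gauss-Bonnet: 1
#' @export
curvature_field <- function(shape, n_samples = 200) {
  shape <- .as_shape(shape)
  if (!is.numeric(n_samples) || n_samples < 8) {
    abort("`n_samples` must be at least 8.")
  }
  a <- shape$a
  c <- shape$c
  gl <- pracma::gaussLegendre(as.integer(n_samples), 0, pi)
  th <- gl$x
  s <- sin(th)
  co <- cos(th)
  w <- sqrt(a^2 * co^2 + c^2 * s^2)

  k1 <- a * c / w^3 # meridional
  k2 <- c / (a * w) # azimuthal
  H <- (k1 + k2) / 2
  K <- k1 * k2
  dA <- 2 * pi * a * s * w * gl$w

  ## analytic Laplace-Beltrami of H:
  ##   lap H = P'(theta) / (w a sin),  P = (a sin / w) H'(theta)
  ## with H' = (c (c^2-a^2) sin cos / 2) (-3a/w^5 - 1/(a w^3)), which gives
  ##   P  = A sin^2 cos (-3a/w^6 - 1/(a w^4)),  A = a c (c^2 - a^2)/2
  A <- a * c * (c^2 - a^2) / 2
  wp <- (c^2 - a^2) * s * co / w
  Pp <- A * ((2 * s * co^2 - s^3) * (-3 * a / w^6 - 1 / (a * w^4)) +
    s^2 * co * (18 * a / w^7 + 4 / (a * w^5)) * wp)
  lap_H <- Pp / (w * a * s)

  out <- tibble::tibble(
    theta = th,
    r = a * s,
    z = c * co,
    n_r = c * s / w,
    n_z = a * co / w,
    kappa1 = k1,
    kappa2 = k2,
    H = H,
    K = K,
    lap_H = lap_H,
    dA = dA
  )
  attr(out, "shape") <- shape
  class(out) <- c("curvature_field", class(out))
  out
}
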