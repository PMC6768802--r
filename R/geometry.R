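#' Idealized unloaded left-ventricular geometry
#'
#' Axisymmetric thick-walled truncated-ellipsoid description of the unloaded
#' (zero pressure, zero active tension) LV.  The endocardial surface is a
#' prolate ellipsoid of revolution with equatorial (short-axis) radius
#' `r_endo` and apex-to-equator semi-axis `c_e = length / (1 + f_base)`,
#' truncated by the base plane at height `z_b = f_base * c_e` above the
#' equator.  Wall shells interpolate linearly: shell `lambda` in \[0, 1\] has
#' semi-axes `r_endo + lambda * wall` and `c_e + lambda * wall`.  The modeled
#' wall domain spans base plane to the endocardial apex level (the small solid
#' sub-apical cap is outside the computational domain, which keeps the
#' incompressible deformation ansatz well defined on the whole domain).
#'
#' The myofiber helix angle varies linearly across the wall from
#' `helix_endo` at the endocardium to `helix_epi` at the epicardium
#' (default +60 to -60 degrees); the sheet direction is transmural and the
#' sheet-normal completes the right-handed triad.
#'
#' @param r_endo Endocardial short-axis (equatorial) radius, mm.
#' @param wall Wall thickness, mm.
#' @param length Base-to-apex endocardial length, mm.
#' @param f_base Base truncation fraction in (0, 1): the base plane sits at
#'   `f_base * c_e` above the equator.
#' @param helix_endo,helix_epi Fiber helix angles at endo- and epicardium,
#'   degrees; `helix_endo >= helix_epi`.
#' @return An object of class `lv_geometry`.
#' @examples
#' lv_geometry(20, 10, 60)
#' @export
lv_geometry <- function(r_endo = 20, wall = 10, length = 60, f_base = 0.5,
                        helix_endo = 60, helix_epi = -60) {
  assert_scalar_number(r_endo, "r_endo", positive = TRUE)
  assert_scalar_number(wall, "wall", positive = TRUE)
  assert_scalar_number(length, "length", positive = TRUE)
  assert_scalar_number(f_base, "f_base")
  if (f_base <= 0 || f_base >= 1)
    abort_validation("f_base must lie strictly in (0, 1)")
  assert_scalar_number(helix_endo, "helix_endo")
  assert_scalar_number(helix_epi, "helix_epi")
  if (helix_endo < helix_epi)
    abort_validation("helix_endo must be >= helix_epi")
  c_e <- length / (1 + f_base)
  structure(list(
    r_endo = r_endo, wall = wall, length = length, f_base = f_base,
    helix_endo = helix_endo, helix_epi = helix_epi,
    c_e = c_e, z_base = f_base * c_e,
    r_epi = r_endo + wall, c_epi = c_e + wall
  ), class = "lv_geometry")
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(sprintf(
    paste0("LV geometry: endo radius %.3g mm, wall %.3g mm, length %.3g mm,\n",
           "  base fraction %.3g, helix %+.3g / %+.3g deg, ",
           "cavity %.4g ml, wall volume %.4g ml\n"),
    x$r_endo, x$wall, x$length, x$f_base, x$helix_endo, x$helix_epi,
    reference_cavity_volume(x), wall_volume(x)))
  invisible(x)
}

# closed-form volume of the solid of revolution of the ellipse (a, c)
# between z = lo and z = hi, closed by planes.
ellipse_revolution_volume <- function(a, c, lo, hi) {
  f <- function(z) z - z^3 / (3 * c^2)
  pi * a^2 * (f(hi) - f(lo))
}

#' Reference cavity volume of an unloaded geometry
#'
#' Volume of the endocardial solid of revolution closed by the base plane, ml.
#' @param geom An [lv_geometry()].
#' @return Volume in ml.
#' @export
reference_cavity_volume <- function(geom) {
  ellipse_revolution_volume(geom$r_endo, geom$c_e, -geom$c_e, geom$z_base) / 1e3
}

#' Wall volume of the modeled domain
#'
#' Myocardial wall volume between endo- and epicardial surfaces over the
#' modeled domain (base plane down to the endocardial apex level), ml.
#' @param geom An [lv_geometry()].
#' @return Volume in ml.
#' @export
wall_volume <- function(geom) {
  (ellipse_revolution_volume(geom$r_epi, geom$c_epi, -geom$c_e, geom$z_base) -
     ellipse_revolution_volume(geom$r_endo, geom$c_e, -geom$c_e, geom$z_base)) / 1e3
}

#' Kinematic boundary conditions
#'
#' The base plane is held at a prescribed axial position and the apex is
#' constrained to the long axis, mirroring the kinematic constraints imposed
#' at the base plane and apex of image-derived models.
#'
#' @param base_z Axial position of the base plane, mm.
#' @param apex_on_axis Logical; constrain the apex to the long axis.
#' @return An object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(base_z, apex_on_axis = TRUE) {
  assert_scalar_number(base_z, "base_z")
  structure(list(base_z = base_z, apex_on_axis = isTRUE(apex_on_axis)),
            class = "boundary_conditions")
}

helix_angle_deg <- function(geom, lambda) {
  geom$helix_endo + lambda * (geom$helix_epi - geom$helix_endo)
}

# reference radius^2 of material point (lambda, z0) and its lambda-derivative
reference_radius_sq <- function(geom, lambda, z0) {
  a0 <- geom$r_endo + lambda * geom$wall
  c0 <- geom$c_e + lambda * geom$wall
  a0^2 * (1 - z0^2 / c0^2)
}

#' Material point set of an unloaded geometry
#'
#' Tensor-product Gauss--Legendre quadrature points over the modeled wall
#' domain in material coordinates: transmural `lambda`, longitudinal `mu`
#' (0 = endocardial apex level, 1 = base plane) and circumferential `theta`
#' (midpoint rule over the periodic direction).  Weights are reference-volume
#' weights and sum to the wall volume of the reference configuration.
#'
#' @param geom An [lv_geometry()].
#' @param n_lambda,n_mu Gauss--Legendre point counts in the transmural and
#'   longitudinal directions.
#' @param n_theta Number of equally spaced circumferential stations.
#' @return A tibble of class `material_points` with columns `lambda`, `mu`,
#'   `theta`, `weight` (mm^3), `helix` (degrees) and reference Cartesian
#'   positions `x`, `y`, `z` (mm); the generating geometry is stored in
#'   attribute `geometry`.
#' @export
material_points <- function(geom, n_lambda = 4, n_mu = 6, n_theta = 8) {
  stopifnot(inherits(geom, "lv_geometry"))
  gl_l <- gauss_legendre(n_lambda, 0, 1)
  gl_m <- gauss_legendre(n_mu, 0, 1)
  theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  w_theta <- 2 * pi / n_theta

  grid <- expand.grid(i = seq_len(n_lambda), j = seq_len(n_mu),
                      k = seq_len(n_theta))
  lam <- gl_l$nodes[grid$i]
  mu <- gl_m$nodes[grid$j]
  th <- theta[grid$k]
  L_dom <- geom$z_base + geom$c_e
  z0 <- -geom$c_e + mu * L_dom
  a0 <- geom$r_endo + lam * geom$wall
  c0 <- geom$c_e + lam * geom$wall
  R0sq <- a0^2 * (1 - z0^2 / c0^2)
  # d(R0^2)/dlambda (smooth; avoids the sqrt singularity at the apex ring)
  dR0sq_dlam <- 2 * a0 * geom$wall * (1 - z0^2 / c0^2) +
    2 * a0^2 * z0^2 * geom$wall / c0^3
  w <- gl_l$weights[grid$i] * gl_m$weights[grid$j] * w_theta *
    0.5 * dR0sq_dlam * L_dom
  R0 <- sqrt(pmax(R0sq, 0))
  out <- tibble::tibble(
    lambda = lam, mu = mu, theta = th, weight = w,
    helix = helix_angle_deg(geom, lam),
    x = R0 * cos(th), y = R0 * sin(th), z = z0
  )
  attr(out, "geometry") <- geom
  class(out) <- c("material_points", class(out))
  out
}
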