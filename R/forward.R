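# Forward inflation operator and its inverse (deflation) on the idealized LV.
#
# Deformation ansatz (cylindrical coordinates, axisymmetric, no twist), with
# three generalized degrees of freedom q = (d0, s_l, s_q):
#   u      = (z_base - z0) / L          normalized depth, 0 at base, 1 at apex
#   Z      = z_base - L (u s_l + u^2 s_q)        axial remap, base plane fixed
#   phi'   = s_l + 2 s_q u                       axial stretch field
#   R^2    = R0^2 / phi' + d0 psi^2,             psi = 1 - z0^2/c_e^2
# The radial mode d0 (mm^2) inflates/deflates the cavity (the squared bump
# profile keeps the shear of the map bounded at the apex, where the energy
# integrand would otherwise be singular), s_l is a uniform axial stretch
# and s_q grades the axial stretch from base to apex.  det F = 1 pointwise
# and exactly for every q, so the ansatz is incompressible by construction
# and the hydrostatic pressure multiplier does no virtual work.  Equilibrium
# is the 3-component virtual-work balance
#   sum_g w_g [ C1 e^Q dQ/dq + Ta dEff/dq ] = P dV_cav/dq
# solved by a damped Newton iteration with load stepping and warm starts.

q_reference <- c(d0 = 0, s_l = 1, s_q = 0)
.n_dof <- 3L

# Precompute reference quantities on the internal (lambda, mu) quadrature
# grid (theta-independent by axisymmetry; theta weight integrated to 2*pi).
make_quad <- function(geom, n_lambda = 4, n_mu = 6) {
  gl_l <- gauss_legendre(n_lambda, 0, 1)
  gl_m <- gauss_legendre(n_mu, 0, 1)
  grid <- expand.grid(i = seq_len(n_lambda), j = seq_len(n_mu))
  lam <- gl_l$nodes[grid$i]
  mu <- gl_m$nodes[grid$j]
  L_dom <- geom$z_base + geom$c_e
  z0 <- -geom$c_e + mu * L_dom
  a0 <- geom$r_endo + lam * geom$wall
  c0 <- geom$c_e + lam * geom$wall
  R0sq <- a0^2 * (1 - z0^2 / c0^2)
  dR0sq_dlam <- 2 * a0 * geom$wall * (1 - z0^2 / c0^2) +
    2 * a0^2 * z0^2 * geom$wall / c0^3
  w <- gl_l$weights[grid$i] * gl_m$weights[grid$j] * 2 * pi *
    0.5 * dR0sq_dlam * L_dom
  # local wall frame in the (R, Z) plane: t transmural (outward shell
  # normal), l longitudinal (apex-to-base tangent); c is circumferential.
  nR <- sqrt(R0sq) / a0^2
  nZ <- z0 / c0^2
  nn <- sqrt(nR^2 + nZ^2)
  tR <- nR / nn; tZ <- nZ / nn
  lR <- -tZ; lZ <- tR
  hel <- helix_angle_deg(geom, lam) * pi / 180
  # cavity-volume quadrature along z0 (exact for the polynomial integrands)
  gz <- gauss_legendre(8, -geom$c_e, geom$z_base)
  psi_z <- 1 - gz$nodes^2 / geom$c_e^2
  u_z <- (geom$z_base - gz$nodes) / L_dom
  list(geom = geom, lam = lam, mu = mu, z0 = z0, u = (geom$z_base - z0) / L_dom,
       L_dom = L_dom, psi = 1 - z0^2 / geom$c_e^2, R0sq = R0sq, w = w,
       cphi = cos(hel), sphi = sin(hel), tR = tR, tZ = tZ, lR = lR, lZ = lZ,
       zq_w = gz$weights, psi_z = psi_z, u_z = u_z,
       n_lambda = n_lambda, n_mu = n_mu)
}

# Green strain components in the fiber/sheet/normal frame at the quadrature
# points (or at externally supplied reference data) for DOF vector q.
# With derivs = TRUE, also returns the analytic partial derivatives of every
# strain component with respect to the three generalized DOFs.
strain_field <- function(pre, q, data = pre, derivs = FALSE) {
  d0 <- q[[1]]; s_l <- q[[2]]; s_q <- q[[3]]
  geom <- pre$geom
  u <- data$u; z0 <- data$z0; psi <- data$psi; R0sq <- data$R0sq
  phip <- s_l + 2 * s_q * u
  if (any(phip <= 0)) return(NULL)
  Rsq <- R0sq / phip + d0 * psi^2
  if (any(Rsq <= 0)) return(NULL)
  R <- sqrt(Rsq)
  R0 <- sqrt(R0sq)
  L_dom <- pre$L_dom
  dphip_dz0 <- -2 * s_q / L_dom
  dpsi_dz0 <- -2 * z0 / geom$c_e^2
  dRsq_dz0 <- -R0sq * dphip_dz0 / phip^2 + 2 * d0 * psi * dpsi_dz0
  F_RR <- R0 / (R * phip)
  F_TT <- R / R0
  F_ZZ <- phip
  F_RZ <- dRsq_dz0 / (2 * R)
  E_RR <- (F_RR^2 - 1) / 2
  E_TT <- (F_TT^2 - 1) / 2
  E_ZZ <- (F_ZZ^2 + F_RZ^2 - 1) / 2
  E_RZ <- (F_RR * F_RZ) / 2
  lR <- data$lR; lZ <- data$lZ; tR <- data$tR; tZ <- data$tZ
  cphi <- data$cphi; sphi <- data$sphi
  rotate_fsn <- function(E_RR, E_TT, E_ZZ, E_RZ) {
    # (c, l, t): circumferential, longitudinal, transmural; then the fiber
    # rotation by the helix angle in the (c, l) plane; s = t.
    E_ll <- lR^2 * E_RR + 2 * lR * lZ * E_RZ + lZ^2 * E_ZZ
    E_tt <- tR^2 * E_RR + 2 * tR * tZ * E_RZ + tZ^2 * E_ZZ
    E_lt <- lR * tR * E_RR + (lR * tZ + lZ * tR) * E_RZ + lZ * tZ * E_ZZ
    E_cc <- E_TT
    list(
      e_ff = cphi^2 * E_cc + sphi^2 * E_ll,
      e_nn = sphi^2 * E_cc + cphi^2 * E_ll,
      e_fn = cphi * sphi * (E_ll - E_cc),
      e_ss = E_tt,
      e_fs = sphi * E_lt,
      e_sn = cphi * E_lt
    )
  }
  out <- rotate_fsn(E_RR, E_TT, E_ZZ, E_RZ)
  if (!derivs) return(out)

  # analytic partials with respect to q = (d0, s_l, s_q)
  dphip <- list(d0 = 0, s_l = 1, s_q = 2 * u)
  dRsq <- list(d0 = psi^2,
               s_l = -R0sq / phip^2,
               s_q = -2 * u * R0sq / phip^2)
  d_dRsq_dz0 <- list(
    d0 = 2 * psi * dpsi_dz0,
    s_l = 2 * R0sq * dphip_dz0 / phip^3,
    s_q = 2 * R0sq / (L_dom * phip^2) + 4 * u * R0sq * dphip_dz0 / phip^3
  )
  dE <- vector("list", .n_dof)
  for (j in seq_len(.n_dof)) {
    dphi_j <- dphip[[j]]; dRsq_j <- dRsq[[j]]
    dF_RR <- R0 * (-0.5 * Rsq^(-1.5) * dRsq_j / phip -
                     Rsq^(-0.5) * dphi_j / phip^2)
    dF_TT <- 0.5 * dRsq_j / (R * R0)
    dF_ZZ <- dphi_j
    dF_RZ <- d_dRsq_dz0[[j]] / (2 * R) - dRsq_dz0 * dRsq_j / (4 * Rsq^1.5)
    dE_RR <- F_RR * dF_RR
    dE_TT <- F_TT * dF_TT
    dE_ZZ <- F_ZZ * dF_ZZ + F_RZ * dF_RZ
    dE_RZ <- (dF_RR * F_RZ + F_RR * dF_RZ) / 2
    dE[[j]] <- rotate_fsn(dE_RR, dE_TT, dE_ZZ, dE_RZ)
  }
  c(out, list(dE = dE))
}

# cavity volume (mm^3) and its gradient with respect to q
cavity_volume_q <- function(pre, q) {
  d0 <- q[[1]]; s_l <- q[[2]]; s_q <- q[[3]]
  geom <- pre$geom
  phip_z <- s_l + 2 * s_q * pre$u_z
  a2psi <- geom$r_endo^2 * pre$psi_z
  delta <- d0 * pre$psi_z^2
  V <- pi * sum(pre$zq_w * (a2psi + delta * phip_z))
  grad <- c(
    d0 = pi * sum(pre$zq_w * pre$psi_z^2 * phip_z),
    s_l = pi * sum(pre$zq_w * delta),
    s_q = pi * sum(pre$zq_w * delta * 2 * pre$u_z)
  )
  list(V = V, grad = grad)
}

# virtual-work residual r(q) (length 3) and a magnitude scale for the
# relative convergence test; NULL signals an inadmissible q.
vw_residual <- function(pre, gpar, beta, P, t_z, q) {
  E <- strain_field(pre, q, derivs = TRUE)
  if (is.null(E)) return(NULL)
  Q <- q_exponent_vec(gpar$c2, gpar$c3, gpar$c4,
                      E$e_ff, E$e_ss, E$e_nn, E$e_fs, E$e_fn, E$e_sn)
  if (any(Q > 500)) return(NULL)
  eQ <- exp(Q)
  lam2 <- 2 * E$e_ff + 1
  if (any(lam2 <= 0)) return(NULL)
  Ta <- t_z * (1 + beta * (sqrt(lam2) - 1))
  cav <- cavity_volume_q(pre, q)
  r <- numeric(.n_dof)
  s <- numeric(.n_dof)
  for (j in seq_len(.n_dof)) {
    d <- E$dE[[j]]
    dQ <- 2 * gpar$c2 * E$e_ff * d$e_ff +
      2 * gpar$c3 * (E$e_ss * d$e_ss + E$e_nn * d$e_nn + 2 * E$e_sn * d$e_sn) +
      2 * gpar$c4 * (2 * E$e_fs * d$e_fs + 2 * E$e_fn * d$e_fn)
    int_pass <- pre$w * gpar$c1 * eQ * dQ
    int_act <- pre$w * Ta * d$e_ff
    r[j] <- sum(int_pass) + sum(int_act) - P * cav$grad[j]
    s[j] <- sum(abs(int_pass)) + sum(abs(int_act)) + abs(P * cav$grad[j])
  }
  list(r = r, scale = pmax(s, 1e-6), V = cav$V)
}

# order of strain components returned by strain_field
.sf_names <- c("e_ff", "e_nn", "e_fn", "e_ss", "e_fs", "e_sn")

clamp_q <- function(pre, q) {
  a2 <- pre$geom$r_endo^2
  q[2] <- min(max(q[2], 0.2), 4)                    # s_l
  q[3] <- min(max(q[3], (0.02 - q[2]) / 2), 1.5)    # s_q
  phip_max <- max(q[2], q[2] + 2 * q[3])
  # keep R^2 > 0 on the endocardium (a2/phip + d0 psi > 0) and cap the
  # bracket expansion at 3x the reference radius
  q[1] <- min(max(q[1], 0.05 * a2 - a2 / phip_max), 9 * a2)
  q
}

newton_solve <- function(pre, gpar, beta, P, t_z, q, tol = 1e-8,
                         max_iter = 40L) {
  res <- vw_residual(pre, gpar, beta, P, t_z, q)
  if (is.null(res)) return(NULL)
  for (iter in seq_len(max_iter)) {
    if (max(abs(res$r) / res$scale) < tol)
      return(list(q = q, residual = max(abs(res$r) / res$scale), V = res$V))
    J <- matrix(0, .n_dof, .n_dof)
    hj <- c(1e-5 * pre$geom$r_endo^2, 1e-6, 1e-6)
    for (j in seq_len(.n_dof)) {
      qj <- q; qj[j] <- q[j] + hj[j]
      rj <- vw_residual(pre, gpar, beta, P, t_z, qj)
      if (is.null(rj)) { qj[j] <- q[j] - hj[j]
        rj <- vw_residual(pre, gpar, beta, P, t_z, qj)
        if (is.null(rj)) return(NULL)
        J[, j] <- (res$r - rj$r) / hj[j]
      } else J[, j] <- (rj$r - res$r) / hj[j]
    }
    dq <- tryCatch(solve(J, -res$r), error = function(cnd) NULL)
    if (is.null(dq))
      dq <- tryCatch(solve(J + diag(1e-8 * max(abs(J)), .n_dof), -res$r),
                     error = function(cnd) NULL)
    if (is.null(dq)) return(NULL)
    nr0 <- sqrt(sum((res$r / res$scale)^2))
    step <- 1
    repeat {
      qn <- clamp_q(pre, q + step * dq)
      resn <- vw_residual(pre, gpar, beta, P, t_z, qn)
      if (!is.null(resn) &&
          sqrt(sum((resn$r / resn$scale)^2)) < (1 - 1e-4 * step) * nr0) break
      step <- step / 2
      if (step < 1 / 256) break
    }
    if (step < 1 / 256 && (is.null(resn) ||
        sqrt(sum((resn$r / resn$scale)^2)) >= nr0))
      return(NULL)  # stagnated
    q <- qn
    res <- resn
  }
  if (max(abs(res$r) / res$scale) < tol * 10)
    return(list(q = q, residual = max(abs(res$r) / res$scale), V = res$V))
  NULL
}

# Equilibrium solve with load stepping (<= 0.25 kPa pressure increments) and
# optional warm start (tried first at the full load).
solve_equilibrium <- function(pre, gpar, beta, P, t_z, warm_start = NULL,
                              tol = 1e-8) {
  if (!is.null(warm_start)) {
    sol <- newton_solve(pre, gpar, beta, P, t_z, clamp_q(pre, warm_start), tol)
    if (!is.null(sol)) return(sol)
  }
  n_steps <- max(1L, ceiling(abs(P) / 0.25), ceiling(abs(t_z) / 2))
  q <- q_reference
  k <- 1L
  tau_prev <- 0
  tau <- 1 / n_steps
  guard <- 0L
  while (tau_prev < 1 - 1e-12) {
    sol <- newton_solve(pre, gpar, beta, P * tau, t_z * tau, q, tol)
    if (is.null(sol)) {
      tau <- tau_prev + (tau - tau_prev) / 2
      guard <- guard + 1L
      if (guard > 60L)
        abort_nonconvergence(sprintf(
          "equilibrium solve failed at load fraction %.4g of P = %g kPa, t_z = %g kPa",
          tau, P, t_z))
      next
    }
    q <- sol$q
    tau_prev <- tau
    tau <- min(1, tau_prev + 1 / n_steps)
  }
  sol
}

# deformed positions from reference data (R0sq, z0, u, psi per point)
deformed_positions_data <- function(geom, q, data, theta) {
  d0 <- q[[1]]; s_l <- q[[2]]; s_q <- q[[3]]
  L_dom <- geom$z_base + geom$c_e
  phip <- s_l + 2 * s_q * data$u
  Rsq <- data$R0sq / phip + d0 * data$psi^2
  if (any(phip <= 0) || any(Rsq < -1e-9))
    abort_unphysical("deformation map inadmissible at requested points")
  R <- sqrt(pmax(Rsq, 0))
  Z <- geom$z_base - L_dom * (data$u * s_l + data$u^2 * s_q)
  list(x = R * cos(theta), y = R * sin(theta), z = Z)
}

# deformed positions for material points (lambda, mu, theta) of geometry geom
deformed_positions <- function(geom, q, lambda, mu, theta) {
  data <- point_reference_data(geom, list(lambda = lambda, mu = mu))
  deformed_positions_data(geom, q, data, theta)
}

#' Inflate the unloaded LV to a load state (forward operator)
#'
#' Solves the quasi-static equilibrium of the idealized incompressible LV
#' wall under cavity pressure `p` and residual active tension `t_z`, i.e. the
#' forward operator mapping the unloaded configuration to the deformed
#' configuration at one load state.  The generalized displacement modes
#' satisfy the virtual-work balance (internal stress work against the strain
#' variations equals the pressure work on the endocardial surface) to a
#' relative tolerance of 1e-8; incompressibility holds pointwise by
#' construction of the ansatz.
#'
#' @param x0 Unloaded geometry, an [lv_geometry()].
#' @param g Constitutive parameters, a [guccione_params()].
#' @param p Cavity pressure, kPa.
#' @param t_z Residual active tension parameter, kPa.
#' @param beta Length-dependence coefficient of the active tension.
#' @param bc Optional [boundary_conditions()]; the base plane position must
#'   agree with the geometry (the model never moves the base plane).
#' @param points Optional [material_points()]-style tibble (columns `lambda`,
#'   `mu`, `theta`) at which deformed positions are reported; defaults to the
#'   quadrature points of `x0`.
#' @param n_lambda,n_mu Internal quadrature orders for the virtual-work
#'   integral.
#' @param warm_start Optional DOF vector from a nearby solve.
#' @return An object of class `deformed_state`: the geometry, the DOF vector
#'   `q`, load, deformed `points` (with Green strain components in the
#'   fiber/sheet/normal frame), cavity `volume` (ml) and the scaled
#'   equilibrium `residual`.
#' @export
inflate <- function(x0, g, p, t_z = 0, beta = 1.45, bc = NULL, points = NULL,
                    n_lambda = 4, n_mu = 6, warm_start = NULL) {
  stopifnot(inherits(x0, "lv_geometry"), inherits(g, "guccione_params"))
  assert_scalar_number(p, "p")
  assert_scalar_number(t_z, "t_z")
  if (!is.null(bc)) {
    stopifnot(inherits(bc, "boundary_conditions"))
    if (abs(bc$base_z - x0$z_base) > 1e-6)
      abort_validation("boundary base plane position disagrees with the geometry")
  }
  pre <- make_quad(x0, n_lambda, n_mu)
  sol <- solve_equilibrium(pre, g, beta, p, t_z, warm_start = warm_start)
  build_deformed_state(x0, g, p, t_z, beta, sol, points, pre)
}

build_deformed_state <- function(x0, g, p, t_z, beta, sol, points, pre) {
  if (is.null(points)) points <- material_points(x0)
  pos <- deformed_positions(x0, sol$q, points$lambda, points$mu, points$theta)
  pts <- points
  pts$x <- pos$x; pts$y <- pos$y; pts$z <- pos$z
  E <- strain_field(pre, sol$q, data = point_reference_data(x0, points))
  for (nm in .sf_names) pts[[nm]] <- E[[nm]]
  structure(list(
    geometry = x0, params = g, p = p, t_z = t_z, beta = beta,
    q = sol$q, points = pts, volume = sol$V / 1e3, residual = sol$residual
  ), class = "deformed_state")
}

# Reference data block (same fields as make_quad uses) for arbitrary points.
# When `positions` (a data frame with x, y, z) is supplied, the reference
# radii and heights are taken from those observed positions instead of the
# analytic surfaces of `geom`: this realizes "the reference state is the
# observed frame" exactly, with `geom` providing only the mode shapes,
# material frame and quadrature bookkeeping.
point_reference_data <- function(geom, points, positions = NULL) {
  lam <- points$lambda; mu <- points$mu
  L_dom <- geom$z_base + geom$c_e
  a0 <- geom$r_endo + lam * geom$wall
  c0 <- geom$c_e + lam * geom$wall
  if (is.null(positions)) {
    z0 <- -geom$c_e + mu * L_dom
    R0sq <- a0^2 * (1 - z0^2 / c0^2)
  } else {
    z0 <- positions$z
    R0sq <- positions$x^2 + positions$y^2
  }
  nR <- sqrt(pmax(R0sq, 0)) / a0^2
  nZ <- z0 / c0^2
  nn <- sqrt(nR^2 + nZ^2)
  tR <- nR / nn; tZ <- nZ / nn
  hel <- helix_angle_deg(geom, lam) * pi / 180
  list(z0 = z0, u = (geom$z_base - z0) / L_dom, psi = 1 - z0^2 / geom$c_e^2,
       R0sq = R0sq, tR = tR, tZ = tZ, lR = -tZ, lZ = tR,
       cphi = cos(hel), sphi = sin(hel))
}

#' @export
print.deformed_state <- function(x, ...) {
  cat(sprintf(
    "Deformed LV state: p = %g kPa, t_z = %g kPa, cavity %.4g ml, residual %.2e\n",
    x$p, x$t_z, x$volume, x$residual))
  invisible(x)
}

#' Cavity volume of a deformed state
#'
#' Volume of the deformed endocardial surface of revolution closed by the
#' base plane, computed by quadrature along the long axis.
#'
#' @param s A `deformed_state` (from [inflate()]) or an [lv_geometry()]
#'   (reference volume).
#' @return Volume in ml.
#' @export
cavity_volume <- function(s) {
  if (inherits(s, "lv_geometry")) {
    pre <- make_quad(s)
    return(cavity_volume_q(pre, q_reference)$V / 1e3)
  }
  stopifnot(inherits(s, "deformed_state"))
  pre <- make_quad(s$geometry)
  cavity_volume_q(pre, s$q)$V / 1e3
}

#' Green strain of a deformed state at a material point
#'
#' Evaluates the Green--Lagrange strain of the deformation ansatz at one
#' material point, rotated into the local fiber/sheet/normal frame built from
#' the transmural helix angle.
#'
#' @param x0 The unloaded [lv_geometry()].
#' @param s The `deformed_state`.
#' @param point Named list or vector with `lambda`, `mu` (and optionally
#'   `theta`, irrelevant by axisymmetry).
#' @return A [green_strain()] object.
#' @export
green_strain_fsn <- function(x0, s, point) {
  stopifnot(inherits(s, "deformed_state"))
  pt <- as.list(point)
  data <- point_reference_data(x0, list(lambda = pt$lambda, mu = pt$mu))
  pre <- make_quad(x0, 2, 2)  # only geometry scalars are used
  E <- strain_field(pre, s$q, data = data)
  green_strain(e_ff = E$e_ff, e_ss = E$e_ss, e_nn = E$e_nn,
               e_fs = E$e_fs, e_fn = E$e_fn, e_sn = E$e_sn, check = FALSE)
}

#' Fit an idealized unloaded-class geometry to a material point cloud
#'
#' Least-squares projection of an observed point cloud (with known material
#' coordinates) onto the unloaded geometry class: the long-axis extent is
#' recovered by a linear fit of the axial coordinates, then the endocardial
#' radius and wall thickness by a Gauss--Newton fit of the squared radii.
#' Used to initialize the reference state from an observed frame and inside
#' the deflation fixed-point iteration.
#'
#' @param points Tibble with columns `lambda`, `mu`, `theta`, `x`, `y`, `z`.
#' @param template Optional [lv_geometry()] providing helix angles and
#'   starting values.
#' @return An [lv_geometry()].
#' @export
fit_geometry <- function(points, template = NULL) {
  mu <- points$mu
  X <- cbind(mu, -(1 - mu))
  zc <- stats::lm.fit(X, points$z)$coefficients
  z_b <- zc[[1]]; c_e <- zc[[2]]
  if (c_e <= 0 || z_b <= 0)
    abort_validation("point cloud does not define a valid long-axis extent")
  L_dom <- z_b + c_e
  z0 <- -c_e + mu * L_dom
  Robs2 <- points$x^2 + points$y^2
  lam <- points$lambda
  r <- if (!is.null(template)) template$r_endo else sqrt(stats::quantile(Robs2, 0.5)[[1]])
  h <- if (!is.null(template)) template$wall else r / 2
  for (it in 1:40) {
    a0 <- r + lam * h
    c0 <- c_e + lam * h
    fac <- 1 - z0^2 / c0^2
    res <- a0^2 * fac - Robs2
    Jr <- 2 * a0 * fac
    Jh <- 2 * a0 * lam * fac + a0^2 * (2 * z0^2 / c0^3) * lam
    J <- cbind(Jr, Jh)
    dp <- tryCatch(unname(qr.solve(J, -res)), error = function(cnd) c(0, 0))
    step <- 1
    if (!all(is.finite(dp))) break
    # keep parameters positive
    while ((r + step * dp[1]) <= 0.1 || (h + step * dp[2]) <= 0.1) step <- step / 2
    r <- r + step * dp[1]
    h <- h + step * dp[2]
    if (max(abs(step * dp)) < 1e-10) break
  }
  tpl <- template
  lv_geometry(r_endo = r, wall = h, length = L_dom, f_base = z_b / c_e,
              helix_endo = if (is.null(tpl)) 60 else tpl$helix_endo,
              helix_epi = if (is.null(tpl)) -60 else tpl$helix_epi)
}

#' Recover the unloaded configuration from a loaded observation (deflation)
#'
#' Backward operator: given an observed deformed point cloud, the
#' constitutive parameters and the load state it was observed under, finds
#' the unloaded geometry whose inflation reproduces the observation.
#' Implemented as a damped fixed-point iteration on the geometry parameters
#' (update = observation minus inflation of the current iterate, in fitted
#' parameter space), damping 0.8, iteration cap 100.
#'
#' @param y Observation: a `deformed_state` or a tibble of material points
#'   with observed positions.
#' @param g Constitutive parameters, a [guccione_params()].
#' @param p,t_z Load state at which `y` was observed (kPa).
#' @param beta Length-dependence coefficient of the active tension.
#' @param bc Optional [boundary_conditions()].
#' @param template Optional [lv_geometry()] template for the geometry fit.
#' @param tol Position RMS tolerance, mm.
#' @return An [lv_geometry()] `x0` such that `inflate(x0, g, p, t_z)`
#'   reproduces the observed positions (RMS < `tol` for observations in the
#'   model range).
#' @export
deflate <- function(y, g, p, t_z = 0, beta = 1.45, bc = NULL, template = NULL,
                    tol = 1e-6) {
  pts <- if (inherits(y, "deformed_state")) y$points else y
  if (inherits(y, "deformed_state") && is.null(template)) template <- y$geometry
  geo <- fit_geometry(pts, template = template)
  damping <- 0.8
  warm <- NULL
  obs_xyz <- cbind(pts$x, pts$y, pts$z)
  last_rms <- Inf
  upd <- pts
  for (it in seq_len(100L)) {
    st <- inflate(geo, g, p, t_z, beta = beta, bc = bc, points = pts,
                  warm_start = warm)
    warm <- st$q
    sim_xyz <- cbind(st$points$x, st$points$y, st$points$z)
    last_rms <- sqrt(mean(rowSums((sim_xyz - obs_xyz)^2)))
    if (last_rms < tol) return(geo)
    # backward-displacement update: move the current reference cloud by the
    # damped observation error, then project onto the unloaded-geometry class
    ref <- deformed_positions(geo, q_reference, pts$lambda, pts$mu, pts$theta)
    upd$x <- ref$x + damping * (obs_xyz[, 1] - sim_xyz[, 1])
    upd$y <- ref$y + damping * (obs_xyz[, 2] - sim_xyz[, 2])
    upd$z <- ref$z + damping * (obs_xyz[, 3] - sim_xyz[, 3])
    geo_new <- fit_geometry(upd, template = geo)
    dpar <- max(abs(c(geo_new$r_endo - geo$r_endo, geo_new$wall - geo$wall,
                      geo_new$length - geo$length)))
    geo <- geo_new
    # an observation outside the model range cannot reach the position
    # tolerance; the parameter fixed point (its model-range projection) can
    if (dpar < 1e-9) return(geo)
  }
  abort_nonconvergence(sprintf(
    "deflation fixed point did not converge in 100 iterations (last RMS %.3g mm)",
    last_rms), rms = last_rms)
}
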