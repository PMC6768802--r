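geo <- lv_geometry(20, 10, 60)
gpar <- table1_params()

test_that("quadrature weights integrate the reference wall volume", {
  mp <- material_points(geo)
  expect_equal(sum(mp$weight) / 1e3, wall_volume(geo), tolerance = 1e-6)
  # quadrature refinement leaves the integral essentially unchanged
  mp2 <- material_points(geo, n_lambda = 8, n_mu = 12, n_theta = 8)
  expect_equal(sum(mp2$weight), sum(mp$weight), tolerance = 1e-6)
})

test_that("zero load leaves the geometry unloaded", {
  st <- inflate(geo, gpar, 0, 0)
  mp <- material_points(geo)
  expect_equal(st$points$x, mp$x, tolerance = 1e-12)
  expect_equal(st$points$z, mp$z, tolerance = 1e-12)
  expect_equal(st$volume, reference_cavity_volume(geo), tolerance = 1e-10)
  expect_lt(st$residual, 1e-8)
})

test_that("cavity volume grows with pressure and shrinks with active tension", {
  vols <- vapply(c(0.5, 1.0, 1.5, 2.0),
                 function(p) inflate(geo, gpar, p, 0)$volume, 0)
  expect_true(all(diff(vols) > 0))
  expect_gt(vols[1], reference_cavity_volume(geo))
  v_act <- vapply(c(2, 5, 8), function(tz) inflate(geo, gpar, 0, tz)$volume, 0)
  expect_true(all(diff(v_act) < 0))
  expect_lt(v_act[1], reference_cavity_volume(geo))
  # active tension also deflates at fixed positive pressure
  expect_lt(inflate(geo, gpar, 1, 5)$volume, inflate(geo, gpar, 1, 0)$volume)
})

test_that("equilibrium states satisfy the virtual-work balance", {
  for (load in list(c(1.0, 0), c(2.0, 0), c(0.5, 4))) {
    st <- inflate(geo, gpar, load[1], load[2])
    expect_lt(st$residual, 1e-8)
  }
  # doubling the quadrature order changes the cavity volume by < 0.1%
  v1 <- inflate(geo, gpar, 2, 0)$volume
  v2 <- inflate(geo, gpar, 2, 0, n_lambda = 8, n_mu = 12)$volume
  expect_lt(abs(v2 - v1) / v1, 1e-3)
})

test_that("identical inputs give bit-identical deformed states", {
  s1 <- inflate(geo, gpar, 1.3, 2.5)
  s2 <- inflate(geo, gpar, 1.3, 2.5)
  expect_identical(s1$q, s2$q)
  expect_identical(s1$points$x, s2$points$x)
})

test_that("the deformation ansatz is pointwise incompressible", {
  st <- inflate(geo, gpar, 1.5, 1.0)
  q <- st$q
  # numeric deformation gradient by finite differences of the map
  # (lambda, mu, theta) -> deformed position, chained with the inverse
  # reference jacobian
  pick <- expand.grid(lambda = c(0.2, 0.7), mu = c(0.3, 0.8), theta = c(0.5, 2))
  h <- 1e-6
  for (i in seq_len(nrow(pick))) {
    pt <- pick[i, ]
    refpos <- function(l, m, t) {
      d <- diastolefit:::point_reference_data(geo, list(lambda = l, mu = m))
      c(sqrt(d$R0sq) * cos(t), sqrt(d$R0sq) * sin(t), d$z0)
    }
    defpos <- function(l, m, t) {
      p <- diastolefit:::deformed_positions(geo, q, l, m, t)
      c(p$x, p$y, p$z)
    }
    Jr <- Jd <- matrix(0, 3, 3)
    for (k in 1:3) {
      d <- c(0, 0, 0); d[k] <- h
      Jr[, k] <- (refpos(pt$lambda + d[1], pt$mu + d[2], pt$theta + d[3]) -
                    refpos(pt$lambda - d[1], pt$mu - d[2], pt$theta - d[3])) / (2 * h)
      Jd[, k] <- (defpos(pt$lambda + d[1], pt$mu + d[2], pt$theta + d[3]) -
                    defpos(pt$lambda - d[1], pt$mu - d[2], pt$theta - d[3])) / (2 * h)
    }
    Fnum <- Jd %*% solve(Jr)
    expect_equal(det(Fnum), 1, tolerance = 1e-7)
    # analytic Green strain agrees with the finite-difference deformation
    # gradient (compared through rotation-invariant moments)
    E_num <- (t(Fnum) %*% Fnum - diag(3)) / 2
    e <- green_strain_fsn(geo, st, pt)
    E_an <- diastolefit:::strain_to_matrix(e)
    expect_equal(sum(diag(E_an)), sum(diag(E_num)), tolerance = 1e-6)
    expect_equal(sum(E_an * E_an), sum(E_num * E_num), tolerance = 1e-6)
  }
})

test_that("green_strain_fsn vanishes for the identity deformation", {
  st <- inflate(geo, gpar, 0, 0)
  e <- green_strain_fsn(geo, st, list(lambda = 0.4, mu = 0.6))
  expect_equal(max(abs(unlist(e))), 0, tolerance = 1e-12)
})

test_that("deflation inverts inflation", {
  # identity at zero load
  y0 <- inflate(geo, gpar, 0, 0)
  x0 <- deflate(y0, gpar, 0, 0)
  expect_equal(c(x0$r_endo, x0$wall, x0$length), c(20, 10, 60), tolerance = 1e-6)

  set.seed(3)
  for (rep in 1:3) {
    gtrue <- lv_geometry(runif(1, 17, 23), runif(1, 8, 12), runif(1, 55, 65))
    cpar <- guccione_params(1, runif(1, 10, 30), runif(1, 5, 15), runif(1, 5, 15))
    load <- c(runif(1, 0.5, 2), runif(1, 0, 4))
    y <- inflate(gtrue, cpar, load[1], load[2])
    xr <- deflate(y, cpar, load[1], load[2])
    y2 <- inflate(xr, cpar, load[1], load[2], points = y$points)
    rms <- sqrt(mean((y2$points$x - y$points$x)^2 +
                       (y2$points$y - y$points$y)^2 +
                       (y2$points$z - y$points$z)^2))
    expect_lt(rms, 1e-6)
    expect_equal(c(xr$r_endo, xr$wall, xr$length),
                 c(gtrue$r_endo, gtrue$wall, gtrue$length), tolerance = 1e-5)
  }
})

test_that("passive deflation from the ED state shrinks the cavity", {
  y <- inflate(geo, gpar, 2.0, 0)
  x0 <- deflate(y, gpar, 2.0, 0)
  expect_lt(reference_cavity_volume(x0), y$volume)
})

test_that("the returned inflation mode is the residual root on a dense grid", {
  st <- inflate(geo, gpar, 1.5, 0)
  pre <- diastolefit:::make_quad(geo)
  q <- st$q
  grid <- seq(q[1] - 5, q[1] + 5, by = 0.5)
  r1 <- vapply(grid, function(d0) {
    diastolefit:::vw_residual(pre, gpar, 1.45, 1.5, 0, c(d0, q[2], q[3]))$r[1]
  }, 0)
  # sign change brackets the returned d0 within one grid spacing
  sgn <- sign(r1)
  flip <- which(diff(sgn) != 0)
  expect_length(flip, 1L)
  expect_lt(abs(grid[flip] - q[1]), 0.5 + 1e-9)
})

test_that("cavity volume matches the closed-form solid of revolution", {
  expect_equal(cavity_volume(geo), reference_cavity_volume(geo),
               tolerance = 1e-3)
  # volume scales with the cube of a uniform scaling
  geo2 <- lv_geometry(2 * 20, 2 * 10, 2 * 60)
  expect_equal(cavity_volume(geo2) / cavity_volume(geo), 8, tolerance = 1e-9)
  st <- inflate(geo, gpar, 1, 0)
  expect_gt(cavity_volume(st), cavity_volume(geo))
  expect_equal(cavity_volume(st), st$volume, tolerance = 1e-9)
})

test_that("the response is isotropic when the helix angle and anisotropy vanish", {
  g0 <- lv_geometry(20, 10, 60, helix_endo = 0, helix_epi = 0)
  perms <- list(c(8, 8, 8), c(8, 8, 8)[c(2, 3, 1)], c(8, 8, 8)[c(3, 1, 2)])
  qs <- lapply(perms, function(p) {
    inflate(g0, guccione_params(1, p[1], p[2], p[3]), 1.2, 0)$q
  })
  expect_equal(qs[[1]], qs[[2]], tolerance = 1e-12)
  expect_equal(qs[[1]], qs[[3]], tolerance = 1e-12)
})

test_that("fit_geometry recovers unloaded-class clouds exactly", {
  mp <- material_points(geo)
  fit <- fit_geometry(mp, template = geo)
  expect_equal(c(fit$r_endo, fit$wall, fit$length), c(20, 10, 60),
               tolerance = 1e-8)
  # and without a template
  fit2 <- fit_geometry(mp)
  expect_equal(c(fit2$r_endo, fit2$wall, fit2$length), c(20, 10, 60),
               tolerance = 1e-6)
})

test_that("boundary conditions must agree with the geometry", {
  expect_error(inflate(geo, gpar, 1, 0, bc = boundary_conditions(5)),
               class = "diastolefit_validation_error")
  st <- inflate(geo, gpar, 1, 0, bc = boundary_conditions(geo$z_base))
  expect_s3_class(st, "deformed_state")
})
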