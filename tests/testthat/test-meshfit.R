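test_that("the value basis is a partition of unity and has Hermite cardinality", {
  p <- function(x) x^2
  m <- hermite_mesh_1d(p, function(x) 2 * x, 3, 0, 3)
  set.seed(1)
  pts <- tracked_points(sample(1:3, 40, TRUE), cbind(runif(40)), mesh = m$mesh)
  H <- shape_matrix(m$mesh, pts)
  # constant field: all value DOFs c, derivative DOFs 0
  U <- numeric(m$mesh$n_dof); U[seq(1, m$mesh$n_dof, 2)] <- 7
  expect_equal(as.vector(H %*% U), rep(7, 40), tolerance = 1e-14)
  # xi = 0 evaluates the left node's value DOF exactly
  p0 <- tracked_points(2L, cbind(0))
  H0 <- shape_matrix(m$mesh, p0)
  Uv <- rnorm(m$mesh$n_dof)
  expect_identical(as.numeric(H0 %*% Uv), Uv[3])  # node 2 value DOF
})

test_that("cubic polynomials are reproduced exactly", {
  p <- function(x) 2 - x + 3 * x^2 - 0.5 * x^3
  dp <- function(x) -1 + 6 * x - 1.5 * x^2
  m <- hermite_mesh_1d(p, dp, 3, 0, 3)
  set.seed(2)
  el <- sample(1:3, 50, TRUE); xi <- runif(50)
  H <- shape_matrix(m$mesh, tracked_points(el, cbind(xi), mesh = m$mesh))
  xglob <- (el - 1 + xi) * m$hx
  expect_equal(as.vector(H %*% m$U), p(xglob), tolerance = 1e-12)
})

test_that("the interpolant is C1 across shared element boundaries", {
  set.seed(3)
  mesh <- hermite_mesh(4, cbind(1:3, 2:4), dim = 1L)
  U <- rnorm(mesh$n_dof)
  evalH <- function(el, xi) {
    as.numeric(shape_matrix(mesh, tracked_points(el, cbind(xi))) %*% U)
  }
  h <- 1e-6
  for (b in 1:2) {  # boundary between elements b and b+1
    expect_equal(evalH(b, 1), evalH(b + 1L, 0), tolerance = 1e-12)
    dleft <- (evalH(b, 1) - evalH(b, 1 - h)) / h
    dright <- (evalH(b + 1L, h) - evalH(b + 1L, 0)) / h
    expect_equal(dleft, dright, tolerance = 1e-4)
  }
})

test_that("propagation solves the least-squares fit exactly when representable", {
  p <- function(x) x; m <- hermite_mesh_1d(p, function(x) 1, 3, 0, 3)
  set.seed(4)
  pts <- tracked_points(sample(1:3, 80, TRUE), cbind(runif(80)), mesh = m$mesh)
  H <- shape_matrix(m$mesh, pts)
  # zero displacement keeps the DOFs
  U_same <- propagate_mesh(cbind(m$U), matrix(0, 80, 1), H)
  expect_equal(as.vector(U_same), m$U, tolerance = 1e-12)
  # displacement generated by a target DOF vector is recovered to 1e-10
  U_t <- rnorm(m$mesh$n_dof)
  Z <- as.matrix(H %*% (U_t - m$U))
  U_fit <- propagate_mesh(cbind(m$U), Z, H)
  expect_equal(as.vector(U_fit), U_t, tolerance = 1e-10)
  # underdetermined layouts raise the ill-posed error
  expect_error(propagate_mesh(cbind(m$U), Z[1:4, , drop = FALSE], H[1:4, ]),
               class = "diastolefit_illposed_fit")
  # Tikhonov regularization rescues the rank-deficient solve (and reports)
  expect_message(
    U_reg <- propagate_mesh(cbind(m$U), Z[1:4, , drop = FALSE], H[1:4, ],
                            lambda = 1e-8),
    "Tikhonov")
  expect_length(as.vector(U_reg), m$mesh$n_dof)
})

test_that("fitting is equivariant under rigid translation", {
  p <- function(x) sin(x); m <- hermite_mesh_1d(p, cos, 4, 0, 2)
  set.seed(5)
  pts <- tracked_points(sample(1:4, 100, TRUE), cbind(runif(100)), mesh = m$mesh)
  H <- shape_matrix(m$mesh, pts)
  Z0 <- matrix(rnorm(100, sd = 0.1), 100, 1)
  U_a <- propagate_mesh(cbind(m$U), Z0, H)
  U_b <- propagate_mesh(cbind(m$U), Z0 + 2.5, H)
  dof_val <- seq(1, m$mesh$n_dof, 2)
  dof_der <- seq(2, m$mesh$n_dof, 2)
  expect_equal(U_b[dof_val, 1] - U_a[dof_val, 1], rep(2.5, length(dof_val)),
               tolerance = 1e-9)
  expect_equal(U_b[dof_der, 1], U_a[dof_der, 1], tolerance = 1e-9)
})

test_that("residuals are orthogonal to the basis and match the hat-matrix law", {
  p <- function(x) x^3; m <- hermite_mesh_1d(p, function(x) 3 * x^2, 2, 0, 1)
  n_pts <- 300L
  set.seed(6)
  pts <- tracked_points(sample(1:2, n_pts, TRUE), cbind(runif(n_pts)),
                        mesh = m$mesh)
  H <- shape_matrix(m$mesh, pts)
  sigma <- 0.1
  sds <- means <- numeric(20)
  for (s in 1:20) {
    noise <- matrix(rnorm(n_pts, 0, sigma), n_pts, 1)
    U_fit <- propagate_mesh(cbind(m$U), noise, H)
    fr <- fit_residual(U_fit, as.matrix(H %*% m$U + noise), H)
    expect_lt(fr$orthogonality, 1e-8)
    sds[s] <- fr$sd
    means[s] <- fr$mean
  }
  expected_sd <- sigma * sqrt(1 - m$mesh$n_dof / n_pts)
  expect_equal(mean(sds), expected_sd, tolerance = 0.2)
  expect_equal(mean(means), 0, tolerance = 0.02)
})

test_that("3-D tensor meshes interpolate trilinear-compatible fields", {
  # single trilinear element: value DOFs at the 8 corners of [0,1]^3,
  # mixed-derivative DOFs consistent with f(x,y,z) = x*y + z
  mesh <- hermite_mesh(8, matrix(1:8, 1), dim = 3L)
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- function(x, y, z) x * y + z
  U <- numeric(mesh$n_dof)
  for (nd in 1:8) {
    base <- (nd - 1L) * 8L
    x <- corners[nd, 1]; y <- corners[nd, 2]; z <- corners[nd, 3]
    U[base + 1L] <- f(x, y, z)       # value
    U[base + 2L] <- y                # d/dx
    U[base + 3L] <- x                # d/dy
    U[base + 4L] <- 1                # dxdy -> d2f/dxdy = 1
    U[base + 5L] <- 1                # d/dz
  }
  set.seed(8)
  xi <- matrix(runif(60), 20, 3)
  H <- shape_matrix(mesh, tracked_points(rep(1L, 20), xi))
  expect_equal(as.vector(H %*% U), f(xi[, 1], xi[, 2], xi[, 3]),
               tolerance = 1e-12)
  # embedding outside the unit cube errors
  expect_error(shape_matrix(mesh, tracked_points(1L, cbind(1.2, 0.5, 0.5))),
               class = "diastolefit_validation_error")
})

test_that("meshes and tracked points round-trip through their file formats", {
  m <- hermite_mesh_1d(function(x) x^2, function(x) 2 * x, 3, 0, 3)
  U <- cbind(m$U, 2 * m$U)
  f <- tempfile(fileext = ".json")
  write_mesh_json(m$mesh, U, f)
  back <- read_mesh_json(f)
  expect_identical(back$mesh$elements, m$mesh$elements)
  expect_equal(unname(back$U), unname(U), tolerance = 1e-15)

  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(element_id = c(1L, 2L), xi1 = c(0.25, 0.75),
                              dx = c(0.1, -0.2), dy = 0, dz = c(1, 2)),
                   csv, row.names = FALSE)
  tp <- read_tracked_points(csv, mesh = m$mesh)
  expect_identical(tp$n, 2L)
  expect_equal(tp$displacement[, "dx"], c(0.1, -0.2))
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_tracked_points(bad), class = "diastolefit_validation_error")
})
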