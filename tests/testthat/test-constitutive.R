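test_that("reformulation maps the Guccione parameters to scale/anisotropy form", {
  r <- reformulate_params(guccione_params(1, 1, 1, 1))
  expect_equal(r$alpha, 3)
  expect_equal(c(r$r2, r$r3, r$r4), rep(1 / 3, 3))

  # healthy-case magnitudes
  r <- reformulate_params(table1_params())
  expect_equal(r$alpha, 42.56)
  expect_equal(r$r3, 0.25070, tolerance = 1e-4)
  expect_equal(r$r4, 0.29981, tolerance = 1e-4)

  expect_error(guccione_params(1, 0, 0, 0), class = "diastolefit_validation_error")
  expect_error(reformulated_params(1, 0, r3 = 0.3, r4 = 0.3),
               class = "diastolefit_validation_error")
})

test_that("reformulate and restore are mutually inverse on random draws", {
  set.seed(42)
  for (i in 1:200) {
    g <- guccione_params(runif(1, 0.1, 5), runif(1, 0, 60), runif(1, 0, 60),
                         runif(1, 1e-3, 60))
    g2 <- restore_params(reformulate_params(g))
    expect_equal(unlist(g2), unlist(g), tolerance = 1e-12)
  }
  r <- reformulated_params(1, 42.56, r3 = 0.25070, r4 = 0.29981)
  g <- restore_params(r)
  expect_equal(c(g$c2, g$c3, g$c4), c(19.13, 10.67, 12.76), tolerance = 1e-3)
  r2 <- reformulate_params(restore_params(r))
  expect_equal(unlist(r2), unlist(r), tolerance = 1e-12)
})

test_that("the strain exponent evaluates the quadratic form", {
  g <- table1_params()
  expect_identical(exponent_q(green_strain(), g), 0)
  expect_equal(exponent_q(green_strain(e_ff = 0.1), g), 0.1913)
  e1 <- green_strain(0.05, -0.03, 0.02, 0.01, -0.02, 0.03)
  e2 <- green_strain(0.10, -0.06, 0.04, 0.02, -0.04, 0.06)
  expect_equal(exponent_q(e2, g), 4 * exponent_q(e1, g))
  # shears enter squared: sign flips leave Q unchanged
  e3 <- green_strain(0.05, -0.03, 0.02, -0.01, 0.02, -0.03)
  expect_equal(exponent_q(e3, g), exponent_q(e1, g))
})

test_that("strain energy is exponential, nonnegative and overflow-guarded", {
  g <- table1_params()
  expect_identical(strain_energy(green_strain(), g), 0)
  expect_equal(strain_energy(green_strain(e_ff = 0.1), g),
               exp(0.1913) - 1, tolerance = 1e-12)
  w1 <- strain_energy(green_strain(e_ff = 0.1), g)
  w2 <- strain_energy(green_strain(e_ff = 0.12), g)
  expect_gt(w2, w1)
  expect_error(strain_energy(green_strain(e_ff = 40, check = FALSE), g),
               class = "diastolefit_unphysical_strain")
})

test_that("passive stress is the tensor derivative of the strain energy", {
  g <- table1_params()
  expect_equal(passive_stress(green_strain(), g), matrix(0, 3, 3))
  S <- passive_stress(green_strain(e_ff = 0.1), g)
  expect_equal(S[1, 1], 2 * 19.13 * 0.1 * exp(0.1913), tolerance = 1e-12)

  # finite-difference oracle: d/dh W(E + h P) = S : P for symmetric P
  set.seed(7)
  h <- 1e-6
  comp <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (rep in 1:10) {
    v <- runif(6, -0.08, 0.08)
    e <- green_strain(v[1], v[2], v[3], v[4], v[5], v[6])
    S <- passive_stress(e, g)
    mk <- function(d) green_strain(v[1] + d[1], v[2] + d[2], v[3] + d[3],
                                   v[4] + d[4], v[5] + d[5], v[6] + d[6],
                                   check = FALSE)
    for (ic in 1:6) {
      d <- numeric(6); d[ic] <- h
      fd <- (strain_energy(mk(d), g) - strain_energy(mk(-d), g)) / (2 * h)
      i <- comp[ic, 1]; j <- comp[ic, 2]
      conj <- if (i == j) S[i, j] else 2 * S[i, j]  # off-diagonals act twice
      expect_equal(fd, conj, tolerance = 1e-6)
    }
  }
})

test_that("active tension follows the length-dependent law", {
  expect_equal(active_tension(active_tension_model(5, 1.45), 0), 5)
  expect_equal(active_tension(active_tension_model(8, 1.45), 0.105), 9.16,
               tolerance = 1e-12)
  expect_equal(active_tension(active_tension_model(0, 1.45), 0.3), 0)
  expect_error(active_tension(active_tension_model(5, 1.45), -0.6),
               class = "diastolefit_unphysical_strain")
})

test_that("total stress decomposes into passive, hydrostatic and active parts", {
  g <- table1_params()
  z <- total_stress(green_strain(), 0, g, active_tension_model(0))
  expect_equal(z$tensor, matrix(0, 3, 3))
  z2 <- total_stress(green_strain(), 2, g, active_tension_model(0))
  expect_equal(z2$tensor, 2 * diag(3))

  set.seed(11)
  for (rep in 1:10) {
    v <- runif(6, -0.08, 0.08)
    e <- green_strain(v[1], v[2], v[3], v[4], v[5], v[6])
    p <- runif(1, -2, 2)
    at <- active_tension_model(runif(1, -5, 10), 1.45)
    S <- total_stress(e, p, g, at)$tensor
    Cinv <- solve(2 * matrix(c(v[1], v[4], v[5], v[4], v[2], v[6],
                               v[5], v[6], v[3]), 3, 3) + diag(3))
    resid <- S - passive_stress(e, g) - p * Cinv
    expect_equal(resid[1, 1], active_tension(at, e$e_ff), tolerance = 1e-10)
    resid[1, 1] <- 0
    expect_equal(max(abs(resid)), 0, tolerance = 1e-10)
  }
  # switching the active tension off reduces the law to the passive model
  e <- green_strain(0.05, -0.02, 0.01, 0.02, 0.01, -0.01)
  s_off <- total_stress(e, 1.5, g, active_tension_model(0))$tensor
  expect_equal(s_off, passive_stress(e, g) + 1.5 * solve(2 * diastolefit:::strain_to_matrix(e) + diag(3)))
})

test_that("parameter sets serialize to flat lists and back", {
  g <- table1_params()
  expect_equal(unlist(params_from_list(params_to_list(g))), unlist(g))
  r <- reformulate_params(g)
  rt <- params_from_list(params_to_list(r))
  expect_equal(unlist(rt), unlist(r))
  expect_error(params_from_list(list(a = 1)), class = "diastolefit_validation_error")
})
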