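test_that("the geometric objective is the masked mean squared distance", {
  set.seed(10)
  a <- matrix(rnorm(60), 20, 3)
  expect_equal(objective(a, a)$j, 0)
  shift <- a; shift[, 1] <- shift[, 1] + 3
  expect_equal(objective(shift, a)$j, 9)
  expect_equal(objective(shift, a)$rmse, 3)
  b <- a + matrix(rnorm(60, sd = 0.5), 20, 3)
  mask <- rep(c(TRUE, FALSE), 10)
  brute <- mean(vapply(which(mask), function(i) sum((a[i, ] - b[i, ])^2), 0))
  expect_equal(objective(a, b, mask)$j, brute, tolerance = 1e-12)
  expect_error(objective(a, b, rep(FALSE, 20)),
               class = "diastolefit_validation_error")
})

test_that("the AT criterion accepts decaying positive profiles only", {
  expect_identical(at_criterion(list(c(5, 3, 1, 0.5))), 1L)
  expect_error(at_criterion(list(c(5, 6, 1, 0.5))),
               class = "diastolefit_criterion_failure")
  expect_identical(at_criterion(list(c(5, 6, 1, 0.5), c(5, 3, 1, 0.5))), 2L)
  # a last value within the quantization tolerance of zero fails positivity
  expect_error(at_criterion(list(c(5, 3, 1, 0.01))),
               class = "diastolefit_criterion_failure")
  # quantization tolerance: a 0.01 kPa uptick does not break monotonicity
  expect_identical(at_criterion(list(c(5, 3, 3.01, 0.5))), 1L)
})

test_that("exponential decay fits recover exact profiles", {
  t <- seq(0, 1, length.out = 6)
  y <- 8 * exp(-t / 0.1)
  fit <- fit_exponential_decay(y, time = t)
  expect_equal(fit$amplitude, 8, tolerance = 1e-6)
  expect_equal(fit$tau, 0.1, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-9)
  # scaling the profile scales the amplitude, not the time constant
  fit2 <- fit_exponential_decay(3 * y, time = t)
  expect_equal(fit2$amplitude, 24, tolerance = 1e-6)
  expect_equal(fit2$tau, fit$tau, tolerance = 1e-9)
  expect_error(fit_exponential_decay(rep(0, 5)), class = "diastolefit_fit_error")
  # zeros are excluded and reported
  fit3 <- fit_exponential_decay(c(y[1:4], 0, -1), time = t)
  expect_equal(fit3$excluded, c(5L, 6L))
})

test_that("active tension estimation recovers known loads", {
  case <- default_case()
  cfg <- sweep_config()
  # with the true constitutive parameters and reference state the sweep
  # recovers the scheduled AT within the refinement step
  est1 <- estimate_at(case$frames, case$truth$geometry, case$truth$params, 1, cfg)
  expect_lt(abs(as.numeric(est1) - 8.00), 0.033 + 1e-9)
  expect_false(attr(est1, "boundary"))
  est2 <- estimate_at(case$frames, case$truth$geometry, case$truth$params, 2, cfg)
  expect_lt(abs(as.numeric(est2) - 2.35), 0.033 + 1e-9)

  # a frame generated fully passively estimates ~0
  pc <- passive_case(pressures = c(0.33, 1.0, 2.0))
  est0 <- estimate_at(pc, attr(pc, "truth")$geometry, table1_params(), 2, cfg)
  expect_lt(abs(as.numeric(est0)), 0.033 + 1e-9)

  # a sweep range that cannot bracket the optimum flags the boundary
  cfg_narrow <- sweep_config(at_range = c(-2, 2))
  expect_warning(
    estb <- estimate_at(case$frames, case$truth$geometry, case$truth$params,
                        1, cfg_narrow),
    "boundary")
  expect_true(attr(estb, "boundary"))
})

test_that("constitutive sweeps recover the generating parameters with the true reference", {
  case <- default_case()
  cfg <- sweep_config()
  C <- estimate_constitutive(case$frames, case$truth$geometry, cfg)
  r <- attr(C, "reformulated")
  truth <- reformulate_params(case$truth$params)
  cell <- alpha_cell_ratio(cfg)
  expect_lt(abs(log(r$alpha / truth$alpha)), log(cell))
  expect_lt(abs(r$r3 - truth$r3), 0.05)
  expect_lt(abs(r$r4 - truth$r4), 0.05)
  # the returned point is the global minimum over every evaluated grid cell
  sweep <- attr(C, "sweep")
  expect_equal(attr(C, "j_min"), min(sweep$j))
})

test_that("the C1-alpha objective valley follows a log-linear coupling law", {
  pc <- passive_case()
  cfg <- sweep_config()
  truth <- reformulate_params(table1_params())
  cp <- analyze_c1_alpha_coupling(pc, attr(pc, "truth")$geometry, cfg,
                                  r34 = c(truth$r3, truth$r4))
  # stiffness scale and exponent scale trade off: positive coupling exponent
  expect_gt(cp$a, 0)
  # the valley passes through the truth cell at the true C1
  i1 <- which.min(abs(cp$valley$c1 - 1))
  expect_lt(abs(log(cp$valley$alpha[i1] / truth$alpha)),
            log(alpha_cell_ratio(cfg)))
  # along-valley objective is far below the off-valley objective
  grid <- cp$grid
  off <- tapply(grid$j, grid$c1, max)
  expect_gt(min(off) / max(cp$valley$j), 100)
})

test_that("a fully passive series yields the no-residual-AT estimate", {
  # minimum diastolic pressure zero: frame 1 coincides with the unloaded state
  pc <- passive_case(pressures = c(0, 1.0, 2.0))
  cfg <- sweep_config()
  est <- suppressWarnings(run_algorithm1(pc, cfg))
  expect_true(est$no_residual_at)
  expect_identical(est$k, 1L)
  expect_equal(est$at_profile$t_z[est$n], 0)
  expect_lt(max(abs(est$at_profile$t_z)), cfg$at_refine_step + 1e-9)
  # broom-style accessors
  expect_s3_class(tidy(est), "tbl_df")
  expect_identical(nrow(glance(est)), 1L)
  expect_equal(glance(est)$alpha, attr(est$params, "reformulated")$alpha)
})
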