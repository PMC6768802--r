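test_that("the in silico configuration validates its schedules", {
  expect_error(insilico_config(pressures = c(1, 2), at = c(1, 0, 0)),
               class = "diastolefit_validation_error")
  expect_error(insilico_config(at = c(8, 2.35, 0.68, 0.21, 0.05, 0.1)),
               class = "diastolefit_validation_error")
  expect_error(insilico_config(pressures = rev(c(0.33, 0.67, 1, 1.33, 1.67, 2))),
               class = "diastolefit_validation_error")
})

test_that("generated series satisfy the frame-series invariants", {
  case <- default_case()
  fr <- case$frames
  expect_s3_class(fr, "frames_data")
  expect_identical(fr$n, 6L)
  expect_equal(fr$pressures[1], min(fr$pressures))
  expect_equal(fr$pressures[6], max(fr$pressures))
  expect_false(is.null(attr(fr, "truth")))
  # end-diastole dilates beyond the first (AT-contracted) frame
  r2 <- function(i) mean(fr$points[[i]]$x^2 + fr$points[[i]]$y^2)
  expect_gt(r2(6), r2(1))
})

test_that("zero loads reproduce the reference configuration", {
  cfg0 <- insilico_config(pressures = c(0, 0), at = c(0, 0))
  fr <- generate_insilico_case(cfg0)
  mp <- material_points(cfg0$geometry)
  expect_equal(fr$points[[1]]$x, mp$x, tolerance = 1e-9)
  expect_equal(fr$points[[2]]$z, mp$z, tolerance = 1e-9)
})

test_that("noise is seeded, reproducible and applied to positions only", {
  c1 <- insilico_config(sigma = 0.3, seed = 7)
  f1 <- generate_insilico_case(c1)
  f2 <- generate_insilico_case(c1)
  expect_identical(f1$points[[1]]$x, f2$points[[1]]$x)
  f3 <- generate_insilico_case(insilico_config(sigma = 0.3, seed = 8))
  expect_false(identical(f1$points[[1]]$x, f3$points[[1]]$x))
  expect_identical(f1$pressures, c1$pressures)       # never perturbed
  expect_identical(attr(f1, "truth")$at, c1$at)      # truth record intact
  # the noiseless generator is deterministic
  f4 <- generate_insilico_case(insilico_config())
  f5 <- generate_insilico_case(insilico_config())
  expect_identical(f4$points[[3]]$x, f5$points[[3]]$x)
})

test_that("the AT profile RMSE matches a brute-force loop", {
  expect_equal(at_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(at_rmse(c(2, 3, 4), c(1, 2, 3)), 1)
  set.seed(9)
  a <- rnorm(5); b <- rnorm(5)
  brute <- sqrt(sum((a - b)^2) / 5)
  expect_equal(at_rmse(a, b), brute, tolerance = 1e-12)
  expect_error(at_rmse(1:3, 1:4), class = "diastolefit_validation_error")
})

test_that("the scenario harness marks reference frames and deflation correctly", {
  # a reduced, faster configuration exercises the bookkeeping
  cfg <- sweep_config(alpha_grid = exp(seq(log(5), log(200), length.out = 12)),
                      r_step = 0.2, at_coarse_step = 2, at_refine_step = 0.2,
                      n_refine = 1L)
  fr <- generate_insilico_case(insilico_config(
    pressures = c(0.33, 1.0, 2.0), at = c(4, 1, 0)))
  rep <- suppressWarnings(run_scenarios(fr, cfg))
  expect_identical(rep$scenario, 1:6)
  expect_identical(rep$deflation, c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(rep$k[1], 1L)
  expect_identical(rep$k[2], 1L)
  expect_true(all(rep$at_rmse >= 0))
  expect_identical(rep$k[5], max(1L, rep$k[4] - 1L))
  expect_identical(rep$k[6], min(fr$n - 1L, rep$k[4] + 1L))
  est <- attr(rep, "estimate_s4")
  expect_s3_class(est, "lv_estimate")
  expect_equal(est$at_profile$t_z[fr$n], 0)
})
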