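# Estimation of constitutive parameters, unloaded reference state and the
# diastolic residual active tension profile from a series of observed
# diastolic frames and cavity pressures, by parameter sweeps.

#' Observed diastolic frame series
#'
#' Container for the per-frame observations the estimator consumes: material
#' point positions (in point correspondence across frames), cavity pressures,
#' an optional free-wall comparison mask and the base-plane boundary data.
#'
#' @param points List of n tibbles with columns `lambda`, `mu`, `theta`,
#'   `x`, `y`, `z` (mm), all with identical material coordinates.
#' @param pressures Numeric vector of n cavity pressures, kPa.  Frame 1 must
#'   be the minimum-pressure frame (zero by clinical convention; generated
#'   cases may have a positive minimum) and frame n the maximum-pressure
#'   (end-diastolic) frame.
#' @param mask Optional logical vector over points restricting the objective
#'   to the free wall; default all points.
#' @param base_z Axial base-plane positions per frame, mm (the boundary
#'   data); a single value is recycled.
#' @param template Optional [lv_geometry()] used as starting template when
#'   fitting reference geometries to frames.
#' @return An object of class `frames_data`.
#' @export
frames_data <- function(points, pressures, mask = NULL, base_z = NULL,
                        template = NULL) {
  n <- length(points)
  if (n < 2L) abort_validation("at least two frames are required")
  if (length(pressures) != n)
    abort_validation("pressures must have one entry per frame")
  if (any(!is.finite(pressures)) || any(pressures < 0))
    abort_validation("pressures must be finite and non-negative")
  if (pressures[1] > min(pressures) + 1e-12)
    abort_validation("frame 1 must be the minimum-pressure frame")
  if (pressures[n] < max(pressures) - 1e-12)
    abort_validation("frame n must be the maximum-pressure (ED) frame")
  n_pts <- vapply(points, nrow, 1L)
  if (length(unique(n_pts)) != 1L)
    abort_validation("all frames must have the same number of points")
  mask <- mask %||% rep(TRUE, n_pts[1])
  if (length(mask) != n_pts[1])
    abort_validation("mask length must match the point count")
  if (!any(mask)) abort_validation("empty free-wall mask")
  if (is.null(base_z)) {
    # base plane: axial position of the mu = 1 edge, from the first frame
    base_z <- rep(max(points[[1]]$z), n)
  }
  if (length(base_z) == 1L) base_z <- rep(base_z, n)
  structure(list(n = n, points = points, pressures = pressures, mask = mask,
                 base_z = base_z, template = template),
            class = "frames_data")
}

#' @export
print.frames_data <- function(x, ...) {
  cat(sprintf(
    "Diastolic frame series: %d frames, %d material points, P = [%s] kPa\n",
    x$n, nrow(x$points[[1]]), paste(format(x$pressures), collapse = ", ")))
  invisible(x)
}

#' Sweep configuration for the estimation algorithm
#'
#' Grids and controls of the parameter-sweep minimization.  `c1` is held
#' fixed during estimation (the stiffness scale and the exponent scale
#' `alpha` are strongly coupled, so one must be pinned; 1 kPa is the
#' literature average).  The exponent scale is swept on a log-spaced grid and
#' the anisotropy fractions on a simplex grid; after the alternating sweep
#' converges on the coarse grids the same sweep is repeated on locally zoomed
#' grids to cut quantization of the estimate.  Active tension is swept
#' coarsely over a physiologic range and then refined locally.
#'
#' @param c1 Fixed stiffness scale, kPa.
#' @param alpha_grid Log-spaced exponent-scale grid (default 32 points in
#'   `[1, 400]`).
#' @param r_step Simplex grid step for the anisotropy fractions (r3, r4).
#' @param at_range Coarse active-tension sweep range, kPa.
#' @param at_coarse_step,at_refine_step Coarse and refinement AT sweep
#'   steps, kPa.
#' @param max_iter Cap on the alternating two-step iterations per grid level.
#' @param n_refine Number of local grid-refinement levels after the coarse
#'   sweep (each zooms the winning cell by `refine_zoom`).
#' @param refine_zoom Grid-step shrink factor per refinement level.
#' @param r34_init Starting anisotropy fractions (r3, r4).
#' @param beta Active-tension length-dependence coefficient.
#' @param n_lambda,n_mu Quadrature orders of the forward solves.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(c1 = 1.0,
                         alpha_grid = exp(seq(log(1), log(400), length.out = 32)),
                         r_step = 0.05,
                         at_range = c(-10, 30),
                         at_coarse_step = 1,
                         at_refine_step = 0.033,
                         max_iter = 10L,
                         n_refine = 3L,
                         refine_zoom = 4,
                         r34_init = c(0.3, 0.3),
                         beta = 1.45,
                         n_lambda = 4, n_mu = 6) {
  if (!length(alpha_grid) || any(alpha_grid <= 0))
    abort_validation("alpha_grid must be nonempty and positive")
  if (at_refine_step >= at_coarse_step)
    abort_validation("the AT refinement step must be smaller than the coarse step")
  structure(list(c1 = c1, alpha_grid = sort(alpha_grid), r_step = r_step,
                 at_range = at_range, at_coarse_step = at_coarse_step,
                 at_refine_step = at_refine_step, max_iter = as.integer(max_iter),
                 n_refine = as.integer(n_refine), refine_zoom = refine_zoom,
                 r34_init = r34_init, beta = beta,
                 n_lambda = n_lambda, n_mu = n_mu),
            class = "sweep_config")
}

#' Geometric objective between simulated and observed point sets
#'
#' Mean squared Euclidean distance over the masked material points
#' (quadrature points) of the simulated and observed configurations, and its
#' root (RMSE).
#'
#' @param sim_points,obs_points Tibbles (or matrices) with columns/cols
#'   `x`, `y`, `z` in point correspondence.
#' @param mask Logical vector selecting the compared (free-wall) points.
#' @return List with `j` (mm^2) and `rmse` (mm).
#' @export
objective <- function(sim_points, obs_points, mask = NULL) {
  sim <- if (is.data.frame(sim_points)) cbind(sim_points$x, sim_points$y, sim_points$z) else as.matrix(sim_points)
  obs <- if (is.data.frame(obs_points)) cbind(obs_points$x, obs_points$y, obs_points$z) else as.matrix(obs_points)
  if (nrow(sim) != nrow(obs))
    abort_validation("simulated and observed point counts differ")
  mask <- mask %||% rep(TRUE, nrow(sim))
  if (!any(mask)) abort_validation("empty free-wall mask")
  d2 <- rowSums((sim[mask, , drop = FALSE] - obs[mask, , drop = FALSE])^2)
  j <- mean(d2)
  list(j = j, rmse = sqrt(j))
}

# --- simulation context: cached quadrature + observation coordinates -------

# Simulation context: cached quadrature and observation coordinates.  With
# `ref_cloud` (an observed frame's point tibble), the reference state of the
# simulations is the observed cloud itself -- the geometry fit provides only
# mode shapes, material frames and quadrature weights, while the reference
# radii/heights at every point come from the observation.  This realizes the
# "reference state := observed frame k" assumption without projecting the
# observed shape onto the idealized geometry class.
make_sim_ctx <- function(x0, frames, cfg, ref_cloud = NULL) {
  pre <- make_quad(x0, cfg$n_lambda, cfg$n_mu)
  pts <- frames$points[[1]]
  ptdata <- NULL
  if (!is.null(ref_cloud)) {
    # override the solver quadrature reference by the theta-mean observed
    # radii/heights at each (lambda, mu) station
    key_q <- paste(signif(pre$lam, 10), signif(pre$mu, 10))
    key_c <- paste(signif(ref_cloud$lambda, 10), signif(ref_cloud$mu, 10))
    idx <- match(key_q, key_c)
    if (anyNA(idx)) {
      warning("reference cloud stations do not match the quadrature grid; using the fitted-class reference")
    } else {
      R2 <- ref_cloud$x^2 + ref_cloud$y^2
      R2m <- tapply(R2, key_c, mean)
      zm <- tapply(ref_cloud$z, key_c, mean)
      pre$R0sq <- as.numeric(R2m[key_q])
      pre$z0 <- as.numeric(zm[key_q])
      pre$u <- (x0$z_base - pre$z0) / pre$L_dom
      pre$psi <- 1 - pre$z0^2 / x0$c_e^2
      ptdata <- point_reference_data(x0, pts, positions = ref_cloud)
    }
  }
  list(pre = pre, x0 = x0,
       lambda = pts$lambda, mu = pts$mu, theta = pts$theta,
       ptdata = ptdata, mask = frames$mask)
}

sim_positions <- function(ctx, gpar, P, t_z, beta, warm = NULL) {
  sol <- solve_equilibrium(ctx$pre, gpar, beta, P, t_z, warm_start = warm)
  pos <- if (is.null(ctx$ptdata)) {
    deformed_positions(ctx$x0, sol$q, ctx$lambda, ctx$mu, ctx$theta)
  } else {
    deformed_positions_data(ctx$x0, sol$q, ctx$ptdata, ctx$theta)
  }
  list(q = sol$q, xyz = cbind(pos$x, pos$y, pos$z))
}

obs_matrix <- function(frames, i) {
  p <- frames$points[[i]]
  cbind(p$x, p$y, p$z)
}

masked_j <- function(xyz, obs, mask) {
  mean(rowSums((xyz[mask, , drop = FALSE] - obs[mask, , drop = FALSE])^2))
}

# --- constitutive parameter estimation (two-step alternating sweeps) -------

#' Estimate constitutive parameters from the end-diastolic frame
#'
#' Two-step alternating parameter sweeps in the reformulated parameter space:
#' the exponent scale `alpha` is swept on its grid with the anisotropy
#' fractions held fixed, then `(r3, r4)` on the simplex grid with `alpha`
#' fixed, iterating until the winning grid cell stops changing; the
#' alternation is then repeated on locally zoomed grids
#' (`cfg$n_refine` levels).  The stiffness scale `c1` is held at its
#' configured value throughout, and the end-diastolic simulation carries zero
#' active tension (the myocardium is assumed fully relaxed at ED).  Exact
#' objective ties prefer smaller `alpha`, then smaller `r3`, then `r4`.
#'
#' @param frames A [frames_data()] series.
#' @param x0 Reference-state geometry used in the sweeps, an
#'   [lv_geometry()].
#' @param cfg A [sweep_config()].
#' @return A [guccione_params()] estimate with attributes `reformulated`
#'   (the equivalent scale/anisotropy view), `sweep` (tibble of every
#'   evaluated grid point: level, alpha, r3, r4, j), `j_min` and `converged`.
#' @export
estimate_constitutive <- function(frames, x0, cfg = sweep_config(),
                                  ref_cloud = NULL) {
  stopifnot(inherits(frames, "frames_data"), inherits(x0, "lv_geometry"))
  ctx <- make_sim_ctx(x0, frames, cfg, ref_cloud = ref_cloud)
  obs <- obs_matrix(frames, frames$n)
  P_n <- frames$pressures[frames$n]
  warm <- new.env(parent = emptyenv()); warm$q <- NULL
  n_fail <- 0L; n_tot <- 0L
  eval_j <- function(alpha, r3, r4) {
    g <- guccione_params(cfg$c1, max(1 - r3 - r4, 0) * alpha, r3 * alpha,
                         r4 * alpha)
    n_tot <<- n_tot + 1L
    res <- tryCatch(sim_positions(ctx, g, P_n, 0, cfg$beta, warm = warm$q),
                    diastolefit_nonconvergence = function(cnd) NULL)
    if (is.null(res)) { n_fail <<- n_fail + 1L; return(Inf) }
    warm$q <- res$q
    masked_j(res$xyz, obs, ctx$mask)
  }
  rows <- list()
  sweep_alpha <- function(grid, r3, r4, level) {
    js <- vapply(grid, eval_j, 0, r3 = r3, r4 = r4)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      level = level, alpha = grid, r3 = r3, r4 = r4, j = js)
    grid[which.min(js)]  # grid ascending: ties prefer smaller alpha
  }
  sweep_r <- function(rgrid, alpha, level) {
    js <- vapply(seq_len(nrow(rgrid)), function(i)
      eval_j(alpha, rgrid$r3[i], rgrid$r4[i]), 0)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      level = level, alpha = alpha, r3 = rgrid$r3, r4 = rgrid$r4, j = js)
    rgrid[which.min(js), ]  # ordered by (r3, r4): ties prefer smaller r3, r4
  }
  simplex_grid <- function(step, center = NULL, span = NULL) {
    if (is.null(center)) {
      v <- seq(0, 1, by = step)
      gr <- expand.grid(r4 = v, r3 = v)[, c("r3", "r4")]
    } else {
      v3 <- center[1] + seq(-span, span, by = step)
      v4 <- center[2] + seq(-span, span, by = step)
      gr <- expand.grid(r4 = v4, r3 = v3)[, c("r3", "r4")]
    }
    gr <- gr[gr$r3 >= -1e-12 & gr$r4 >= -1e-12 & gr$r3 + gr$r4 <= 1 + 1e-12, ]
    gr$r3 <- pmin(pmax(gr$r3, 0), 1); gr$r4 <- pmin(pmax(gr$r4, 0), 1)
    gr <- unique(gr)
    gr <- gr[order(gr$r3, gr$r4), ]
    tibble::as_tibble(gr)
  }
  alternate <- function(alpha_grid, rgrid, alpha, r34, level) {
    for (it in seq_len(cfg$max_iter)) {
      alpha_new <- sweep_alpha(alpha_grid, r34[1], r34[2], level)
      rbest <- sweep_r(rgrid, alpha_new, level)
      r34_new <- c(rbest$r3, rbest$r4)
      if (alpha_new == alpha && all(abs(r34_new - r34) < 1e-15))
        return(list(alpha = alpha_new, r34 = r34_new, converged = TRUE))
      alpha <- alpha_new; r34 <- r34_new
    }
    list(alpha = alpha, r34 = r34, converged = FALSE)
  }
  # Local pattern search: joint sweep on a grid centered on the current
  # winner (log-spaced in alpha, linear in the fractions), re-centered until
  # the winner is the center cell.  `free` masks which of (alpha, r3, r4)
  # move.  Candidate cells are ordered so that exact ties prefer smaller
  # alpha, then smaller r3, then smaller r4.
  psearch <- function(center, dlog, rstep, free = c(TRUE, TRUE, TRUE),
                      level, span = 2L, max_moves = 60L) {
    alpha <- center[1]; r34 <- center[2:3]
    conv_loc <- FALSE
    for (mv in seq_len(max_moves)) {
      agrid <- if (free[1]) exp(log(alpha) + seq(-span, span) * dlog) else alpha
      v3 <- if (free[2]) r34[1] + seq(-span, span) * rstep else r34[1]
      v4 <- if (free[3]) r34[2] + seq(-span, span) * rstep else r34[2]
      rg <- expand.grid(r4 = v4, r3 = v3)[, c("r3", "r4")]
      rg <- rg[rg$r3 >= -1e-12 & rg$r4 >= -1e-12 & rg$r3 + rg$r4 <= 1 + 1e-12, ]
      rg$r3 <- pmin(pmax(rg$r3, 0), 1); rg$r4 <- pmin(pmax(rg$r4, 0), 1)
      rg <- unique(rg)
      cells <- expand.grid(ir = seq_len(nrow(rg)), ia = seq_along(agrid))
      ord <- order(agrid[cells$ia], rg$r3[cells$ir], rg$r4[cells$ir])
      cells <- cells[ord, ]
      js <- vapply(seq_len(nrow(cells)), function(i)
        eval_j(agrid[cells$ia[i]], rg$r3[cells$ir[i]], rg$r4[cells$ir[i]]), 0)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        level = level, alpha = agrid[cells$ia], r3 = rg$r3[cells$ir],
        r4 = rg$r4[cells$ir], j = js)
      best <- which.min(js)
      alpha_new <- agrid[cells$ia[best]]
      r34_new <- c(rg$r3[cells$ir[best]], rg$r4[cells$ir[best]])
      if (abs(log(alpha_new) - log(alpha)) < 1e-15 &&
          all(abs(r34_new - r34) < 1e-15)) { conv_loc <- TRUE; break }
      alpha <- alpha_new; r34 <- r34_new
    }
    list(alpha = alpha, r34 = r34, converged = conv_loc,
         j = min(rows[[length(rows)]]$j))
  }
  dlog0 <- if (length(cfg$alpha_grid) > 1)
    mean(diff(log(cfg$alpha_grid))) else log(2)
  # (alpha, r3) minimization at fixed r4, coarse-to-fine (used by the r4
  # profile sweep below)
  inner_min <- function(alpha, r3, r4, span0 = 2L) {
    dlog <- dlog0; rstep <- cfg$r_step
    res <- psearch(c(alpha, r3, r4), dlog, rstep, free = c(TRUE, TRUE, FALSE),
                   level = 1L, span = span0)
    ok <- res$converged
    for (lev in seq_len(cfg$n_refine + 1L)) {
      dlog <- dlog / cfg$refine_zoom; rstep <- rstep / cfg$refine_zoom
      res <- psearch(c(res$alpha, res$r34[1], r4), dlog, rstep,
                     free = c(TRUE, TRUE, FALSE), level = 1L, span = 1L)
      ok <- ok && res$converged
    }
    list(alpha = res$alpha, r3 = res$r34[1], j = res$j, converged = ok)
  }

  # Stage A -- the two-step alternation over the full coarse grids.
  resA <- alternate(cfg$alpha_grid, simplex_grid(cfg$r_step),
                    cfg$alpha_grid[1], cfg$r34_init, level = 0L)
  conv <- resA$converged
  # Stage B -- profile sweep over r4: the exponent scale and the anisotropy
  # fractions trade off along a narrow curved valley of the objective, which
  # axiswise alternation cannot follow; profiling the objective over r4 with
  # (alpha, r3) re-minimized (warm-started along the profile) resolves it.
  r4_grid <- seq(0, 1, by = cfg$r_step)
  alpha_c <- resA$alpha; r3_c <- resA$r34[1]
  prof_j <- rep(Inf, length(r4_grid))
  prof_sol <- vector("list", length(r4_grid))
  start <- which.min(abs(r4_grid - resA$r34[2]))
  for (dir in list(seq(start, length(r4_grid)), seq(start - 1L, 1L))) {
    if (length(dir) == 0L || dir[1] < 1) next
    a <- alpha_c; r3 <- r3_c
    for (idx in dir) {
      r4 <- r4_grid[idx]
      if (r4 > 1 - 1e-12) break
      r3 <- min(r3, 1 - r4)
      sol <- inner_min(a, r3, r4, span0 = 2L)
      prof_j[idx] <- sol$j
      prof_sol[[idx]] <- sol
      a <- sol$alpha; r3 <- sol$r3
    }
  }
  ibest <- which.min(prof_j)
  res <- list(alpha = prof_sol[[ibest]]$alpha,
              r34 = c(prof_sol[[ibest]]$r3, r4_grid[ibest]))
  # Stage C -- full 3-D local refinement around the profile winner.
  dlog <- dlog0; rstep <- cfg$r_step
  for (lev in seq_len(cfg$n_refine)) {
    dlog <- dlog / cfg$refine_zoom
    rstep <- rstep / cfg$refine_zoom
    resC <- psearch(c(res$alpha, res$r34), dlog, rstep, level = 1L + lev,
                    span = 2L)
    conv <- conv && resC$converged
    res <- resC
  }
  if (n_fail == n_tot)
    abort_nonconvergence("all forward solves failed during the constitutive sweep")
  if (!conv)
    warning("constitutive sweep did not reach grid convergence; returning best-so-far")
  sweep_tbl <- do.call(rbind, rows)
  j_min <- min(sweep_tbl$j)
  ref <- reformulated_params(cfg$c1, res$alpha,
                             r2 = max(1 - res$r34[1] - res$r34[2], 0),
                             r3 = res$r34[1], r4 = res$r34[2])
  out <- restore_params(ref)
  attr(out, "reformulated") <- ref
  attr(out, "sweep") <- sweep_tbl
  attr(out, "j_min") <- j_min
  attr(out, "converged") <- conv
  out
}

# --- active tension estimation ---------------------------------------------

#' Estimate residual active tension at one diastolic frame
#'
#' One-dimensional parameter sweep of the active tension parameter: a coarse
#' regular sweep over the configured range followed by a local refinement
#' with the fine step around the coarse optimum.  Uses the given reference
#' state and constitutive parameters; frame `i` is simulated at its observed
#' pressure.
#'
#' @param frames A [frames_data()] series.
#' @param x0 Reference geometry.
#' @param g Constitutive parameters.
#' @param i Frame index in `[1, n - 1]`.
#' @param cfg A [sweep_config()].
#' @return Estimated active tension, kPa, with attributes `boundary` (TRUE
#'   when the optimum sits at the sweep range boundary), `j` (objective at
#'   the optimum, mm^2) and `rmse` (mm).
#' @export
estimate_at <- function(frames, x0, g, i, cfg = sweep_config(),
                        ref_cloud = NULL) {
  stopifnot(inherits(frames, "frames_data"), inherits(x0, "lv_geometry"),
            inherits(g, "guccione_params"))
  if (i < 1 || i > frames$n - 1)
    abort_validation("frame index must lie in [1, n - 1]")
  ctx <- make_sim_ctx(x0, frames, cfg, ref_cloud = ref_cloud)
  obs <- obs_matrix(frames, i)
  P_i <- frames$pressures[i]
  warm <- new.env(parent = emptyenv()); warm$q <- NULL
  eval_j <- function(tz) {
    res <- tryCatch(sim_positions(ctx, g, P_i, tz, cfg$beta, warm = warm$q),
                    diastolefit_nonconvergence = function(cnd) NULL)
    if (is.null(res)) return(Inf)
    warm$q <- res$q
    masked_j(res$xyz, obs, ctx$mask)
  }
  pick <- function(grid, js) {
    jm <- min(js)
    cand <- which(js == jm)
    cand[which.min(abs(grid[cand]))]  # ties prefer smaller |Tz|
  }
  coarse <- seq(cfg$at_range[1], cfg$at_range[2], by = cfg$at_coarse_step)
  js <- vapply(coarse, eval_j, 0)
  if (all(!is.finite(js)))
    abort_nonconvergence("all forward solves failed during the AT sweep")
  t0 <- coarse[pick(coarse, js)]
  fine <- seq(t0 - cfg$at_coarse_step, t0 + cfg$at_coarse_step,
              by = cfg$at_refine_step)
  fine <- fine[fine >= cfg$at_range[1] & fine <= cfg$at_range[2]]
  warm$q <- NULL
  jf <- vapply(fine, eval_j, 0)
  kbest <- pick(fine, jf)
  est <- fine[kbest]
  # a coarse optimum at the range end means the sweep range did not bracket
  # the optimum: the estimate is untrustworthy
  boundary <- t0 <= cfg$at_range[1] || t0 >= cfg$at_range[2] ||
    est <= cfg$at_range[1] + cfg$at_refine_step / 2 ||
    est >= cfg$at_range[2] - cfg$at_refine_step / 2
  if (boundary)
    warning(sprintf("AT optimum at the sweep range boundary (%g kPa)", est))
  structure(est, boundary = boundary, j = jf[kbest], rmse = sqrt(jf[kbest]))
}

# --- AT criterion ----------------------------------------------------------

at_profile_ok <- function(tz, eps, boundary = NULL) {
  n1 <- length(tz)
  viol <- character(0)
  shortfall <- 0
  for (i in seq_len(n1 - 1L)) for (j in seq((i + 1L), n1)) {
    gap <- tz[i] - (tz[j] - eps)
    if (gap <= 0) {
      viol <- c(viol, sprintf("Tz(%d) = %.3f not above Tz(%d) = %.3f",
                              i, tz[i], j, tz[j]))
      shortfall <- shortfall + (-gap)
      break
    }
  }
  if (!(tz[n1] > eps)) {
    viol <- c(viol, sprintf("Tz(n-1) = %.3f not positive", tz[n1]))
    shortfall <- shortfall + (eps - tz[n1])
  }
  has_boundary <- !is.null(boundary) && any(boundary)
  if (has_boundary) {
    viol <- c(viol, sprintf("AT estimate at the sweep range boundary (frames %s)",
                            paste(which(boundary), collapse = ", ")))
    shortfall <- Inf
  }
  list(ok = length(viol) == 0L, violations = viol, shortfall = shortfall)
}

#' Reference-frame selection by the active tension criterion
#'
#' A physiologically admissible residual AT profile must decay monotonically
#' during diastole and still be positive at the penultimate frame.  Given
#' candidate profiles for reference frames `k = 1 .. n-1`, returns the
#' smallest `k` whose profile satisfies both conditions.  The inequalities
#' are applied with a tolerance of the AT sweep refinement step, since the
#' estimates are quantized to that step.
#'
#' @param profiles List of numeric AT profiles (frames `1 .. n-1`), indexed
#'   by candidate reference frame `k`.
#' @param eps Tolerance, kPa (default the standard refinement step 0.033).
#' @return The chosen `k` (integer).  If no profile qualifies, a
#'   criterion-failure error listing the per-k violations is raised.
#' @export
at_criterion <- function(profiles, eps = 0.033) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  all_viol <- list()
  for (k in seq_along(profiles)) {
    chk <- at_profile_ok(profiles[[k]], eps)
    if (chk$ok) return(k)
    all_viol[[k]] <- chk$violations
  }
  stop_df(paste0(
    "no candidate reference frame satisfies the AT criterion:\n",
    paste(sprintf("  k = %d: %s", seq_along(all_viol),
                  vapply(all_viol, paste, "", collapse = "; ")),
          collapse = "\n")),
    "diastolefit_criterion_failure", violations = all_viol)
}

# Reference-frame selection over evaluated candidates: the first candidate
# satisfying the criterion wins; when none does, a candidate whose only
# defect is a small shortfall (within a few sweep quantization steps, and no
# boundary-clipped estimate) is accepted as the least-violating fallback.
select_reference_frame <- function(cands, eps) {
  for (i in seq_along(cands)) if (cands[[i]]$ok)
    return(list(cand = cands[[i]], relaxed = FALSE))
  short <- vapply(cands, function(cc) cc$shortfall, 0)
  if (any(is.finite(short)) && min(short) <= 5 * eps) {
    i <- which.min(short)
    warning(sprintf(
      "no reference frame satisfies the AT criterion strictly; accepting k = %d with shortfall %.3f kPa",
      cands[[i]]$k, short[i]))
    return(list(cand = cands[[i]], relaxed = TRUE))
  }
  NULL
}

# --- the full estimation algorithm -----------------------------------------

# One candidate-k pass: steps 1-4 (initial reference from frame k,
# constitutive sweep at ED, optional deflation refinement, per-frame AT).
algorithm1_candidate <- function(frames, cfg, k, deflation = TRUE,
                                 C_known = NULL, x0_init_known = NULL) {
  n <- frames$n
  y_k <- frames$points[[k]]
  x0_init <- x0_init_known %||% fit_geometry(y_k, template = frames$template)
  # step 2: constitutive sweep with the reference state taken literally from
  # the observed frame k
  Ck <- C_known %||% estimate_constitutive(frames, x0_init, cfg, ref_cloud = y_k)
  if (deflation) {
    # step 3: refine the reference state by deflating the ED observation
    x0k <- deflate(frames$points[[n]], Ck, frames$pressures[n], 0,
                   beta = cfg$beta, template = x0_init)
    ref_cloud <- NULL
  } else {
    x0k <- x0_init
    ref_cloud <- y_k
  }
  tz <- numeric(n - 1L)
  attrs <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    est <- suppressWarnings(estimate_at(frames, x0k, Ck, i, cfg,
                                        ref_cloud = ref_cloud))
    tz[i] <- as.numeric(est)
    attrs[[i]] <- attributes(est)
  }
  boundary <- vapply(attrs, function(a) isTRUE(a$boundary), TRUE)
  chk <- at_profile_ok(tz, cfg$at_refine_step, boundary = boundary)
  list(k = k, x0_init = x0_init, C = Ck, x0 = x0k, tz = tz,
       ok = chk$ok, violations = chk$violations, shortfall = chk$shortfall,
       boundary = boundary)
}

#' Run the full estimation algorithm
#'
#' Joint estimation of the constitutive parameters, the unloaded reference
#' state and the diastolic residual active tension profile.  For each
#' candidate reference frame `k` (processed lazily in increasing order): the
#' reference state is initialized from observed frame `k`; the constitutive
#' parameters are estimated by sweeps against the end-diastolic frame (with
#' zero ED active tension); the reference state is refined by deflating the
#' ED observation; and the AT at every earlier frame is estimated by 1-D
#' sweeps.  The first `k` whose AT profile is positive and monotonically
#' decaying is accepted.  The ED active tension is zero by construction.
#'
#' A series with no detectable residual AT (all candidate profiles ~0, the
#' healthy fully-relaxed limit) fails the strict positivity clause; in that
#' case `k = 1` is returned flagged `no_residual_at` rather than an error.
#'
#' @param frames A [frames_data()] series.
#' @param cfg A [sweep_config()].
#' @param deflation Include the deflation refinement step (default TRUE).
#' @param k_policy `"criterion"` (default) selects `k` by the AT criterion;
#'   `"fixed"` uses `k_fixed` without testing the criterion.
#' @param k_fixed Candidate reference frame when `k_policy = "fixed"`.
#' @param evaluate_all Evaluate every candidate `k` (audit trail) instead of
#'   stopping at the first acceptance.
#' @return An object of class `lv_estimate`: constitutive estimate (both
#'   parameterizations), refined reference geometry, AT profile (with the ED
#'   entry exactly 0), chosen `k`, per-frame objective values, and the per-k
#'   audit trail.
#' @export
run_algorithm1 <- function(frames, cfg = sweep_config(), deflation = TRUE,
                           k_policy = c("criterion", "fixed"), k_fixed = NULL,
                           evaluate_all = FALSE) {
  k_policy <- match.arg(k_policy)
  n <- frames$n
  cands <- list()
  chosen <- NULL
  ks <- if (k_policy == "fixed") {
    if (is.null(k_fixed) || k_fixed < 1 || k_fixed > n - 1)
      abort_validation("k_fixed must lie in [1, n - 1]")
    k_fixed
  } else seq_len(n - 1L)
  no_residual_at <- FALSE
  criterion_relaxed <- FALSE
  for (k in ks) {
    cand <- algorithm1_candidate(frames, cfg, k, deflation = deflation)
    cands[[length(cands) + 1L]] <- cand
    if (k_policy == "fixed") { chosen <- cand; break }
    if (k == 1L && max(abs(cand$tz)) <= cfg$at_refine_step) {
      # degenerate all-passive limit (healthy, fully relaxed): the frame-1
      # profile is identically ~0, which fails strict positivity but needs
      # no other reference frame; accept k = 1 with a flag
      chosen <- cand
      no_residual_at <- TRUE
      if (!evaluate_all) break
    }
    if (cand$ok && is.null(chosen)) {
      chosen <- cand
      if (!evaluate_all) break
    }
  }
  if (is.null(chosen) && k_policy == "criterion") {
    {
      sel <- select_reference_frame(cands, cfg$at_refine_step)
      if (!is.null(sel)) {
        chosen <- sel$cand
        criterion_relaxed <- sel$relaxed
      } else {
        stop_df(paste0(
          "no candidate reference frame satisfies the AT criterion:\n",
          paste(sprintf("  k = %d: %s", vapply(cands, function(cc) cc$k, 1L),
                        vapply(cands, function(cc) paste(cc$violations, collapse = "; "), "")),
                collapse = "\n")),
          "diastolefit_criterion_failure",
          audit = cands)
      }
    }
  }
  # per-frame objective at the accepted estimate
  ctx <- make_sim_ctx(chosen$x0, frames, cfg)
  tz_full <- c(chosen$tz, 0)
  js <- numeric(n)
  warm <- NULL
  for (i in seq_len(n)) {
    res <- sim_positions(ctx, chosen$C, frames$pressures[i], tz_full[i],
                         cfg$beta, warm = warm)
    warm <- res$q
    js[i] <- masked_j(res$xyz, obs_matrix(frames, i), ctx$mask)
  }
  audit <- tibble::tibble(
    k = vapply(cands, function(cc) cc$k, 1L),
    accepted = vapply(cands, function(cc) cc$ok, TRUE),
    violations = vapply(cands, function(cc)
      paste(cc$violations, collapse = "; "), ""),
    profile = lapply(cands, function(cc) cc$tz)
  )
  structure(list(
    params = chosen$C,
    reformulated = attr(chosen$C, "reformulated"),
    x0 = chosen$x0,
    k = chosen$k,
    at_profile = tibble::tibble(
      frame = seq_len(n),
      pressure = frames$pressures,
      t_z = tz_full,
      j = js,
      rmse = sqrt(js)
    ),
    no_residual_at = no_residual_at,
    criterion_relaxed = criterion_relaxed,
    boundary = chosen$boundary,
    audit = audit,
    config = cfg,
    n = n
  ), class = "lv_estimate")
}

#' @export
print.lv_estimate <- function(x, ...) {
  cat("LV diastolic estimation result\n")
  cat(sprintf("  reference frame k = %d%s\n", x$k,
              if (x$no_residual_at) " (no residual AT detected)" else ""))
  r <- x$reformulated
  cat(sprintf("  constitutive: C1 = %g kPa, alpha = %.4g, r2 = %.4g, r3 = %.4g, r4 = %.4g\n",
              r$c1, r$alpha, r$r2, r$r3, r$r4))
  g <- x$params
  cat(sprintf("                (C2 = %.4g, C3 = %.4g, C4 = %.4g)\n", g$c2, g$c3, g$c4))
  cat(sprintf("  unloaded geometry: r_endo = %.4g mm, wall = %.4g mm, length = %.4g mm\n",
              x$x0$r_endo, x$x0$wall, x$x0$length))
  cat("  AT profile (kPa):", paste(sprintf("%.3f", x$at_profile$t_z), collapse = ", "), "\n")
  invisible(x)
}

# --- AT profile exponential fit --------------------------------------------

#' Exponential fit of an active tension decay profile
#'
#' Least-squares fit of `A * exp(-t / tau)` to the strictly positive profile
#' points via the log-linear normal equations; zero or negative entries are
#' excluded and reported.
#'
#' @param t_z Numeric AT profile, kPa (or an `lv_estimate`, whose profile
#'   over frames `1 .. n-1` is used).
#' @param time Time coordinates of the profile points; defaults to
#'   normalized time `(frame - 1) / (n - 1)`.
#' @return A list of class `exp_decay_fit`: `amplitude` (kPa), `tau` (same
#'   unit as `time`), `residual_rms` (kPa, on the original scale, over the
#'   points used), `n_used` and `excluded` (indices).
#' @export
fit_exponential_decay <- function(t_z, time = NULL) {
  if (inherits(t_z, "lv_estimate"))
    t_z <- t_z$at_profile$t_z[seq_len(t_z$n - 1L)]
  n <- length(t_z)
  if (n < 3L) stop_df("need at least 3 profile points", "diastolefit_fit_error")
  time <- time %||% ((seq_len(n) - 1) / (n - 1))
  pos <- which(t_z > 0)
  if (length(pos) < 3L)
    stop_df("need at least 3 strictly positive profile points for the log-linear fit",
            "diastolefit_fit_error")
  fit <- stats::lm(log(t_z[pos]) ~ time[pos])
  A <- exp(stats::coef(fit)[[1]])
  slope <- stats::coef(fit)[[2]]
  if (slope >= 0) warning("profile does not decay: fitted rate is non-negative")
  tau <- -1 / slope
  pred <- A * exp(-time[pos] / tau)
  structure(list(amplitude = A, tau = tau,
                 residual_rms = sqrt(mean((pred - t_z[pos])^2)),
                 n_used = length(pos), excluded = setdiff(seq_len(n), pos)),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf("Exponential AT decay fit: %.4g kPa * exp(-t / %.4g), RMS %.3g kPa (%d points)\n",
              x$amplitude, x$tau, x$residual_rms, x$n_used))
  invisible(x)
}

# --- identifiability landscape ---------------------------------------------

#' Stiffness-scale coupling analysis in the (C1, alpha) plane
#'
#' Traces the flat valley of the single-frame objective in the
#' (C1, alpha) plane -- for each C1 on a log-spaced grid, the best alpha on
#' the sweep grid -- and fits the log-linear coupling law
#' `C1^a * alpha = b`.  The valley flatness (largest objective along the
#' valley relative to the global minimum) quantifies the non-uniqueness of
#' the pair from a single observed frame.
#'
#' @param frames A [frames_data()] series.
#' @param x0 Reference geometry for the simulations.
#' @param cfg A [sweep_config()]; its `alpha_grid` is swept per C1 value.
#' @param frame Frame compared against (default the ED frame `n`).
#' @param c1_grid Log-spaced C1 grid, kPa (default 9 points in `[0.25, 4]`).
#' @param r34 Anisotropy fractions held fixed during the analysis.
#' @param t_z Active tension used in the simulations (default 0: passive).
#' @return A list of class `coupling_fit`: exponents `a` and `b` of
#'   `C1^a * alpha = b`, the `valley` tibble (c1, alpha, j), `flatness`, and
#'   the full objective `grid`.
#' @export
analyze_c1_alpha_coupling <- function(frames, x0, cfg = sweep_config(),
                                      frame = NULL, c1_grid = NULL,
                                      r34 = c(1 / 3, 1 / 3), t_z = 0) {
  stopifnot(inherits(frames, "frames_data"), inherits(x0, "lv_geometry"))
  frame <- frame %||% frames$n
  c1_grid <- c1_grid %||% exp(seq(log(0.25), log(4), length.out = 9))
  if (length(c1_grid) < 4)
    stop_df("need at least 4 C1 grid columns for the coupling fit",
            "diastolefit_fit_error")
  ctx <- make_sim_ctx(x0, frames, cfg)
  obs <- obs_matrix(frames, frame)
  P <- frames$pressures[frame]
  rows <- vector("list", length(c1_grid))
  warm <- NULL
  for (ic in seq_along(c1_grid)) {
    c1 <- c1_grid[ic]
    js <- numeric(length(cfg$alpha_grid))
    for (ia in seq_along(cfg$alpha_grid)) {
      alpha <- cfg$alpha_grid[ia]
      g <- guccione_params(c1, max(1 - sum(r34), 0) * alpha, r34[1] * alpha,
                           r34[2] * alpha)
      res <- tryCatch(sim_positions(ctx, g, P, t_z, cfg$beta, warm = warm),
                      diastolefit_nonconvergence = function(cnd) NULL)
      js[ia] <- if (is.null(res)) Inf else masked_j(res$xyz, obs, ctx$mask)
      if (!is.null(res)) warm <- res$q
    }
    rows[[ic]] <- tibble::tibble(c1 = c1, alpha = cfg$alpha_grid, j = js)
  }
  grid <- do.call(rbind, rows)
  valley <- do.call(rbind, lapply(rows, function(tb) tb[which.min(tb$j), ]))
  interior <- valley$alpha > min(cfg$alpha_grid) & valley$alpha < max(cfg$alpha_grid)
  if (sum(interior) < 4)
    stop_df("valley shorter than 4 grid columns inside the alpha range",
            "diastolefit_fit_error")
  vfit <- valley[interior, ]
  fit <- stats::lm(log(alpha) ~ log(c1), data = vfit)
  a <- -stats::coef(fit)[[2]]
  b <- exp(stats::coef(fit)[[1]])
  flat <- max(vfit$j) / max(min(vfit$j), .Machine$double.xmin)
  structure(list(a = a, b = b, valley = valley, flatness = flat,
                 grid = grid, frame = frame),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf(
    "C1-alpha coupling: C1^%.3f * alpha = %.4g (frame %d), valley flatness %.3g\n",
    x$a, x$b, x$frame, x$flatness))
  invisible(x)
}
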