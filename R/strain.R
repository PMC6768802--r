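#' Green--Lagrange strain state in the fiber/sheet/normal frame
#'
#' Six independent components of the symmetric Green--Lagrange strain tensor
#' \eqn{E = (F^T F - I)/2} expressed in the local material frame: fiber (f),
#' sheet (s) and sheet-normal (n).
#'
#' @param e_ff,e_ss,e_nn Normal components (dimensionless).
#' @param e_fs,e_fn,e_sn Shear components (full tensor components, not
#'   engineering shears).
#' @param check If `TRUE` (default), verify that `2 E + I` is positive
#'   definite, i.e. that the state corresponds to a physical deformation.
#' @return An object of class `green_strain`.
#' @export
green_strain <- function(e_ff = 0, e_ss = 0, e_nn = 0,
                         e_fs = 0, e_fn = 0, e_sn = 0, check = TRUE) {
  vals <- c(e_ff, e_ss, e_nn, e_fs, e_fn, e_sn)
  if (!all(is.finite(vals)))
    abort_validation("all strain components must be finite")
  e <- structure(list(e_ff = e_ff, e_ss = e_ss, e_nn = e_nn,
                      e_fs = e_fs, e_fn = e_fn, e_sn = e_sn),
                 class = "green_strain")
  if (check) {
    C <- strain_to_C(e)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      abort_unphysical("2E + I is not positive definite: unphysical strain")
  }
  e
}

strain_to_matrix <- function(e) {
  matrix(c(e$e_ff, e$e_fs, e$e_fn,
           e$e_fs, e$e_ss, e$e_sn,
           e$e_fn, e$e_sn, e$e_nn), 3, 3)
}

strain_to_C <- function(e) 2 * strain_to_matrix(e) + diag(3)

# Vectorized core used by both the scalar API and the forward model.
# Each argument is a numeric vector; returns the exponent Q of the law.
q_exponent_vec <- function(c2, c3, c4, e_ff, e_ss, e_nn, e_fs, e_fn, e_sn) {
  c2 * e_ff^2 + c3 * (e_ss^2 + e_nn^2 + 2 * e_sn^2) +
    c4 * (2 * e_fs^2 + 2 * e_fn^2)
}

#' Exponent of the Guccione law
#'
#' Evaluates the quadratic strain form
#' \eqn{Q = C_2 E_{ff}^2 + C_3 (E_{ss}^2 + E_{nn}^2 + 2 E_{sn}^2) +
#'      C_4 (2 E_{fs}^2 + 2 E_{fn}^2)}.
#'
#' @param e A [green_strain()] state.
#' @param g A [guccione_params()] object.
#' @return Dimensionless non-negative scalar.
#' @export
exponent_q <- function(e, g) {
  stopifnot(inherits(e, "green_strain"), inherits(g, "guccione_params"))
  q_exponent_vec(g$c2, g$c3, g$c4,
                 e$e_ff, e$e_ss, e$e_nn, e$e_fs, e$e_fn, e$e_sn)
}

#' Strain-energy density of the Guccione law
#'
#' \eqn{W = C_1 (e^Q - 1)}, in kPa.  Zero at zero strain, strictly positive
#' otherwise.  An exponent large enough to overflow double precision raises an
#' unphysical-strain error rather than returning infinity.
#'
#' @inheritParams exponent_q
#' @return Strain energy density, kPa.
#' @export
strain_energy <- function(e, g) {
  q <- exponent_q(e, g)
  if (q > 700)
    abort_unphysical(sprintf("strain energy overflow: exponent Q = %g", q))
  g$c1 * (exp(q) - 1)
}

#' Passive (deviatoric) second Piola--Kirchhoff stress
#'
#' Closed-form derivative of the strain energy with respect to the Green
#' strain tensor, e.g. the fiber-fiber component is
#' \eqn{2 C_1 C_2 E_{ff} e^Q}.  Off-diagonal entries are full tensor
#' components: the derivative is taken treating E as a symmetric tensor, so
#' e.g. \eqn{S_{fs} = 2 C_1 C_4 E_{fs} e^Q} and the work conjugacy
#' \eqn{S : \delta E = C_1 e^Q \delta Q} holds with off-diagonal terms
#' counted twice.
#'
#' @inheritParams exponent_q
#' @return A symmetric 3x3 matrix (kPa) in the f/s/n frame, with rows/cols
#'   ordered (f, s, n).
#' @export
passive_stress <- function(e, g) {
  stopifnot(inherits(e, "green_strain"), inherits(g, "guccione_params"))
  q <- exponent_q(e, g)
  if (q > 700)
    abort_unphysical(sprintf("stress overflow: exponent Q = %g", q))
  eq <- exp(q)
  k <- 2 * g$c1 * eq
  matrix(c(k * g$c2 * e$e_ff, k * g$c4 * e$e_fs, k * g$c4 * e$e_fn,
           k * g$c4 * e$e_fs, k * g$c3 * e$e_ss, k * g$c3 * e$e_sn,
           k * g$c4 * e$e_fn, k * g$c3 * e$e_sn, k * g$c3 * e$e_nn), 3, 3)
}

#' Length-dependent active tension
#'
#' \eqn{T_a = T_z (1 + \beta (\sqrt{2 E_{ff} + 1} - 1))} where
#' \eqn{\sqrt{2 E_{ff} + 1}} is the fiber extension ratio.
#'
#' @param at An [active_tension_model()].
#' @param e_ff Fiber-direction Green strain (dimensionless); requires
#'   `2 * e_ff + 1 > 0`.
#' @return Active tension, kPa.
#' @export
active_tension <- function(at, e_ff) {
  stopifnot(inherits(at, "active_tension_model"))
  lam2 <- 2 * e_ff + 1
  if (any(lam2 <= 0))
    abort_unphysical("2*e_ff + 1 <= 0: fiber extension ratio undefined")
  at$t_z * (1 + at$beta * (sqrt(lam2) - 1))
}

#' Total second Piola--Kirchhoff stress
#'
#' Sum of the passive (deviatoric) stress, the hydrostatic part
#' \eqn{p C^{-1}} from tissue incompressibility, and the active stress
#' \eqn{T_a f \otimes f} occupying only the fiber-fiber slot of the f/s/n
#' frame.
#'
#' @inheritParams exponent_q
#' @param p Hydrostatic pressure multiplier, kPa.
#' @param at An [active_tension_model()].
#' @return A list of class `stress_state` with elements `tensor` (symmetric
#'   3x3, kPa, f/s/n frame) and `p`.
#' @export
total_stress <- function(e, p, g, at = active_tension_model(0)) {
  assert_scalar_number(p, "p")
  Cmat <- strain_to_C(e)
  Cinv <- tryCatch(solve(Cmat), error = function(cnd)
    abort_unphysical("C = 2E + I is singular: unphysical strain"))
  S <- passive_stress(e, g) + p * Cinv
  S[1, 1] <- S[1, 1] + active_tension(at, e$e_ff)
  structure(list(tensor = S, p = p), class = "stress_state")
}
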