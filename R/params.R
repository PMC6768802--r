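#' Guccione constitutive parameters
#'
#' Container for the four parameters of the transversely isotropic Fung-type
#' exponential strain-energy law for passive myocardium,
#' \eqn{W = C_1 (e^Q - 1)} with
#' \eqn{Q = C_2 E_{ff}^2 + C_3 (E_{ss}^2 + E_{nn}^2 + 2 E_{sn}^2) +
#'      C_4 (2 E_{fs}^2 + 2 E_{fn}^2)},
#' where the strains are Green--Lagrange components in the local
#' fiber/sheet/sheet-normal frame.
#'
#' @param c1 Stiffness scale, kPa. Must be positive.
#' @param c2,c3,c4 Dimensionless exponent coefficients, non-negative with
#'   `c2 + c3 + c4 > 0`.
#' @return An object of class `guccione_params`.
#' @seealso [reformulate_params()], [restore_params()]
#' @examples
#' guccione_params(1, 19.13, 10.67, 12.76)
#' @export
guccione_params <- function(c1, c2, c3, c4) {
  assert_scalar_number(c1, "c1", positive = TRUE)
  assert_scalar_number(c2, "c2", nonneg = TRUE)
  assert_scalar_number(c3, "c3", nonneg = TRUE)
  assert_scalar_number(c4, "c4", nonneg = TRUE)
  if (c2 + c3 + c4 <= 0)
    abort_validation("degenerate parameters: c2 + c3 + c4 must be > 0")
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4),
            class = "guccione_params")
}

#' @export
print.guccione_params <- function(x, ...) {
  cat(sprintf("Guccione parameters: C1 = %g kPa, C2 = %g, C3 = %g, C4 = %g\n",
              x$c1, x$c2, x$c3, x$c4))
  invisible(x)
}

#' Reformulated (scale/anisotropy) constitutive parameters
#'
#' Equivalent parameterization of the Guccione law separating a homogeneous
#' exponent scale \eqn{\alpha = C_2 + C_3 + C_4} from anisotropy fractions
#' \eqn{r_i = C_i / \alpha} with \eqn{r_2 + r_3 + r_4 = 1}.  The scale
#' \eqn{\alpha} (together with \eqn{C_1}) carries the bulk stiffness while the
#' fractions carry the relative stiffness of the material directions, which
#' makes the \eqn{C_1}--\eqn{\alpha} coupling of the original law explicit.
#'
#' @param c1 Stiffness scale, kPa.
#' @param alpha Dimensionless exponent scale, positive.
#' @param r2,r3,r4 Anisotropy fractions, non-negative, summing to 1 within
#'   1e-12. `r2` may be omitted, in which case it is `1 - r3 - r4`.
#' @return An object of class `reformulated_params`.
#' @export
reformulated_params <- function(c1, alpha, r2 = NULL, r3, r4) {
  assert_scalar_number(c1, "c1", positive = TRUE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    abort_validation("degenerate parameters: alpha must be > 0")
  assert_scalar_number(r3, "r3", nonneg = TRUE)
  assert_scalar_number(r4, "r4", nonneg = TRUE)
  r2 <- r2 %||% (1 - r3 - r4)
  assert_scalar_number(r2, "r2", nonneg = TRUE)
  if (abs(r2 + r3 + r4 - 1) >= 1e-12)
    abort_validation("anisotropy fractions r2 + r3 + r4 must equal 1")
  structure(list(c1 = c1, alpha = alpha, r2 = r2, r3 = r3, r4 = r4),
            class = "reformulated_params")
}

#' @export
print.reformulated_params <- function(x, ...) {
  cat(sprintf(
    "Reformulated parameters: C1 = %g kPa, alpha = %g, r2 = %g, r3 = %g, r4 = %g\n",
    x$c1, x$alpha, x$r2, x$r3, x$r4))
  invisible(x)
}

#' Map Guccione parameters to the scale/anisotropy form
#'
#' @param g A [guccione_params()] object.
#' @return A [reformulated_params()] object with `alpha = c2 + c3 + c4` and
#'   `ri = ci / alpha`; `c1` is unchanged.
#' @examples
#' reformulate_params(guccione_params(1, 1, 1, 1))
#' @export
reformulate_params <- function(g) {
  stopifnot(inherits(g, "guccione_params"))
  alpha <- g$c2 + g$c3 + g$c4
  if (alpha <= 0)
    abort_validation("degenerate parameters: alpha = c2 + c3 + c4 is zero")
  r2 <- g$c2 / alpha
  r3 <- g$c3 / alpha
  r4 <- g$c4 / alpha
  # guard rounding so that the fractions sum to 1 exactly
  reformulated_params(g$c1, alpha, r2 = 1 - r3 - r4, r3 = r3, r4 = r4)
}

#' Map scale/anisotropy parameters back to the Guccione form
#'
#' Inverse of [reformulate_params()]: `ci = ri * alpha`.
#'
#' @param r A [reformulated_params()] object.
#' @return A [guccione_params()] object.
#' @export
restore_params <- function(r) {
  stopifnot(inherits(r, "reformulated_params"))
  guccione_params(r$c1, r$r2 * r$alpha, r$r3 * r$alpha, r$r4 * r$alpha)
}

#' Active tension model
#'
#' Length-dependent residual active tension along the fiber direction,
#' \eqn{T_a = T_z (1 + \beta (\sqrt{2 E_{ff} + 1} - 1))}.  `t_z` is the
#' combined reference-tension-times-activation parameter (the reference
#' tension and the activation level are never represented separately); `beta`
#' is the linear length-dependence coefficient on the fiber extension ratio.
#'
#' @param t_z Active tension parameter, kPa.  May be negative (the estimator
#'   sweep range extends below zero); a negative value is a fiber-direction
#'   pushing stress and is flagged by the estimator.
#' @param beta Dimensionless length-dependence coefficient, non-negative.
#'   Default 1.45.
#' @return An object of class `active_tension_model`.
#' @export
active_tension_model <- function(t_z, beta = 1.45) {
  assert_scalar_number(t_z, "t_z")
  assert_scalar_number(beta, "beta", nonneg = TRUE)
  structure(list(t_z = t_z, beta = beta), class = "active_tension_model")
}

#' Serialize a parameter set to a flat list
#'
#' Parameter sets round-trip through flat named lists (YAML/JSON-friendly)
#' with keys `c1, c2, c3, c4` or `c1, alpha, r2, r3, r4`.
#'
#' @param x A `guccione_params` or `reformulated_params` object.
#' @return A named list of plain numbers.
#' @export
params_to_list <- function(x) {
  if (inherits(x, "guccione_params"))
    list(c1 = x$c1, c2 = x$c2, c3 = x$c3, c4 = x$c4)
  else if (inherits(x, "reformulated_params"))
    list(c1 = x$c1, alpha = x$alpha, r2 = x$r2, r3 = x$r3, r4 = x$r4)
  else abort_validation("not a parameter object")
}

#' Deserialize a parameter set from a flat list
#'
#' @param x A named list with keys `c1, c2, c3, c4` (Guccione form) or
#'   `c1, alpha, r3, r4` (+ optional `r2`, reformulated form).
#' @return The corresponding parameter object.
#' @export
params_from_list <- function(x) {
  nm <- names(x)
  if (all(c("c1", "c2", "c3", "c4") %in% nm))
    guccione_params(x$c1, x$c2, x$c3, x$c4)
  else if (all(c("c1", "alpha", "r3", "r4") %in% nm))
    reformulated_params(x$c1, x$alpha, r2 = x$r2 %||% NULL, r3 = x$r3, r4 = x$r4)
  else abort_validation("list does not match either parameter layout")
}
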