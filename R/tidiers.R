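# broom-style tidiers for the fitted-result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the active tension profile of an estimation result
#'
#' @param x An `lv_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per diastolic frame: `frame`, `pressure`
#'   (kPa), `t_z` (kPa) and, when available, the per-frame objective `j`
#'   (mm^2) and `rmse` (mm).
#' @export
tidy.lv_estimate <- function(x, ...) {
  x$at_profile
}

#' One-row summary of an estimation result
#'
#' @param x An `lv_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: chosen reference frame `k`, the constitutive
#'   estimate in both parameterizations, the reference cavity volume (ml)
#'   and the ED fit RMSE (mm).
#' @export
glance.lv_estimate <- function(x, ...) {
  g <- x$params; r <- x$reformulated
  tibble::tibble(
    k = x$k, c1 = g$c1, c2 = g$c2, c3 = g$c3, c4 = g$c4,
    alpha = r$alpha, r2 = r$r2, r3 = r$r3, r4 = r$r4,
    cavity_volume = reference_cavity_volume(x$x0),
    ed_rmse = if (!is.null(x$at_profile$rmse)) x$at_profile$rmse[x$n] else NA_real_,
    no_residual_at = x$no_residual_at,
    criterion_relaxed = x$criterion_relaxed %||% FALSE
  )
}

#' @export
tidy.exp_decay_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "tau"),
                 estimate = c(x$amplitude, x$tau))
}

#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, tau = x$tau,
                 residual_rms = x$residual_rms, n_used = x$n_used)
}

#' @export
tidy.coupling_fit <- function(x, ...) {
  x$valley
}

#' @export
glance.coupling_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, flatness = x$flatness, frame = x$frame)
}
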