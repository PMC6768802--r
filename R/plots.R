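# ggplot2 displays for the result classes.

#' Plot an estimated active tension profile
#'
#' Points are the per-frame sweep optima; the line is the exponential decay
#' fit (when at least three positive points exist).
#'
#' @param object An `lv_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lv_estimate <- function(object, ...) {
  prof <- object$at_profile
  n <- object$n
  prof$time <- (prof$frame - 1) / (n - 1)
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$time, y = .data$t_z)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "normalized diastolic time", y = "residual AT (kPa)",
                  title = sprintf("Residual diastolic active tension (k = %d)",
                                  object$k)) +
    ggplot2::theme_minimal()
  fit <- tryCatch(fit_exponential_decay(object), diastolefit_fit_error = function(cnd) NULL)
  if (!is.null(fit)) {
    tt <- seq(0, 1, length.out = 100)
    line <- tibble::tibble(time = tt, t_z = fit$amplitude * exp(-tt / fit$tau))
    p <- p + ggplot2::geom_line(data = line, linetype = 2)
  }
  p
}

#' Plot the six-scenario AT error report
#'
#' Bar chart of the AT RMSE per scenario, annotated with the reference frame
#' and the deflation flag.
#'
#' @param object A `scenario_report` from [run_scenarios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_report <- function(object, ...) {
  df <- tibble::as_tibble(object[, c("scenario", "k", "deflation", "at_rmse")])
  df$label <- sprintf("k=%d%s", df$k, ifelse(df$deflation, "+defl", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$scenario),
                                   y = .data$at_rmse,
                                   fill = .data$deflation)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "scenario", y = "AT RMSE (kPa)",
                  title = "Sensitivity of AT estimation to reference frame and deflation") +
    ggplot2::theme_minimal()
}

#' Plot the objective landscape of the stiffness-scale coupling
#'
#' Log-log heat map of the single-frame objective over the (C1, alpha) grid
#' with the fitted valley overlaid.
#'
#' @param object A `coupling_fit` from [analyze_c1_alpha_coupling()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coupling_fit <- function(object, ...) {
  grid <- object$grid
  grid$logj <- log10(pmax(grid$j, .Machine$double.xmin))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$c1, y = .data$alpha)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$logj)) +
    ggplot2::geom_line(data = object$valley, color = "white") +
    ggplot2::geom_point(data = object$valley, color = "white", size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "C1 (kPa)", y = "alpha",
                  fill = "log10 J",
                  title = sprintf("C1-alpha coupling: C1^%.2f alpha = %.1f",
                                  object$a, object$b)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
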