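# Internal helpers: condition constructors and small numerics.

stop_df <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "diastolefit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_validation <- function(msg, ...) stop_df(msg, "diastolefit_validation_error", ...)
abort_nonconvergence <- function(msg, ...) stop_df(msg, "diastolefit_nonconvergence", ...)
abort_unphysical <- function(msg, ...) stop_df(msg, "diastolefit_unphysical_strain", ...)

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                                 finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_validation(sprintf("`%s` must be a single non-missing number", name))
  if (finite && !is.finite(x))
    abort_validation(sprintf("`%s` must be finite", name))
  if (positive && x <= 0)
    abort_validation(sprintf("`%s` must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    abort_validation(sprintf("`%s` must be >= 0 (got %g)", name, x))
  invisible(x)
}

# Gauss-Legendre nodes/weights on [a, b].
gauss_legendre <- function(n, a = 0, b = 1) {
  if (n == 1L) {
    x <- 0; w <- 2
  } else {
    i <- seq_len(n - 1L)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- beta
    J[cbind(i + 1L, i)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1L, ]^2
    o <- order(x)
    x <- x[o]; w <- w[o]
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
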