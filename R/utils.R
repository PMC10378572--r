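# internal numerical helpers

#' Trapezoidal quadrature
#'
#' @param t abscissae (strictly increasing)
#' @param y ordinates
#' @return scalar integral estimate
#' @keywords internal
#' @noRd
trapz <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-n] + y[-1]) / 2)
}

# per-sample trapezoid weights w such that sum(w * y) == trapz(t, y)
trapz_weights <- function(t) {
  d <- diff(t)
  c(d / 2, 0) + c(0, d / 2)
}

# zero-mean, unit-variance scaling (sd with n-1 denominator)
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate signal: zero variance", call. = FALSE)
  }
  (x - mean(x)) / s
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}

# gradient of F = sum(w * (xhat - ref)^2) with respect to x, where
# xhat = (x - mean(x)) / sd(x) and ref is fixed. Chain rule through the
# mean/sd so that adjoint gradients match finite differences of the
# normalized loss exactly.
normalized_l2_grad <- function(x, ref, w) {
  n <- length(x)
  s <- stats::sd(x)
  xh <- (x - mean(x)) / s
  r <- xh - ref
  (2 / s) * (w * r - mean(w * r) - xh * sum(w * r * xh) / (n - 1))
}
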