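#' Savitzky-Golay filter coefficients
#'
#' Least-squares projection weights for a local polynomial of given degree
#' fitted over a symmetric window. Row `i` of the returned matrix gives the
#' weights that evaluate the fitted polynomial (or its `deriv`-th
#' derivative) at window position `i`; the centre row is the classical
#' convolution kernel.
#'
#' @param window odd window length.
#' @param degree polynomial degree (< window).
#' @param deriv derivative order (0 = smoothing).
#' @return `window x window` weight matrix.
#' @keywords internal
sg_weights <- function(window, degree, deriv = 0L) {
  stopifnot(window %% 2L == 1L, degree < window, deriv <= degree)
  half <- (window - 1L) %/% 2L
  x <- seq.int(-half, half)
  A <- outer(x, 0:degree, `^`)                       # Vandermonde
  # B %*% y = fitted polynomial coefficients; evaluate derivative at each x
  B <- solve(crossprod(A), t(A))
  D <- outer(x, 0:degree, function(xi, k)
    ifelse(k < deriv, 0, xi^pmax(k - deriv, 0) *
             factorial(k) / factorial(pmax(k - deriv, 0))))
  if (deriv > 0L) D[, seq_len(deriv)] <- 0
  D %*% B
}

#' Savitzky-Golay smoothing and differentiation
#'
#' Filters a uniformly sampled series with a local least-squares polynomial.
#' Interior points use the symmetric window; the first and last half-windows
#' are handled by evaluating the polynomial fitted to the truncated
#' (first/last full) window at their positions, so a series sampled from any
#' polynomial of degree `<= degree` is reproduced exactly, derivatives
#' included.
#'
#' @param x numeric series, uniformly sampled.
#' @param window odd window length (default 15).
#' @param degree polynomial degree (default 3).
#' @param deriv derivative order (0 = smoothing, 1 = first derivative).
#' @param dt sample spacing, used to scale derivatives to per-unit-time.
#' @return filtered series, same length as `x`.
#' @examples
#' t <- 0:29
#' y <- 2 + 0.5 * t - 0.01 * t^3
#' all.equal(savitzky_golay(y), y)  # cubics pass through unchanged
#' @export
savitzky_golay <- function(x, window = 15L, degree = 3L, deriv = 0L, dt = 1) {
  n <- length(x)
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("window must be odd")
  if (n < window)
    stop(sprintf("series of length %d is shorter than the window; at least %d points are required",
                 n, window))
  if (any(!is.finite(x))) stop("savitzky_golay: series contains non-finite values")
  W <- sg_weights(window, degree, deriv)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  centre <- W[half + 1L, ]
  # interior: convolution with the centre kernel
  if (n >= window) {
    idx <- seq.int(half + 1L, n - half)
    for (j in seq_len(window)) {
      out[idx] <- out[idx] + centre[j] * x[idx + (j - half - 1L)]
    }
  }
  # edges: evaluate the polynomial fitted to the first/last window
  head_w <- W[seq_len(half), , drop = FALSE] %*% x[seq_len(window)]
  tail_w <- W[seq.int(half + 2L, window), , drop = FALSE] %*%
    x[seq.int(n - window + 1L, n)]
  out[seq_len(half)] <- head_w
  out[seq.int(n - half + 1L, n)] <- tail_w
  out / dt^deriv
}
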