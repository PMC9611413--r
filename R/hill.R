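#' Downward Hill concentration-response function
#'
#' Mean viability under the downward Hill model
#' \deqn{y = y_0 \left(1 - \frac{(x/x_0)^n}{1 + (x/x_0)^n}\right)
#'         = \frac{y_0}{1 + (x/x_0)^n},}
#' where `y0` is the baseline viability, `x0` the concentration at a 50%
#' decrease from baseline (EC50) and `n` the Hill coefficient. The response is
#' strictly decreasing in `x` with range `(0, y0]`; `x = 0` returns `y0` and
#' `x = x0` returns `y0/2`.
#'
#' @param x Concentration(s), same units as `x0` (conventionally µM);
#'   non-negative.
#' @param y0 Baseline viability (positive; 1 corresponds to vehicle-control
#'   normalized data).
#' @param x0 EC50 in µM; positive.
#' @param n Hill coefficient; restricted to `n >= 1` to exclude implausibly
#'   shallow curves.
#' @return Numeric vector of mean viabilities (no residual noise).
#' @seealso [ec10_to_x0()] for the EC10/EC50 relationship,
#'   [hill_inverse()] for the deterministic inversion.
#' @export
#' @examples
#' hill_response(9, y0 = 1, x0 = 9, n = 1)   # half-maximal point: 0.5
#' hill_response(1, y0 = 1, x0 = 9, n = 1)   # EC10 when n = 1, x0 = 9: 0.9
hill_response <- function(x, y0 = 1, x0, n) {
  if (any(!is.finite(x) & !is.infinite(x)) || any(x < 0))
    stop("'x' must be non-negative", call. = FALSE)
  if (any(x0 <= 0)) stop("'x0' must be positive", call. = FALSE)
  if (any(n < 1)) stop("Hill coefficient 'n' must be >= 1", call. = FALSE)
  if (any(y0 <= 0)) stop("'y0' must be positive", call. = FALSE)
  y0 / (1 + (x / x0)^n)
}

#' Convert between EC10 and EC50 of a downward Hill curve
#'
#' For a downward Hill curve with coefficient `n`, the concentration at a 10%
#' decrement from baseline (EC10) and the midpoint `x0` (EC50) are related by
#' \deqn{x_0 = EC_{10} \, (0.9/0.1)^{1/n} = EC_{10} \cdot 9^{1/n}.}
#' `ec10_to_x0()` and `x0_to_ec10()` are exact inverses.
#'
#' @param ec10,x0 Positive concentrations (µM).
#' @param n Hill coefficient, `n >= 1`.
#' @return Concentration in µM.
#' @export
#' @examples
#' ec10_to_x0(1, n = 1)  # 9
#' ec10_to_x0(1, n = 2)  # 3
ec10_to_x0 <- function(ec10, n) {
  if (any(ec10 <= 0)) stop("'ec10' must be positive", call. = FALSE)
  if (any(n < 1)) stop("Hill coefficient 'n' must be >= 1", call. = FALSE)
  ec10 * 9^(1 / n)
}

#' @rdname ec10_to_x0
#' @export
x0_to_ec10 <- function(x0, n) {
  if (any(x0 <= 0)) stop("'x0' must be positive", call. = FALSE)
  if (any(n < 1)) stop("Hill coefficient 'n' must be >= 1", call. = FALSE)
  x0 * 9^(-1 / n)
}

#' Invert a noise-free Hill response
#'
#' Solves \eqn{y = y_0/(1 + (x/x_0)^n)} for `x`. Useful for recovering the
#' concentration (and hence the EC10) from a single noise-free observation at
#' any response strictly between 0 and `y0`.
#'
#' @param y Observed mean viability, `0 < y < y0`.
#' @inheritParams hill_response
#' @return Concentration `x` in µM.
#' @export
hill_inverse <- function(y, y0 = 1, x0, n) {
  if (any(y <= 0) || any(y >= y0))
    stop("'y' must lie strictly between 0 and 'y0'", call. = FALSE)
  if (any(x0 <= 0)) stop("'x0' must be positive", call. = FALSE)
  if (any(n < 1)) stop("Hill coefficient 'n' must be >= 1", call. = FALSE)
  x0 * (y0 / y - 1)^(1 / n)
}
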