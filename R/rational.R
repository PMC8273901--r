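#' Three-parameter rational saturation coefficients
#'
#' Coefficients of the Moebius form \eqn{x \mapsto (a x + b)/(x + c)} used
#' as the oxygen-saturation response: `a` is the asymptote as x grows,
#' `b/c` the value at x = 0, and `c` (> 0, same unit as x) sets the
#' half-saturation scale.  The pole at -c lies outside the physical domain
#' x >= 0.
#'
#' @param a Asymptote value.
#' @param b Numerator offset.
#' @param c Denominator offset, > 0.
#' @return An object of class `rational_coeffs`.
#' @examples
#' g <- rational_coeffs(a = 20, b = 8, c = 1)
#' rational_eval(g, 0)    # b/c = 8
#' rational_eval(g, 1e6)  # ~ a
#' @export
rational_coeffs <- function(a, b, c) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  if (c <= 0) stop("denominator offset c must be > 0", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "rational_coeffs")
}

#' @export
print.rational_coeffs <- function(x, ...) {
  cat(sprintf("<rational_coeffs> (%.6g x + %.6g) / (x + %.6g)\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Evaluate a rational saturation function
#'
#' @param coeffs A [rational_coeffs()] object.
#' @param x Non-negative argument (scalar or vector), same unit as `c`.
#' @return (a x + b)/(x + c), monotone in x with direction given by the
#'   sign of `a c - b`.
#' @export
rational_eval <- function(coeffs, x) {
  stopifnot(inherits(coeffs, "rational_coeffs"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("argument x must be finite and >= 0", call. = FALSE)
  }
  (x * coeffs$a + coeffs$b) / (x + coeffs$c)
}
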