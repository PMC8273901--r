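#' Parameters of the empirical chemical-repair model
#'
#' Container for the four adjustable parameters of the empirical model of
#' chemical repair in competition with oxygen fixation: `K`, the oxygen
#' concentration (percent) at which half of the maximum number of
#' repairable DNA radicals are removed; `M0`, the maximum repair factor
#' (>= 1); and the shape parameters `q` and `r` of the kinematic
#' interpolation M(y).
#'
#' @param K Half-effect oxygen concentration in percent, > 0.
#' @param M0 Maximum repair factor, >= 1 (dimensionless).
#' @param q,r Positive dimensionless shape parameters.
#' @return An object of class `stewart_params`.
#' @export
stewart_params <- function(K, M0, q, r) {
  stopifnot(K > 0, M0 >= 1, q > 0, r > 0)
  structure(list(K = K, M0 = M0, q = q, r = r), class = "stewart_params")
}

#' Repair factor M(y)
#'
#' Interpolates the maximum chemical-repair factor between the high-LET
#' limit (M = 1, no oxygen effect) and the low-LET limit M0 as a function
#' of the kinematic factor \eqn{y = (z_{eff}/\beta)^2}:
#' \deqn{M(y) = M_0 - (M_0 - 1) / (1 + (q/y)^r).}
#' Large y (slow, high-LET particles) drives M to 1; small y (fast
#' particles) drives M toward M0.
#'
#' @param y Kinematic factor, > 0 (scalar or vector).
#' @param params A [stewart_params()] object.
#' @return M(y), in `[1, M0]`.
#' @export
stewart_M <- function(y, params) {
  stopifnot(inherits(params, "stewart_params"))
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("y must be finite and > 0", call. = FALSE)
  }
  params$M0 - (params$M0 - 1) / (1 + (params$q / y)^params$r)
}

#' High-energy limit of the repair factor
#'
#' As E grows, beta tends to 1 and y tends to z_eff^2, so M(y) tends to the
#' finite limit
#' \deqn{M_\infty = \frac{1 + M_0 (q/z_{eff}^2)^r}{1 + (q/z_{eff}^2)^r}.}
#'
#' @param params A [stewart_params()] object.
#' @param z_eff Asymptotic effective charge (the bare charge number for
#'   fully stripped fast ions; 1 for electrons and protons).
#' @return The limiting repair factor.
#' @export
stewart_M_inf <- function(params, z_eff = 1) {
  stopifnot(inherits(params, "stewart_params"))
  t <- (params$q / z_eff^2)^params$r
  (1 + params$M0 * t) / (1 + t)
}

#' Fraction of chemically repaired DNA radicals
#'
#' The fraction of initial DNA radicals removed by chemical repair before
#' oxygen can fix them:
#' \deqn{p_R(y, [O_2]) = 1 - \frac{[O_2] + K}{[O_2] + M(y) K}.}
#' At zero oxygen the full repair capacity 1 - 1/M(y) is realised; with
#' abundant oxygen every radical is fixed first and p_R tends to 0.  In the
#' high-LET limit (beta -> 0, M -> 1) p_R vanishes for every oxygen level.
#'
#' @param O2 Oxygen tension: an [oxygen_tension()] object or percent values.
#' @param y Kinematic factor, > 0.
#' @param params A [stewart_params()] object.
#' @return p_R in `[0, 1 - 1/M0]`; vectorised elementwise over `O2` and `y`.
#' @export
stewart_pR <- function(O2, y, params) {
  x <- .o2_percent(O2)
  M <- stewart_M(y, params)
  1 - (x + params$K) / (x + M * params$K)
}

#' Reduce the chemical-repair model to Moebius form
#'
#' At fixed particle kinematics the unrepaired fraction
#' \eqn{1 - p_R = ([O_2] + K) / ([O_2] + M(y) K)} is a three-parameter
#' rational (Moebius) function of oxygen, \eqn{x \mapsto (a x + b)/(x + c)}
#' with a = 1, b = K and c = M(y) K.  This is the saturation form on which
#' the full damage surface is built.
#'
#' @param params A [stewart_params()] object.
#' @param y Kinematic factor (scalar), > 0.
#' @return A [rational_coeffs()] object.
#' @export
stewart_to_rational <- function(params, y) {
  stopifnot(length(y) == 1L)
  M <- stewart_M(y, params)
  rational_coeffs(a = 1, b = params$K, c = M * params$K)
}
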