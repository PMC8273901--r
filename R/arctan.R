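#' Arctangent LET-transition parameters
#'
#' Parameters of the energy dependence of complex-damage (DSBc) yield for
#' a single oxygen level: `dsb0` is the low-energy (high-LET) asymptote,
#' `dsb_inf` the high-energy (low-LET) asymptote, both in
#' DSB per cell per Gbp per Gy; `E0` (MeV) is the energy at which half of
#' the particles interact in a high-LET fashion, and `Gamma` (MeV) the
#' width of the transition.
#'
#' @param dsb0 Low-energy asymptote, > 0.
#' @param dsb_inf High-energy asymptote, > 0.
#' @param E0 Transition midpoint energy in MeV.
#' @param Gamma Transition width in MeV, > 0.
#' @return An object of class `arctan_params`.
#' @export
arctan_params <- function(dsb0, dsb_inf, E0, Gamma) {
  stopifnot(dsb0 > 0, dsb_inf > 0, Gamma > 0)
  structure(list(dsb0 = dsb0, dsb_inf = dsb_inf, E0 = E0, Gamma = Gamma),
            class = "arctan_params")
}

#' Complex-damage yield versus kinetic energy
#'
#' The single-oxygen-level energy model
#' \deqn{DSB_c(E) = (dsb_0 - dsb_\infty)
#'   \left[\frac{1}{\pi}\arctan\frac{E_0 - E}{\Gamma} + \frac12\right]
#'   + dsb_\infty,}
#' a smooth switch between the high-LET yield at low energy and the
#' low-LET plateau at high energy.  The bracket lies strictly in (0, 1),
#' so the yield stays between the two asymptotes.
#'
#' @param params An [arctan_params()] object.
#' @param E Kinetic energy in MeV (scalar or vector, > 0).
#' @return Yield in DSB per cell per Gbp per Gy.
#' @export
arctan_damage <- function(params, E) {
  stopifnot(inherits(params, "arctan_params"))
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("kinetic energy must be finite and > 0", call. = FALSE)
  }
  s <- atan((params$E0 - E) / params$Gamma) / pi + 0.5
  (params$dsb0 - params$dsb_inf) * s + params$dsb_inf
}
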