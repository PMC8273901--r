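#' Oxygen tension
#'
#' Oxygen concentration handled in a single canonical unit: percent O2,
#' with 100% meaning pure oxygen.  Partial pressures in Torr (mmHg) are
#' accepted on input and converted with 7.6 Torr per percent (760 Torr
#' atmosphere), so 20% corresponds to 152 Torr and 50% to 380 Torr.
#'
#' @param percent Oxygen concentration in percent (scalar or vector, >= 0).
#' @param torr Alternatively, partial pressure in Torr; exactly one of
#'   `percent` / `torr` must be given.
#' @return An object of class `oxygen_tension` with fields `percent` and
#'   `torr`.
#' @examples
#' oxygen_tension(20)$torr          # 152
#' oxygen_tension(torr = 380)$percent  # 50
#' @export
oxygen_tension <- function(percent = NULL, torr = NULL) {
  if (inherits(percent, "oxygen_tension")) return(percent)
  if (is.null(percent) == is.null(torr)) {
    stop("give exactly one of `percent` or `torr`", call. = FALSE)
  }
  if (is.null(percent)) percent <- torr / TORR_PER_PERCENT
  if (any(!is.finite(percent)) || any(percent < 0)) {
    stop("oxygen tension must be finite and >= 0", call. = FALSE)
  }
  structure(list(percent = percent, torr = percent * TORR_PER_PERCENT),
            class = "oxygen_tension")
}

#' @rdname oxygen_tension
#' @format `TORR_PER_PERCENT` is the fixed conversion constant, 7.6 Torr/%.
#' @export
TORR_PER_PERCENT <- 7.6

# accept oxygen_tension objects or bare numerics (interpreted as percent)
.o2_percent <- function(O2) {
  if (inherits(O2, "oxygen_tension")) return(O2$percent)
  if (any(!is.finite(O2)) || any(O2 < 0)) {
    stop("oxygen tension must be finite and >= 0", call. = FALSE)
  }
  O2
}
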