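#' Charged-particle species registry
#'
#' A small registry of the particle species used throughout the package.
#' Each species carries its charge number `z` and rest energy in MeV.
#' Electrons take `z = 1` in the kinematic factor and skip effective-charge
#' screening (screening is an ionic phenomenon).
#'
#' @param name One of `"electron"`, `"proton"`, `"deuteron"`, `"helium"`,
#'   `"lithium"`, `"carbon"`, or a `particle_species` object (returned
#'   unchanged).
#' @return An object of class `particle_species` with fields `name`, `z`
#'   (integer charge number) and `rest_energy` (MeV).
#' @examples
#' particle_species("proton")
#' particle_species("carbon")$z
#' @export
particle_species <- function(name) {
  if (inherits(name, "particle_species")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  reg <- .species_registry()
  if (!name %in% names(reg)) {
    stop("unknown species '", name, "'; known: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

.species_registry <- function() {
  mk <- function(name, z, rest_energy) {
    structure(list(name = name, z = as.integer(z), rest_energy = rest_energy),
              class = "particle_species")
  }
  list(
    electron = mk("electron", 1L, 0.51099895),
    proton   = mk("proton",   1L, 938.27208816),
    deuteron = mk("deuteron", 1L, 1875.61294257),
    helium   = mk("helium",   2L, 3727.3794066),
    lithium  = mk("lithium",  3L, 6533.83),
    carbon   = mk("carbon",   6L, 11174.86)
  )
}

#' @export
print.particle_species <- function(x, ...) {
  cat(sprintf("<particle_species> %s  z = %d  rest energy = %.5f MeV\n",
              x$name, x$z, x$rest_energy))
  invisible(x)
}

#' Relativistic kinematics and the (z_eff / beta)^2 factor
#'
#' Computes the relativistic speed fraction `beta`, the Barkas-screened
#' effective charge `z_eff`, and the kinematic factor
#' \eqn{y = (z_{eff}/\beta)^2} that governs the LET dependence of the
#' chemical-repair fraction.  For ions the effective charge follows the
#' Barkas rule \eqn{z_{eff} = z (1 - e^{-125 \beta z^{-2/3}})}; electrons
#' keep `z_eff = 1`.
#'
#' @param species A species name or `particle_species` object.
#' @param E Kinetic energy in MeV (scalar or vector, all > 0).
#' @return A list of class `kinematic_state` with vector fields
#'   `kinetic_energy`, `beta`, `z_eff` and `y`.
#' @examples
#' ks <- kinematics("proton", 938.27208816)  # Lorentz factor exactly 2
#' ks$beta                                   # sqrt(3)/2
#' @export
kinematics <- function(species, E) {
  sp <- particle_species(species)
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("kinetic energy must be finite and > 0", call. = FALSE)
  }
  gamma <- 1 + E / sp$rest_energy
  beta <- sqrt(1 - 1 / gamma^2)
  z_eff <- if (sp$name == "electron") {
    rep(1, length(beta))
  } else {
    sp$z * (1 - exp(-125 * beta * sp$z^(-2 / 3)))
  }
  structure(
    list(species = sp, kinetic_energy = E, beta = beta, z_eff = z_eff,
         y = (z_eff / beta)^2),
    class = "kinematic_state"
  )
}
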