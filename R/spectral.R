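#' Differential fluence spectra
#'
#' A fluence spectrum carries the differential fluence psi(E) of one
#' particle species on a strictly increasing energy grid, in particles
#' per cm^2 per MeV.  Grid points are point samples of the density at
#' bin-centre energies, not histogram integrals.  A length-1 grid is
#' treated as a monoenergetic beam whose `fluence` value is the total
#' fluence in particles per cm^2.
#'
#' @param species Species name or [particle_species()] object.
#' @param energy_MeV Strictly increasing energies, > 0.
#' @param fluence Non-negative densities (or total fluence if length 1).
#' @return An object of class `fluence_spectrum`.
#' @export
fluence_spectrum <- function(species, energy_MeV, fluence) {
  sp <- particle_species(species)
  stopifnot(length(energy_MeV) == length(fluence), length(energy_MeV) >= 1L)
  if (any(!is.finite(energy_MeV)) || any(energy_MeV <= 0)) {
    stop("energies must be finite and > 0", call. = FALSE)
  }
  if (length(energy_MeV) > 1L && any(diff(energy_MeV) <= 0)) {
    stop("energy grid must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(fluence)) || any(fluence < 0)) {
    stop("fluence densities must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(species = sp, energy_MeV = as.numeric(energy_MeV),
         fluence = as.numeric(fluence),
         monoenergetic = length(energy_MeV) == 1L),
    class = "fluence_spectrum"
  )
}

# Gy per (MeV / g): 1 MeV = 1.602176634e-13 J; 1 g = 1e-3 kg
GY_PER_MEV_G <- 1.602176634e-10

#' Mass stopping-power models
#'
#' Two closures for S/rho(E) in MeV cm^2 / g: a tabulated model with
#' log-log interpolation (PSTAR/ESTAR-style tables), and an analytic model
#' derived from the Bragg-Kleeman range-energy rule R = alpha E^p, namely
#' \eqn{S/\rho(E) = E^{1-p} / (\rho\,\alpha\,p)}.
#'
#' @param species Species name or [particle_species()] object.
#' @param energy_MeV Strictly increasing tabulated energies (> 0).
#' @param S_over_rho Tabulated mass stopping powers, > 0.
#' @return An object of class `stopping_power` with fields `species`,
#'   `fun(E)` and `domain` (MeV).
#' @export
stopping_power_table <- function(species, energy_MeV, S_over_rho) {
  sp <- particle_species(species)
  stopifnot(length(energy_MeV) == length(S_over_rho), length(energy_MeV) >= 2L)
  if (any(diff(energy_MeV) <= 0)) {
    stop("tabulated energy grid must be strictly increasing", call. = FALSE)
  }
  if (any(S_over_rho <= 0)) stop("stopping powers must be > 0", call. = FALSE)
  lE <- log(energy_MeV); lS <- log(S_over_rho)
  structure(
    list(species = sp,
         fun = function(E) exp(approx(lE, lS, xout = log(E))$y),
         domain = range(energy_MeV),
         table = data.frame(energy_MeV = energy_MeV,
                            mass_stopping_power_MeV_cm2_g = S_over_rho)),
    class = "stopping_power"
  )
}

#' @rdname stopping_power_table
#' @param bk A [bragg_kleeman_params()] object.
#' @param rho Material density in g/cm^3 (1 for water).
#' @export
stopping_power_bragg_kleeman <- function(species = "proton",
                                         bk = bragg_kleeman_params(),
                                         rho = 1) {
  sp <- particle_species(species)
  alpha <- bk$alpha; p <- bk$p
  structure(
    list(species = sp,
         fun = function(E) E^(1 - p) / (rho * alpha * p),
         domain = c(0, Inf)),
    class = "stopping_power"
  )
}

.check_spectrum_sp <- function(spectrum, sp) {
  stopifnot(inherits(spectrum, "fluence_spectrum"),
            inherits(sp, "stopping_power"))
  if (spectrum$species$name != sp$species$name) {
    stop("species mismatch: spectrum is ", spectrum$species$name,
         ", stopping power is ", sp$species$name, call. = FALSE)
  }
  E <- spectrum$energy_MeV
  if (min(E) < sp$domain[1] || max(E) > sp$domain[2]) {
    stop("spectrum grid outside the stopping-power domain", call. = FALSE)
  }
}

# refine > 1 subdivides every interval, linearly interpolating psi (and
# any extra integrand factor is re-evaluated exactly on the fine grid)
.refined_grid <- function(E, refine) {
  if (refine <= 1L) return(E)
  out <- unlist(lapply(seq_len(length(E) - 1L), function(i) {
    seq(E[i], E[i + 1L], length.out = refine + 1L)[-(refine + 1L)]
  }))
  c(out, E[length(E)])
}

.trapz <- function(x, y) pracma::trapz(x, y)

#' Dose delivered by a fluence spectrum
#'
#' The dose in a thin voxel equals the fluence-weighted stopping-power
#' integral
#' \deqn{D = k \int \psi(E)\, (S/\rho)(E)\, dE,}
#' with k = 1.602e-10 Gy g / MeV, evaluated by the trapezoidal rule on the
#' caller's grid (no hidden re-gridding).  A monoenergetic spectrum uses
#' the delta-function form k Phi (S/rho)(E*).
#'
#' @param spectrum A [fluence_spectrum()].
#' @param sp A `stopping_power` model of the same species.
#' @param refine Integer subdivision factor for convergence studies;
#'   psi is interpolated linearly onto the refined grid.
#' @return Dose in Gy.
#' @export
dose_integral <- function(spectrum, sp, refine = 1L) {
  .check_spectrum_sp(spectrum, sp)
  if (spectrum$monoenergetic) {
    return(GY_PER_MEV_G * spectrum$fluence * sp$fun(spectrum$energy_MeV))
  }
  E <- .refined_grid(spectrum$energy_MeV, refine)
  psi <- approx(spectrum$energy_MeV, spectrum$fluence, xout = E)$y
  GY_PER_MEV_G * .trapz(E, psi * sp$fun(E))
}

#' Damage delivered by a fluence spectrum
#'
#' The spectral damage integral
#' \deqn{M_d = k \int F_d(E, p)\, \psi(E)\, (S/\rho)(E)\, dE}
#' in DSBc per cell per Gbp; with `per_gy = TRUE` the dose-normalised
#' mean damage M_d / D (per Gy) is returned instead.
#'
#' @inheritParams dose_integral
#' @param model An [fd_model()] of the same species as the spectrum.
#' @param O2 Oxygen tension ([oxygen_tension()] or percent).
#' @param per_gy If `TRUE`, return M_d / D.
#' @return Damage in DSBc per cell per Gbp (or per Gy if `per_gy`).
#' @export
damage_integral <- function(spectrum, sp, model, O2, refine = 1L,
                            per_gy = FALSE) {
  .check_spectrum_sp(spectrum, sp)
  stopifnot(inherits(model, "fd_model"))
  if (model$species$name != spectrum$species$name) {
    stop("species mismatch: model is ", model$species$name,
         ", spectrum is ", spectrum$species$name, call. = FALSE)
  }
  p <- .o2_percent(O2)
  md <- if (spectrum$monoenergetic) {
    E <- spectrum$energy_MeV
    GY_PER_MEV_G * spectrum$fluence * sp$fun(E) * .fd_eval_raw(model, E, p)
  } else {
    E <- .refined_grid(spectrum$energy_MeV, refine)
    psi <- approx(spectrum$energy_MeV, spectrum$fluence, xout = E)$y
    GY_PER_MEV_G * .trapz(E, psi * sp$fun(E) * .fd_eval_raw(model, E, p))
  }
  if (per_gy) md / dose_integral(spectrum, sp, refine = refine) else md
}

#' Spectrum-level oxygen enhancement ratio of damage
#'
#' OER_d for a polyenergetic beam: the ratio of the spectral damage
#' integral at oxygen tension `O2` to the one at `O2_ref` (fully hypoxic
#' by default) on the identical spectrum, so the fluence normalisation
#' cancels.
#'
#' @inheritParams damage_integral
#' @param O2_ref Reference oxygen tension (default 0%).
#' @return The dimensionless OER_d.
#' @export
oer_spectrum <- function(spectrum, sp, model, O2, O2_ref = 0, refine = 1L) {
  num <- damage_integral(spectrum, sp, model, O2, refine = refine)
  den <- damage_integral(spectrum, sp, model, O2_ref, refine = refine)
  if (den == 0) stop("reference damage is zero", call. = FALSE)
  num / den
}

#' Voxelwise damage map under the median-energy approximation
#'
#' For electron (and hence photon) dose distributions the damage response
#' is virtually flat in energy, so the spectral integral collapses to the
#' Hadamard product of the dose grid with the surface evaluated at a fixed
#' median energy:
#' \deqn{M_d = D \circ F_d(P, E_m).}
#' Grids must arrive pre-aligned on a common voxel lattice.
#'
#' @param D Dose array in Gy (any shape).
#' @param P Oxygen array in percent, same shape as `D`.
#' @param E_m Median energy in MeV (scalar).
#' @param model An [fd_model()].
#' @return An array of damages (DSBc per cell per Gbp), same shape as `D`.
#' @export
voxel_damage_map <- function(D, P, E_m, model) {
  stopifnot(inherits(model, "fd_model"), length(E_m) == 1L, E_m > 0)
  if (!identical(dim(D), dim(P)) || length(D) != length(P)) {
    stop("dose and oxygen grids must share the same shape", call. = FALSE)
  }
  if (any(D < 0)) stop("dose must be non-negative", call. = FALSE)
  D * fd_eval(model, E_m, P)
}

#' Read or write a fluence-spectrum CSV
#'
#' Format: a comment line `# species=<name>` followed by a CSV with
#' header `energy_MeV,fluence_per_cm2_MeV`.  The grid must be strictly
#' increasing and densities non-negative; numbers round-trip at 17
#' significant digits.
#'
#' @param path CSV file path.
#' @param spectrum A [fluence_spectrum()] to write.
#' @return The read spectrum, or (for the writer) `path` invisibly.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  cm <- grep("^\\s*#", lines, value = TRUE)
  m <- regmatches(cm, regexpr("species\\s*=\\s*[A-Za-z]+", cm))
  if (!length(m)) {
    stop("spectrum file lacks a '# species=<name>' comment", call. = FALSE)
  }
  species <- sub("species\\s*=\\s*", "", m[[1]])
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("energy_MeV", "fluence_per_cm2_MeV"), names(df))
  if (length(miss)) {
    stop("spectrum CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 1L && any(diff(df$energy_MeV) <= 0)) {
    stop("spectrum energy grid must be strictly increasing", call. = FALSE)
  }
  if (any(df$fluence_per_cm2_MeV < 0)) {
    stop("negative fluence density", call. = FALSE)
  }
  fluence_spectrum(species, df$energy_MeV, df$fluence_per_cm2_MeV)
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "fluence_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# species=", spectrum$species$name), con)
  writeLines("energy_MeV,fluence_per_cm2_MeV", con)
  writeLines(paste(formatC(spectrum$energy_MeV, digits = 17, format = "g"),
                   formatC(spectrum$fluence, digits = 17, format = "g"),
                   sep = ","), con)
  invisible(path)
}

#' @rdname stopping_power_table
#' @param path CSV with columns `energy_MeV,mass_stopping_power_MeV_cm2_g`
#'   and a `# species=<name>` comment line.
#' @export
read_stopping_power <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  cm <- grep("^\\s*#", lines, value = TRUE)
  m <- regmatches(cm, regexpr("species\\s*=\\s*[A-Za-z]+", cm))
  if (!length(m)) {
    stop("stopping-power file lacks a '# species=<name>' comment",
         call. = FALSE)
  }
  species <- sub("species\\s*=\\s*", "", m[[1]])
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("energy_MeV", "mass_stopping_power_MeV_cm2_g"), names(df))
  if (length(miss)) {
    stop("stopping-power CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stopping_power_table(species, df$energy_MeV,
                       df$mass_stopping_power_MeV_cm2_g)
}

#' Write a voxel damage map as flat CSV plus JSON sidecar
#'
#' Rows are `i,j,k,dose_Gy,oxygen_percent,damage`; the sidecar
#' `<path>.json` records the grid shape.
#'
#' @param damage,D,P Arrays of identical shape (damage, dose, oxygen).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_damage_map <- function(damage, D, P, path) {
  dm <- dim(damage)
  if (is.null(dm)) dm <- length(damage)
  idx <- arrayInd(seq_along(damage), .dim = if (length(dm)) dm else length(damage))
  if (ncol(idx) < 3L) {
    idx <- cbind(idx, matrix(1L, nrow(idx), 3L - ncol(idx)))
  }
  df <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                   dose_Gy = as.vector(D), oxygen_percent = as.vector(P),
                   damage = as.vector(damage))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  writeLines(jsonlite::toJSON(list(shape = dm), auto_unbox = FALSE),
             paste0(path, ".json"))
  invisible(path)
}
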