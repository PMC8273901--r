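#' Built-in reference damage surfaces
#'
#' Synthetic twelve-coefficient surfaces with the qualitative structure of
#' microdosimetric Monte Carlo yield tables: a low-LET plateau near
#' 8 DSBc per cell per Gbp per Gy in anoxia, a high-LET maximum near 28,
#' an LET transition around 1 MeV for protons (and around 0.3 keV for
#' electrons), and oxygen saturation with a half-effect at 0.3% O2 --
#' commensurate with the ~0.26% half-effect oxygen concentration of the
#' chemical-repair competition, so that yields at 20% and 50% oxygen are
#' practically indistinguishable.  They are package fixtures for
#' generating test data and demonstrations, not fitted to any external
#' dataset.
#'
#' @param species `"proton"` or `"electron"`.
#' @return An [fd_model()] object.
#' @examples
#' m <- fd_model_preset("proton")
#' fd_eval(m, 100, 20)  # low-LET, atmospheric oxygen
#' @export
fd_model_preset <- function(species = c("proton", "electron")) {
  species <- match.arg(species)
  if (species == "proton") {
    fd_model(
      species = "proton",
      g1 = rational_coeffs(1.2, 0.24, 0.3),   # transition midpoint, MeV
      g2 = rational_coeffs(0.6, 0.12, 0.3),   # transition width, MeV
      g3 = rational_coeffs(20, 2.4, 0.3),     # low-LET plateau
      g4 = rational_coeffs(28, 8.1, 0.3),     # high-LET maximum
      energy_range = c(0.01, 1000),
      oxygen_range = c(0, 100),
      provenance = "synthetic proton-like preset"
    )
  } else {
    fd_model(
      species = "electron",
      g1 = rational_coeffs(4e-4, 6e-5, 0.3),
      g2 = rational_coeffs(3e-4, 6e-5, 0.3),
      g3 = rational_coeffs(24, 2.4, 0.3),
      g4 = rational_coeffs(30, 8.7, 0.3),
      energy_range = c(1e-7, 10),
      oxygen_range = c(0, 100),
      provenance = "synthetic electron-like preset"
    )
  }
}

#' Configuration for the synthetic yield-table generator
#'
#' @param truth The generating [fd_model()].
#' @param energy_grid Energies in MeV; default 40 log-spaced points over
#'   the truth model's energy range.
#' @param oxygen_grid Oxygen tensions in percent; default 8 levels
#'   spanning anoxia to 50% with the saturation knee resolved.
#' @param noise_sigma Standard deviation of additive Gaussian noise, in
#'   yield units (>= 0).
#' @param seed Integer seed; a fixed seed makes the generated table
#'   bit-reproducible.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(truth,
                         energy_grid = NULL,
                         oxygen_grid = c(0, 0.1, 0.5, 1, 2, 5, 20, 50),
                         noise_sigma = 0,
                         seed = 1L) {
  stopifnot(inherits(truth, "fd_model"), noise_sigma >= 0)
  if (is.null(energy_grid)) {
    energy_grid <- 10^seq(log10(truth$energy_range[1]),
                          log10(truth$energy_range[2]), length.out = 40L)
  }
  stopifnot(length(energy_grid) > 0, length(oxygen_grid) > 0)
  structure(
    list(truth = truth, energy_grid = as.numeric(energy_grid),
         oxygen_grid = as.numeric(oxygen_grid),
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# run expr with a private RNG stream; global .Random.seed is untouched
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic damage-yield table
#'
#' Evaluates the truth surface on the configured energy-by-oxygen grid and
#' adds i.i.d. Gaussian noise of standard deviation `noise_sigma`
#' (truncated below at 1e-6 so yields stay positive).  Records carry
#' `sigma = noise_sigma` when noise is present.  Output is deterministic
#' for a fixed seed and ordered by (oxygen, energy).
#'
#' @param cfg A [synth_config()] object.
#' @return A [damage_yield_table()].
#' @export
generate_yield_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  grid <- expand.grid(energy_MeV = cfg$energy_grid,
                      oxygen_percent = cfg$oxygen_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$oxygen_percent, grid$energy_MeV), , drop = FALSE]
  mu <- .fd_eval_raw(cfg$truth, grid$energy_MeV, grid$oxygen_percent)
  y <- if (cfg$noise_sigma > 0) {
    noise <- .with_seed(cfg$seed, rnorm(nrow(grid), 0, cfg$noise_sigma))
    pmax(mu + noise, 1e-6)
  } else {
    mu
  }
  damage_yield_table(cfg$truth$species$name, grid$energy_MeV,
                     grid$oxygen_percent, y,
                     sigma = if (cfg$noise_sigma > 0) cfg$noise_sigma else NULL)
}
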