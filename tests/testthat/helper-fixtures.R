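# shared fixtures, built once per test run

proton_truth <- fd_model_preset("proton")
electron_truth <- fd_model_preset("electron")

noise_free_table <- function(model = proton_truth) {
  generate_yield_table(synth_config(model))
}

# ESTAR-like collision stopping powers for electrons in water (MeV cm^2/g),
# coarse but smooth; only the shape matters for the flatness checks
electron_stopping <- function() {
  stopping_power_table(
    "electron",
    energy_MeV = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10),
    S_over_rho = c(22.56, 11.75, 6.603, 4.115, 2.793, 2.034,
                   1.849, 1.795, 1.867, 1.968)
  )
}

# smooth broad electron spectrum on [0.05, 5] MeV
broad_electron_spectrum <- function() {
  E <- seq(0.05, 5, by = 0.01)
  fluence_spectrum("electron", E, exp(-(E - 1)^2 / (2 * 0.8^2)))
}

coef_vector <- function(model) {
  unlist(lapply(model[c("g1", "g2", "g3", "g4")],
                function(g) c(g$a, g$b, g$c)))
}

# the SOBP scenario is the most expensive fixture; build it lazily, once
.sobp_cache <- new.env(parent = emptyenv())

default_sobp_plan <- function() {
  if (is.null(.sobp_cache$plan)) .sobp_cache$plan <- sobp_plan()
  .sobp_cache$plan
}

default_sobp_profile <- function() {
  if (is.null(.sobp_cache$profile)) {
    .sobp_cache$profile <- depth_oer_profile(
      default_sobp_plan(), proton_truth, O2_levels = c(0, 0.1, 10, 20))
  }
  .sobp_cache$profile
}

# independent midpoint-rule quadrature oracle on an `refine`-times finer
# grid, with psi interpolated linearly (the density-sample convention)
midpoint_oracle <- function(spectrum, sp, integrand_extra = NULL,
                            refine = 100L) {
  E <- spectrum$energy_MeV
  total <- 0
  for (i in seq_len(length(E) - 1L)) {
    edges <- seq(E[i], E[i + 1L], length.out = refine + 1L)
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    psi <- approx(E, spectrum$fluence, xout = mids)$y
    f <- psi * sp$fun(mids)
    if (!is.null(integrand_extra)) f <- f * integrand_extra(mids)
    total <- total + sum(f * diff(edges))
  }
  1.602176634e-10 * total
}
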