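test_that("monoenergetic and null spectra integrate in closed form", {
  sp <- stopping_power_bragg_kleeman("proton")
  delta <- fluence_spectrum("proton", 50, 1e9)
  expect_equal(dose_integral(delta, sp),
               1.602176634e-10 * 1e9 * sp$fun(50), tolerance = 1e-15)

  E <- seq(10, 100, by = 1)
  nothing <- fluence_spectrum("proton", E, rep(0, length(E)))
  expect_identical(dose_integral(nothing, sp), 0)

  m <- proton_truth
  expect_equal(damage_integral(delta, sp, m, 20),
               fd_eval(m, 50, 20) * dose_integral(delta, sp),
               tolerance = 1e-15)
})

test_that("trapezoid integrals agree with a 100x-refined midpoint oracle", {
  sp <- stopping_power_bragg_kleeman("proton")
  E <- seq(5, 150, by = 1)
  spec <- fluence_spectrum("proton", E, 1e8 * exp(-(E - 60)^2 / (2 * 25^2)))

  d <- dose_integral(spec, sp)
  expect_equal(d, midpoint_oracle(spec, sp), tolerance = 1e-3)

  m <- proton_truth
  md <- damage_integral(spec, sp, m, 20)
  oracle <- midpoint_oracle(spec, sp,
                            integrand_extra = function(E) fd_eval(m, E, 20))
  expect_equal(md, oracle, tolerance = 1e-3)

  # the refinement flag converges toward the oracle
  expect_equal(dose_integral(spec, sp, refine = 100L), midpoint_oracle(spec, sp),
               tolerance = 1e-7)
})

test_that("spectral integrals are linear and species-checked", {
  sp <- stopping_power_bragg_kleeman("proton")
  m <- proton_truth
  E1 <- seq(5, 50, by = 0.5)
  E2 <- seq(60, 150, by = 0.5)
  f1 <- 1e8 * exp(-(E1 - 30)^2 / 50)
  f2 <- 5e7 * exp(-(E2 - 100)^2 / 200)
  s1 <- fluence_spectrum("proton", E1, f1)
  s2 <- fluence_spectrum("proton", E2, f2)
  joined <- fluence_spectrum("proton", c(E1, E2), c(f1, f2))

  # additivity over disjoint supports (up to the stitching bin)
  md <- function(s) damage_integral(s, sp, m, 10)
  expect_equal(md(joined), md(s1) + md(s2), tolerance = 1e-2)

  # homogeneity of degree one in fluence
  s3 <- fluence_spectrum("proton", E1, 7.5 * f1)
  expect_equal(md(s3), 7.5 * md(s1), tolerance = 1e-12)

  e_sp <- electron_stopping()
  expect_error(dose_integral(s1, e_sp), "species mismatch")
  expect_error(damage_integral(broad_electron_spectrum(), e_sp, m, 10),
               "species mismatch")
  # grid outside the tabulated domain
  wide <- fluence_spectrum("electron", c(0.001, 0.01, 0.1), c(1, 1, 1))
  expect_error(dose_integral(wide, e_sp), "domain")
})

test_that("spectrum OER cancels fluence normalisation and matches the point value", {
  sp <- stopping_power_bragg_kleeman("proton")
  m <- proton_truth
  E <- seq(0.3, 1.3, by = 0.01)
  spec <- fluence_spectrum("proton", E, exp(-(E - 0.76)^2 / (2 * 0.1^2)))

  expect_identical(oer_spectrum(spec, sp, m, 20, O2_ref = 20), 1)

  scaled <- fluence_spectrum("proton", E, 123.4 * spec$fluence)
  expect_equal(oer_spectrum(scaled, sp, m, 20), oer_spectrum(spec, sp, m, 20),
               tolerance = 1e-14)

  mono <- fluence_spectrum("proton", 0.76, 1e7)
  expect_equal(oer_spectrum(mono, sp, m, 20), oer_point(m, 0.76, 20),
               tolerance = 1e-14)
})

test_that("mixed fields commute with species order", {
  mp <- proton_truth
  me <- electron_truth
  spp <- stopping_power_bragg_kleeman("proton")
  spe <- electron_stopping()
  sproton <- fluence_spectrum("proton", seq(5, 50, 0.5),
                              rep(1e7, length(seq(5, 50, 0.5))))
  selectron <- broad_electron_spectrum()
  a <- damage_integral(sproton, spp, mp, 10) +
    damage_integral(selectron, spe, me, 10)
  b <- damage_integral(selectron, spe, me, 10) +
    damage_integral(sproton, spp, mp, 10)
  expect_identical(a, b)
})

test_that("broad electron spectra are flat: dose-normalised damage matches the median energy", {
  m <- electron_truth
  sp <- electron_stopping()
  spec <- broad_electron_spectrum()
  mdg <- damage_integral(spec, sp, m, 20, per_gy = TRUE)
  # dose-weighted median energy of the spectrum
  w <- spec$fluence * sp$fun(spec$energy_MeV)
  E_med <- spec$energy_MeV[which(cumsum(w) >= sum(w) / 2)[1]]
  expect_lt(abs(mdg - fd_eval(m, E_med, 20)) / mdg, 0.02)
})

test_that("voxel damage maps equal the explicit per-voxel loop bitwise", {
  m <- electron_truth
  set.seed(5)
  D <- array(runif(125, 0, 2), dim = c(5, 5, 5))
  P <- array(runif(125, 0, 50), dim = c(5, 5, 5))
  M <- voxel_damage_map(D, P, 0.1, m)
  oracle <- array(0, dim = dim(D))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    oracle[i, j, k] <- D[i, j, k] * fd_eval(m, 0.1, P[i, j, k])
  }
  expect_identical(M, oracle)

  # uniform grids collapse to a single product
  Du <- array(1.5, dim = c(3, 3, 3))
  Pu <- array(10, dim = c(3, 3, 3))
  expect_equal(unique(as.vector(voxel_damage_map(Du, Pu, 0.1, m))),
               1.5 * fd_eval(m, 0.1, 10))
  # zero dose voxels give zero damage
  Du[2, 2, 2] <- 0
  expect_identical(voxel_damage_map(Du, Pu, 0.1, m)[2, 2, 2], 0)

  expect_error(voxel_damage_map(array(1, c(2, 2, 2)), array(1, c(3, 2, 2)),
                                0.1, m), "shape")
})

test_that("spectrum and stopping-power CSVs round-trip and validate", {
  spec <- fluence_spectrum("proton", c(1, 2.5, exp(1)), c(0.1, 1 / 3, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(spec, path)
  back <- read_spectrum(path)
  expect_identical(back$energy_MeV, spec$energy_MeV)
  expect_identical(back$fluence, spec$fluence)
  expect_identical(back$species$name, "proton")

  # single-row file: the monoenergetic delta path
  mono <- fluence_spectrum("proton", 5, 2e8)
  write_spectrum(mono, path)
  back1 <- read_spectrum(path)
  expect_true(back1$monoenergetic)
  sp <- stopping_power_bragg_kleeman("proton")
  expect_equal(dose_integral(back1, sp),
               1.602176634e-10 * 2e8 * sp$fun(5))

  # unsorted grids and negative densities are rejected
  writeLines(c("# species=proton", "energy_MeV,fluence_per_cm2_MeV",
               "2,1", "1,1"), path)
  expect_error(read_spectrum(path), "strictly increasing")
  writeLines(c("# species=proton", "energy_MeV,fluence_per_cm2_MeV",
               "1,-1"), path)
  expect_error(read_spectrum(path), "negative")
  writeLines(c("energy_MeV,fluence_per_cm2_MeV", "1,1"), path)
  expect_error(read_spectrum(path), "species")

  tab <- electron_stopping()$table
  writeLines(c("# species=electron",
               paste("energy_MeV", "mass_stopping_power_MeV_cm2_g", sep = ","),
               paste(tab[[1]], tab[[2]], sep = ",")), path)
  spt <- read_stopping_power(path)
  expect_equal(spt$fun(0.3), electron_stopping()$fun(0.3))
})

test_that("damage maps write flat CSV plus a shape sidecar", {
  m <- electron_truth
  D <- array(1, dim = c(2, 3, 2))
  P <- array(10, dim = c(2, 3, 2))
  M <- voxel_damage_map(D, P, 0.1, m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_damage_map(M, D, P, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 12)
  expect_equal(sort(unique(df$j)), 1:3)
  expect_equal(df$damage, as.vector(M))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(side$shape, c(2, 3, 2))
  unlink(paste0(path, ".json"))
})
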