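test_that("kinematics reproduces relativistic and classical limits", {
  # kinetic energy equal to the rest energy means Lorentz factor 2
  ks <- kinematics("proton", 938.27208816)
  expect_equal(ks$beta, sqrt(3) / 2, tolerance = 1e-12)

  # non-relativistic protons: beta ~ sqrt(2E/m) to 0.1% relative
  ks1 <- kinematics("proton", 1)
  expect_equal(ks1$beta, sqrt(2 * 1 / 938.27208816), tolerance = 1e-3)

  # ultrarelativistic: beta -> 1 and full Barkas de-screening z_eff -> z
  for (sn in c("proton", "helium", "carbon")) {
    ks <- kinematics(sn, 1e9)
    expect_equal(ks$beta, 1, tolerance = 1e-6)
    expect_equal(ks$z_eff, particle_species(sn)$z, tolerance = 1e-6)
  }

  # electrons skip screening entirely
  expect_equal(kinematics("electron", 0.001)$z_eff, 1)
  expect_error(kinematics("proton", -1), "> 0")
  expect_error(particle_species("muon"), "unknown species")
})

test_that("repair factor M(y) interpolates between 1 and M0", {
  prm <- stewart_params(K = 0.26, M0 = 3, q = 950, r = 0.9)
  # slow particles (huge y): no repair advantage
  expect_equal(stewart_M(1e12, prm), 1, tolerance = 1e-6)
  # the half-way point is exact for any exponent
  for (r in c(0.5, 1, 2.7)) {
    p2 <- stewart_params(K = 0.26, M0 = 3, q = 950, r = r)
    expect_equal(stewart_M(950, p2), (3 + 1) / 2, tolerance = 1e-12)
  }
  # degenerate no-repair model
  p3 <- stewart_params(K = 0.26, M0 = 1, q = 950, r = 0.9)
  expect_equal(stewart_M(c(0.1, 10, 1e6), p3), rep(1, 3))
  expect_error(stewart_M(-1, prm), "> 0")
})

test_that("repaired fraction obeys its closed-form endpoints and limits", {
  prm <- stewart_params(K = 0.26, M0 = 3, q = 950, r = 0.9)
  y <- 100
  M <- stewart_M(y, prm)
  expect_equal(stewart_pR(0, y, prm), 1 - 1 / M, tolerance = 1e-12)
  expect_equal(stewart_pR(1e9, y, prm), 0, tolerance = 1e-6)

  # high-LET limit: beta -> 0 kills the oxygen effect at every tension
  y_slow <- (1 / 1e-6)^2
  expect_lt(max(abs(stewart_pR(c(0, 1, 20, 100), y_slow, prm))), 1e-6)

  # low-LET limit matches the closed-form M_infinity
  beta <- 1 - 1e-9
  y_fast <- (1 / beta)^2
  Minf <- stewart_M_inf(prm, z_eff = 1)
  o2 <- c(0, 0.5, 2, 20)
  expect_equal(stewart_pR(o2, y_fast, prm),
               1 - (o2 + prm$K) / (o2 + Minf * prm$K), tolerance = 1e-8)

  # bounds
  yy <- 10^seq(-2, 8, length.out = 30)
  for (y in yy) {
    pr <- stewart_pR(seq(0, 100, length.out = 20), y, prm)
    expect_true(all(pr >= 0 & pr <= 1 - 1 / prm$M0 + 1e-15))
  }
})

test_that("the chemical-repair model reduces exactly to Moebius form", {
  prm <- stewart_params(K = 0.26, M0 = 3, q = 950, r = 0.9)
  o2 <- seq(0, 100, length.out = 100)
  for (y in 10^seq(-1, 7, length.out = 10)) {
    rc <- stewart_to_rational(prm, y)
    expect_equal(rc$a, 1)
    # intercept consistency: value at zero oxygen is 1/M
    expect_equal(rational_eval(rc, 0), 1 / stewart_M(y, prm),
                 tolerance = 1e-14)
    direct <- 1 - stewart_pR(o2, y, prm)
    expect_lt(max(abs(rational_eval(rc, o2) - direct) / direct), 1e-12)
  }
})

test_that("rational saturation evaluates intercept, asymptote and midpoint", {
  g <- rational_coeffs(a = 20, b = 8, c = 1.5)
  expect_equal(rational_eval(g, 0), 8 / 1.5)
  expect_equal(rational_eval(g, 1e12), 20, tolerance = 1e-9)
  expect_equal(rational_eval(g, 1.5), (20 * 1.5 + 8) / 3)
  expect_error(rational_eval(g, -1), ">= 0")
  expect_error(rational_coeffs(1, 1, 0), "c must be > 0")
})

test_that("arctangent energy model hits its exact special points", {
  prm <- arctan_params(dsb0 = 28, dsb_inf = 8, E0 = 1.1, Gamma = 0.55)
  expect_equal(arctan_damage(prm, 1.1), (28 + 8) / 2, tolerance = 1e-14)
  expect_equal(arctan_damage(prm, 1e9), 8, tolerance = 1e-6)
  narrow <- arctan_params(dsb0 = 28, dsb_inf = 8, E0 = 1.1, Gamma = 1e-9)
  expect_equal(arctan_damage(narrow, 0.5), 28, tolerance = 1e-6)
  # bounded by the two asymptotes
  E <- 10^seq(-3, 4, length.out = 200)
  v <- arctan_damage(prm, E)
  expect_true(all(v > 8 & v < 28))
})

test_that("damage surface reduces to the arctangent model and stays bracketed", {
  # constant-coefficient surface: b_i = a_i * c_i makes every g_i flat
  flat <- fd_model("proton",
                   g1 = rational_coeffs(1.1, 1.1 * 2, 2),
                   g2 = rational_coeffs(0.5, 0.5 * 2, 2),
                   g3 = rational_coeffs(8, 8 * 2, 2),
                   g4 = rational_coeffs(28, 28 * 2, 2))
  prm <- arctan_params(dsb0 = 28, dsb_inf = 8, E0 = 1.1, Gamma = 0.5)
  E <- 10^seq(-2, 3, length.out = 50)
  for (p in c(0, 1, 20, 100)) {
    expect_equal(fd_eval(flat, E, p), arctan_damage(prm, E),
                 tolerance = 1e-12)
  }

  # bracket: F_d always between the two branches g3, |g4-g3|+g3
  m <- proton_truth
  grid <- expand.grid(E = 10^seq(-2, 3, length.out = 40),
                      p = seq(0, 100, length.out = 15))
  v <- fd_eval(m, grid$E, grid$p)
  lo <- rational_eval(m$g3, grid$p)
  hi <- abs(rational_eval(m$g4, grid$p) - lo) + lo
  expect_true(all(v > lo & v < hi))
})

test_that("preset proton surface stays in the 5-30 yield envelope and saturates", {
  m <- proton_truth
  grid <- expand.grid(E = 10^seq(log10(0.01), 3, length.out = 60),
                      p = seq(0, 100, length.out = 21))
  v <- fd_eval(m, grid$E, grid$p)
  expect_true(all(v >= 5 & v <= 30))

  # 50% oxygen is practically indistinguishable from atmospheric 20%
  E <- 10^seq(log10(0.01), 3, length.out = 200)
  rel <- abs(fd_eval(m, E, 50) - fd_eval(m, E, 20)) / fd_eval(m, E, 20)
  expect_lt(max(rel), 0.01)
})

test_that("point OER is 1 at the reference and non-decreasing in oxygen", {
  m <- proton_truth
  for (pref in c(0, 5, 20)) {
    expect_identical(oer_point(m, 10, pref, pref), 1)
  }
  p <- seq(0, 100, length.out = 50)
  for (E in c(0.05, 1, 10, 500)) {
    o <- oer_point(m, E, p)
    expect_true(all(diff(o) >= -1e-12))
    # grid scan agrees with direct surface ratios
    expect_equal(o, fd_eval(m, E, p) / fd_eval(m, E, 0), tolerance = 1e-15)
  }
})

test_that("point operations vectorise identically to scalar loops", {
  m <- proton_truth
  E <- 10^seq(-2, 3, length.out = 17)
  p <- seq(0, 90, length.out = 17)
  vec <- fd_eval(m, E, p)
  loop <- vapply(seq_along(E), function(i) fd_eval(m, E[i], p[i]), 0)
  expect_identical(vec, loop)

  prm <- stewart_params(K = 0.26, M0 = 3, q = 950, r = 0.9)
  y <- 10^seq(0, 6, length.out = 11)
  expect_identical(stewart_M(y, prm),
                   vapply(y, stewart_M, 0, params = prm))
})

test_that("evaluation outside the fitted window warns but still evaluates", {
  m <- fd_model("proton",
                g1 = proton_truth$g1, g2 = proton_truth$g2,
                g3 = proton_truth$g3, g4 = proton_truth$g4,
                energy_range = c(0.1, 100), oxygen_range = c(0, 50))
  expect_warning(v <- fd_eval(m, 1000, 20), "fitted range")
  expect_true(is.finite(v))
  expect_warning(fd_eval(m, 10, 80), "oxygen")
  expect_silent(fd_eval(m, 10, 20))
})

test_that("model JSON files round-trip bit-exactly", {
  m <- fd_model("proton",
                g1 = rational_coeffs(1.2345678901234567, 1 / 3, pi),
                g2 = rational_coeffs(sqrt(2), 0.4, exp(1)),
                g3 = rational_coeffs(20.000000001, 8, 1 / 7),
                g4 = rational_coeffs(28, 27, 1.0000000000000002),
                provenance = "round-trip fixture")
  path <- withr::local_tempfile(fileext = ".json")
  write_fd_model(m, path)
  m2 <- read_fd_model(path)
  expect_identical(coef_vector(m2), coef_vector(m))
  expect_identical(m2$energy_range, m$energy_range)
  expect_identical(m2$species$name, m$species$name)
  expect_identical(m2$provenance, m$provenance)

  # missing keys are reported by name
  writeLines('{"species": "proton", "g1": {"a": 1, "b": 1, "c": 1}}', path)
  expect_error(read_fd_model(path), "missing keys")
})
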