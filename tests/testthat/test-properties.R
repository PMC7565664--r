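# Thermophysical property layer: Peng-Robinson density, He-Yu diffusivity,
# solubility interpolation.

test_that("Peng-Robinson density approaches the ideal gas law at low pressure", {
  Rg <- 8.314462618
  M <- 0.04401
  expect_equal(co2_density(313, 1e5), 1e5 * M / (Rg * 313),
               tolerance = 0.015)
  for (T in seq(300, 350, by = 10)) {
    for (p in c(0.5e5, 1e5, 2e5)) {
      expect_equal(co2_density(T, p), p * M / (Rg * T), tolerance = 0.02)
    }
  }
})

test_that("critical-point density matches the closed-form critical compressibility", {
  # triple root of the critical cubic: Z_c = (1 - Omega_b) / 3
  z_c <- (1 - 0.07779607390388846832) / 3
  rho_c <- 7.377e6 * 0.04401 / (z_c * 8.314462618 * 304.13)
  expect_equal(z_c, 0.3074, tolerance = 2e-4)     # the universal PR value
  expect_equal(co2_density(304.13, 7.377e6), rho_c, tolerance = 1e-3)
})

test_that("the supercritical root reproduces the cubic found independently", {
  T <- 323; p <- 1.4e7
  rho <- co2_density(T, p)
  v <- 0.04401 / rho
  # independent root solve of p(v) = p by bisection on the EOS itself
  b <- 0.07779607390388846832 * 8.314462618 * 304.13 / 7.377e6
  v_star <- uniroot(function(x) pr_pressure_oracle(x, T) - p,
                    c(1.001 * b, 1), tol = 1e-16)$root
  expect_equal(v, v_star, tolerance = 1e-8)
  # the returned root satisfies the pressure relation to near machine level
  expect_lt(abs(pr_pressure_oracle(v, T) / p - 1), 1e-10)
})

test_that("density is monotonically increasing in pressure along a supercritical isotherm", {
  p_grid <- seq(120e5, 200e5, length.out = 20)
  for (T in c(313, 323, 333)) {
    rho <- co2_density(rep(T, 20), p_grid)
    expect_true(all(diff(rho) > 0))
    # every root closes the EOS pressure relation
    for (k in seq_along(p_grid)) {
      v <- 0.04401 / rho[k]
      expect_lt(abs(pr_pressure_oracle(v, T) / p_grid[k] - 1), 1e-10)
    }
  }
})

test_that("Peng-Robinson rejects unphysical inputs", {
  expect_error(co2_density(-300, 1e5), "positive")
  expect_error(co2_density(313, 0), "positive")
})

test_that("He-Yu diffusivity has the correct magnitude and frozen reference value", {
  rho <- co2_density(323, 1.4e7)
  d <- molecular_diffusivity(323, rho)
  expect_gt(d, 5e-9)
  expect_lt(d, 5e-8)
  # regression freeze of the implemented correlation constants
  expect_equal(d, 1.157259e-08, tolerance = 1e-5)
})

test_that("He-Yu diffusivity is monotone in temperature and density", {
  rho_a <- 500; rho_b <- 700
  expect_gt(molecular_diffusivity(323, rho_a),
            molecular_diffusivity(323, rho_b))
  expect_gt(molecular_diffusivity(333, rho_a),
            molecular_diffusivity(323, rho_a))
})

test_that("He-Yu diffusivity scales as the inverse square root of solute molar mass", {
  heavy <- substance_parameters("heavy", 4 * 0.20628, 749.7, 2.95e6, 0.8)
  d1 <- molecular_diffusivity(323, 600)
  d4 <- molecular_diffusivity(323, 600, solute = heavy)
  expect_equal(d4 / d1, 0.5, tolerance = 1e-12)
})

test_that("He-Yu correlation rejects states at/below its singular reduced volume", {
  # Vr <= 0.23 corresponds to rho >= M1 / (0.23 Vc1) ~ 2033 kg/m^3
  expect_error(molecular_diffusivity(323, 2100), "singular")
})

test_that("solubility lookup returns exact entries and linear interpolants", {
  tab <- solubility_table(temperature_K = c(323, 323), pressure_bar = c(120, 160),
                          y_p = c(0.01, 0.02))
  expect_identical(solubility(323, 120e5, tab), 0.01)
  expect_equal(solubility(323, 140e5, tab), 0.015)   # midpoint
})

test_that("solubility bilinear interpolation matches hand arithmetic on a 2x2 grid", {
  tab <- solubility_table(temperature_K = c(300, 300, 320, 320),
                          pressure_bar = c(100, 200, 100, 200),
                          y_p = c(0.01, 0.03, 0.02, 0.04))
  expect_equal(solubility(310, 150e5, tab), 0.025, tolerance = 1e-12)
  expect_equal(solubility(315, 100e5, tab), 0.0175, tolerance = 1e-12)
})

test_that("solubility refuses extrapolation unless asked to clamp", {
  tab <- solubility_table(temperature_K = c(300, 300, 320, 320),
                          pressure_bar = c(100, 200, 100, 200),
                          y_p = c(0.01, 0.03, 0.02, 0.04))
  expect_error(solubility(350, 150e5, tab), "outside")
  expect_equal(solubility(350, 150e5, tab, extrapolate = TRUE), 0.03)
})

test_that("solubility tables validate their entries", {
  expect_error(solubility_table(323, 140, 0), "strictly")
  expect_error(solubility_table(c(323, 323), c(140, 140), c(0.01, 0.02)),
               "duplicate")
  tab <- default_solubility_table()
  expect_true(all(tab$entries$y_p_kg_per_kg > 0 &
                    tab$entries$y_p_kg_per_kg < 1))
})

test_that("solubility CSV round-trips", {
  tab <- default_solubility_table()
  f <- tempfile(fileext = ".csv")
  write_solubility_table(tab, f)
  expect_equal(read_solubility_table(f)$entries, tab$entries)
})
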