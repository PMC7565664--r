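# Adsorption kinetics and equilibrium relations.

test_that("aerogel sample structure is self-consistent", {
  s <- aerogel_sample()
  expect_equal(s$envelope_density * (s$specific_pore_volume +
                                       1 / s$skeletal_density), 1,
               tolerance = 1e-9)
  expect_equal(s$envelope_density, 525, tolerance = 0.01)
  expect_equal(s$porosity, 0.761, tolerance = 0.01)
  expect_error(aerogel_sample(envelope_density = 400), "inconsistent")
  expect_error(aerogel_sample(diameter = 0), "> 0")
})

test_that("effective diffusivity matches the direct-arithmetic oracle", {
  d <- effective_diffusivity(323, 140)
  oracle <- (0.0125 * 140 - 0.74) * exp(-(7.50 * 140 + 4800) / 323)
  expect_equal(d, oracle, tolerance = 1e-12)
  expect_equal(effective_diffusivity(333, 160),
               (0.0125 * 160 - 0.74) * exp(-(7.50 * 160 + 4800) / 333),
               tolerance = 1e-12)
})

test_that("effective diffusivity handles degenerate coefficients and monotonicity", {
  c0 <- coefficient_set(a1 = 0, a2 = 2e-8, a3 = 0, a4 = 4800,
                        b1 = 0.007, b2 = -1.802)
  expect_equal(effective_diffusivity(323, 120, c0),
               effective_diffusivity(323, 200, c0))
  expect_equal(effective_diffusivity(323, 150, c0), 2e-8 * exp(-4800 / 323),
               tolerance = 1e-12)
  expect_gt(effective_diffusivity(333, 160), effective_diffusivity(323, 160))
  # prefactor a1*p + a2 <= 0 is meaningless
  expect_error(effective_diffusivity(323, 50), "non-positive")
})

test_that("maximum loading matches the arithmetic oracle and guards its range", {
  expect_equal(max_loading(323), (0.007 * 323 - 1.802) * 100,
               tolerance = 1e-12)
  expect_equal(max_loading(333), 52.9, tolerance = 1e-9)
  const <- coefficient_set(0.0125, -0.74, 7.5, 4800, b1 = 0, b2 = 0.3)
  expect_equal(max_loading(300, const), 30)
  expect_equal(max_loading(400, const), 30)
  expect_error(max_loading(250), "outside")
  expect_error(max_loading(430), "outside")
})

test_that("adsorption limit matches the arithmetic oracle", {
  s <- aerogel_sample(envelope_density = NULL)
  q <- adsorption_limit(45.9, s, co2_density = 640, y_p = 0.01)
  oracle <- (45.9 * s$envelope_density) / ((100 - 45.9) * 640 * s$porosity) - 0.01
  expect_equal(q, oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.905, tolerance = 0.01)
})

test_that("adsorption limit scales and degenerates correctly", {
  s <- aerogel_sample()
  # q_inf + y_p is inversely proportional to the CO2 density
  q1 <- adsorption_limit(45.9, s, 640, 0.01)
  q2 <- adsorption_limit(45.9, s, 1280, 0.01)
  expect_equal((q2 + 0.01) * 2, q1 + 0.01, tolerance = 1e-12)
  # A_inf -> 0+ with y_p = 0 gives q_inf -> 0+
  expect_lt(adsorption_limit(1e-4, s, 640, 1e-12), 1e-5)
  # a loading target below the solubility capacity is rejected
  expect_error(adsorption_limit(0.5, s, 640, 0.5), "solubility capacity")
  expect_error(adsorption_limit(120, s, 640, 0.01), "0, 100")
})

test_that("adsorption rate constant carries the kinetic-theory scalings", {
  s <- aerogel_sample()
  K <- function(T = 323, p = 1.4e7, q_inf = 0.9)
    adsorption_rate_constant(T, p, s, q_inf = q_inf)
  expect_equal(K(q_inf = 0.45), 2 * K(q_inf = 0.9), tolerance = 1e-12)
  expect_equal(K(p = 2.8e7), 2 * K(p = 1.4e7), tolerance = 1e-12)
  # T^(-1/2) through the impingement flux
  expect_equal(K(T = 4 * 323) * 2, K(T = 323), tolerance = 1e-12)
  # independent hand evaluation of the closed form
  Ma <- 0.20628; Mmix <- 0.04401; Rg <- 8.314462618
  hand <- 1.4e7 * 9.75e5 * Ma /
    (2 * 0.9 * Mmix * sqrt(2 * pi * Ma * Rg * 323))
  expect_equal(K(), hand, tolerance = 1e-12)
  # the alternative typographic reading differs by the documented factor
  K2 <- adsorption_rate_constant(323, 1.4e7, s, q_inf = 0.9,
                                 variant = "molar-mass-squared")
  expect_equal(K2 / K(), 2 * Ma, tolerance = 1e-12)
  expect_error(K(q_inf = 0), "> 0")
})

test_that("adsorption source term is an antisymmetric sink/gain pair", {
  st <- adsorption_state(q = 0.4, q_inf = 0.9, rate_constant = 2)
  src <- adsorption_source(0.01, st)
  expect_equal(src$S_q, -0.01, tolerance = 1e-14)
  expect_equal(src$dq_dt, 0.01, tolerance = 1e-14)
  # saturated and solute-free states are inert
  expect_equal(adsorption_source(0.01, adsorption_state(0.9, 0.9, 2))$S_q, 0)
  expect_equal(adsorption_source(0, st)$dq_dt, 0)
  # property: S_q + dq_dt = 0 at machine precision over random states
  set.seed(42)
  for (i in 1:200) {
    qi <- runif(1, 0, 1); y2 <- runif(1)
    sti <- adsorption_state(qi, q_inf = 1, rate_constant = runif(1, 0, 1e6))
    sr <- adsorption_source(y2, sti)
    expect_identical(sr$S_q + sr$dq_dt, 0)
  }
  expect_error(adsorption_state(1.2, 0.9, 2), "q_inf")
})

test_that("exact adsorption step conserves mass and approaches q_inf monotonically", {
  q_inf <- 0.9
  for (K in c(1, 1e9)) {            # non-stiff and very stiff exchange
    for (dt in c(0.01, 100)) {
      q <- 0; y2 <- 0.01
      traj <- numeric(0)
      for (i in 1:300) {
        upd <- adsorption_step(y2, q, q_inf, K, dt)
        # the pair exchange conserves y2 + q exactly
        expect_equal(upd$y2 + upd$q, y2 + q, tolerance = 1e-15)
        q <- upd$q
        y2 <- 0.01                  # replenished bath
        traj <- c(traj, q)
      }
      expect_true(all(diff(traj) >= -1e-15))
      expect_true(all(traj <= q_inf * (1 + 1e-12)))
    }
  }
  # saturating limit: stiff exchange strips the fluid within one step
  upd <- adsorption_step(0.01, 0, q_inf, 1e12, 10)
  expect_equal(upd$q, 0.01, tolerance = 1e-9)
  expect_equal(upd$y2, 0, tolerance = 1e-11)
})

test_that("coefficient sets serialize to flat JSON with a pressure-unit marker", {
  f <- tempfile(fileext = ".json")
  write_coefficients(default_coefficients(), f)
  obj <- jsonlite::read_json(f)
  expect_identical(obj$pressure_unit, "bar")
  back <- read_coefficients(f)
  expect_equal(unclass(back), unclass(default_coefficients()))
})
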