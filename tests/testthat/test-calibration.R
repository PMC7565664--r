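# Golden-section search, discrepancy objective, and correlation regression.

test_that("golden-section search minimises smooth and non-smooth unimodal functions", {
  r1 <- golden_section_minimize(function(x) (x - 2)^2, 0, 5, tol = 1e-8)
  expect_equal(r1$minimum, 2, tolerance = 1e-7)
  expect_true(r1$interior)
  r2 <- golden_section_minimize(function(x) abs(x - 0.3), 0, 1, tol = 1e-6)
  expect_equal(r2$minimum, 0.3, tolerance = 1e-5)
})

test_that("golden-section iteration count follows the contraction arithmetic", {
  r <- golden_section_minimize(function(x) (x - 2)^2, 0, 5, tol = 1e-8)
  invphi <- (sqrt(5) - 1) / 2
  expected <- ceiling(log(5 / 1e-8) / log(1 / invphi))
  expect_lte(abs(r$iterations - expected), 2)
})

test_that("golden-section search never leaves the bracket and validates inputs", {
  seen <- numeric(0)
  f <- function(x) { seen <<- c(seen, x); (x - 0.7)^2 }
  golden_section_minimize(f, 0.2, 1.3, tol = 1e-6)
  expect_true(all(seen >= 0.2 & seen <= 1.3))
  expect_error(golden_section_minimize(f, 0, 1, tol = -1), "tol")
  expect_error(golden_section_minimize(f, 1, 0), "lo < hi")
  expect_error(
    golden_section_minimize(function(x) ifelse(x > 0.5, NaN, x), 0, 1),
    "non-finite")
})

test_that("relative error metric matches its defining arithmetic", {
  d <- data.frame(temperature_K = 323, pressure_bar = 140,
                  time_h = rep(1:2, each = 2),
                  loading_pct = c(10, 10, 25, 25), replicate = c(1, 2, 1, 2))
  model_exact <- data.frame(time_h = 1:2, loading_pct = c(10, 25))
  expect_equal(relative_error(model_exact, d), 0)
  model_11 <- data.frame(time_h = 1:2, loading_pct = c(11, 27.5))
  expect_equal(relative_error(model_11, d), 10, tolerance = 1e-12)
  model_mix <- data.frame(time_h = 1:2, loading_pct = c(10, 20))
  expect_equal(relative_error(model_mix, d), 10, tolerance = 1e-12)
  d0 <- d; d0$loading_pct[3:4] <- 0
  expect_warning(e <- relative_error(model_mix, d0), "zero")
  expect_equal(e, 0)
})

test_that("replicate averaging makes the objective invariant to duplication", {
  d1 <- data.frame(temperature_K = 323, pressure_bar = 140,
                   time_h = 1:3, loading_pct = c(10, 20, 30), replicate = 1)
  d2 <- rbind(d1, d1, d1)   # triplicated time points
  model <- data.frame(time_h = 1:3, loading_pct = c(11, 21, 32))
  expect_equal(relative_error(model, d1), relative_error(model, d2))
})

test_that("the effective diffusivity is recovered from a noise-free curve", {
  g <- default_grid_8x32()
  cond <- data.frame(temperature_K = 323, pressure_bar = 160)
  data <- generate_kinetics(cond, noise_cv = 0, grid = g)
  fit <- fit_effective_diffusivity(data, 323, 160, a_inf = max_loading(323),
                                   grid = g)
  expect_equal(fit$d_omega_hat, effective_diffusivity(323, 160),
               tolerance = 0.01)
  expect_true(fit$interior)
})

test_that("a bracket that misses the truth is flagged as a non-interior minimum", {
  g <- default_grid_8x32()
  cond <- data.frame(temperature_K = 323, pressure_bar = 160)
  data <- generate_kinetics(cond, noise_cv = 0, grid = g)
  expect_warning(
    fit <- fit_effective_diffusivity(data, 323, 160,
                                     a_inf = max_loading(323), grid = g,
                                     bracket = c(1e-13, 2e-11)),
    "not interior")
  expect_false(fit$interior)
  expect_equal(log10(fit$d_omega_hat), log10(2e-11), tolerance = 0.01)
})

test_that("correlation regression reproduces generating coefficients exactly", {
  truth <- default_coefficients()
  pc <- fit_conditions()
  pc$d_omega_hat <- mapply(function(T, p) effective_diffusivity(T, p, truth),
                           pc$temperature_K, pc$pressure_bar)
  pc$a_inf_hat <- max_loading(pc$temperature_K, truth)
  fit <- fit_correlations(pc)
  for (nm in c("a1", "a2", "a3", "a4"))
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-4)
  # two-temperature line solved by hand: b1 = (0.529 - 0.459)/10
  expect_equal(fit$b1, 0.007, tolerance = 1e-10)
  expect_equal(fit$b2, -1.802, tolerance = 1e-7)
})

test_that("identical diffusivities yield the degenerate pressure-free fit", {
  pc <- fit_conditions()
  pc$d_omega_hat <- 1e-8
  pc$a_inf_hat <- max_loading(pc$temperature_K)
  expect_warning(fit <- fit_correlations(pc), "degenerate")
  expect_equal(fit$a1, 0)
  expect_equal(fit$a3, 0)
  expect_equal(fit$a2 * exp(-fit$a4 / 323), 1e-8, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with informative errors", {
  pc <- fit_conditions()
  pc$d_omega_hat <- mapply(effective_diffusivity, pc$temperature_K,
                           pc$pressure_bar)
  pc$a_inf_hat <- max_loading(pc$temperature_K)
  expect_error(fit_correlations(pc[1:3, ]), "4 distinct")
  one_T <- data.frame(temperature_K = 323,
                      pressure_bar = c(120, 140, 160, 200))
  one_T$d_omega_hat <- mapply(effective_diffusivity, one_T$temperature_K,
                              one_T$pressure_bar)
  one_T$a_inf_hat <- max_loading(one_T$temperature_K)
  expect_error(fit_correlations(one_T), "temperatures")
  one_p <- pc[pc$pressure_bar == 120, ]
  expect_error(fit_correlations(one_p), "4 distinct|pressures")
})
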