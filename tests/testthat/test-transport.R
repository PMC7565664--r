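# Axisymmetric finite-volume transport solver.

test_that("the grid tiles the reactor and the monolith exactly", {
  geom <- reactor_geometry()
  g <- build_grid(geom, 8, 32)
  expect_equal(sum(g$volume), geom$reactor_volume, tolerance = 5e-3)
  v_omega <- sum(g$volume[g$region == "omega"])
  expect_equal(v_omega, pi * 0.005^2 * 0.05, tolerance = 5e-3)
  # the conforming edges actually make both exact
  expect_equal(v_omega, pi * 0.005^2 * 0.05, tolerance = 1e-12)
  # refinement by 2x increases the cell count 4x
  g2 <- build_grid(geom, 16, 64)
  expect_equal(length(g2$volume), 4L * length(g$volume))
})

test_that("grids reject unresolvable monoliths", {
  expect_error(build_grid(reactor_geometry(), 2, 32), ">= 4")
  expect_error(build_grid(reactor_geometry(), 8, 4), ">= 8")
  thin <- reactor_geometry(monolith_diameter = 0.002)
  expect_error(build_grid(thin, 8, 32), "not resolvable")
})

test_that("a zero source concentration leaves all fields identically zero", {
  g <- default_grid_8x32()
  ctl <- scad_control(ys = 0)
  sim <- simulate_adsorption(323, 140, aerogel_sample(),
                             default_coefficients(),
                             default_solubility_table(), g, t_end = 3600,
                             control = ctl)
  expect_identical(max(abs(sim$y2_field)), 0)
  expect_identical(max(abs(sim$q_field)), 0)
  expect_identical(max(abs(sim$loading_curve$loading_pct)), 0)
})

test_that("solute is conserved to round-off in both reactor treatments", {
  g <- default_grid_8x32()
  s <- aerogel_sample()
  for (mode in c("well_mixed", "diffusive")) {
    ctl <- scad_control(theta_model = mode)
    sim <- simulate_adsorption(323, 140, s, default_coefficients(),
                               default_solubility_table(), g,
                               t_end = 4 * 3600, control = ctl)
    expect_lt(max(abs(sim$conservation$rel_error)), 1e-10)
  }
})

test_that("pure diffusion respects the maximum principle", {
  g <- default_grid_8x32()
  ctl <- scad_control(theta_model = "diffusive", k_rate = 0)
  sim <- simulate_adsorption(323, 140, aerogel_sample(),
                             default_coefficients(),
                             default_solubility_table(), g,
                             t_end = 10 * 3600, control = ctl)
  ys <- sim$params$ys
  expect_gte(min(sim$y2_field), 0)
  expect_lte(max(sim$y2_field), ys * (1 + 1e-10))
})

test_that("the loading curve is monotone and increases with the effective diffusivity", {
  g <- default_grid_8x32()
  s <- aerogel_sample()
  d0 <- effective_diffusivity(323, 140)
  a5 <- vapply(c(0.5, 1, 2) * d0, function(d) {
    sim <- simulate_adsorption(323, 140, s, default_coefficients(),
                               default_solubility_table(), g,
                               t_end = 2 * 3600,
                               control = scad_control(d_omega = d))
    expect_true(all(diff(sim$loading_curve$loading_pct) >= -1e-10))
    tail(sim$loading_curve$loading_pct, 1)
  }, numeric(1))
  expect_true(all(diff(a5) > 0))
})

test_that("adsorbed amount is non-decreasing cell-wise and bounded by q_inf", {
  g <- default_grid_8x32()
  sim <- simulate_adsorption(323, 140, aerogel_sample(),
                             default_coefficients(),
                             default_solubility_table(), g, t_end = 4 * 3600)
  dq <- t(apply(sim$q_field, 1, diff))
  expect_true(all(dq >= -1e-14))
  expect_lte(max(sim$q_field), sim$params$q_inf * (1 + 1e-12))
  expect_lte(max(sim$y2_field), sim$params$ys * (1 + 1e-10))
})

test_that("spatial refinement converges at first order or better", {
  geom <- reactor_geometry()
  s <- aerogel_sample()
  A <- vapply(list(c(6L, 17L), c(12L, 34L), c(24L, 68L)), function(nn) {
    g <- build_grid(geom, nn[1], nn[2])
    sim <- simulate_adsorption(323, 140, s, default_coefficients(),
                               default_solubility_table(), g,
                               t_end = 5400, dt = 30)
    tail(sim$loading_curve$loading_pct, 1)
  }, numeric(1))
  order_obs <- log2(abs(A[2] - A[1]) / abs(A[3] - A[2]))
  expect_gte(order_obs, 0.9)
})

test_that("the explicit scheme auto-reduces an unstable step with a warning", {
  g <- default_grid_8x32()
  ctl <- scad_control(scheme = "explicit")
  expect_warning(
    sim <- simulate_adsorption(323, 140, aerogel_sample(),
                               default_coefficients(),
                               default_solubility_table(), g,
                               t_end = 1800, dt = 1800, control = ctl),
    "stability")
  expect_lt(max(abs(sim$conservation$rel_error)), 1e-10)
})

test_that("total loading reproduces constructed uniform fields", {
  g <- default_grid_8x32()
  s <- aerogel_sample()
  rho <- 640
  om <- which(g$region == "omega")
  v_om <- sum(g$volume[om])
  m_aero <- s$envelope_density * v_om
  # uniform fields engineered so that m_ibu = m_aero / 3, i.e. A = 25 %
  target <- m_aero / 3 / (rho * s$porosity * v_om)
  A <- total_loading(rep(target / 2, length(om)), rep(target / 2, length(om)),
                     g, s, rho)
  expect_equal(A, 25, tolerance = 1e-12)
  expect_equal(total_loading(rep(0, length(om)), rep(0, length(om)), g, s, rho),
               0)
})

test_that("equilibrium fields close on the maximum-loading correlation", {
  g <- default_grid_8x32()
  s <- aerogel_sample()
  rho <- co2_density(323, 140e5)
  ys <- solubility(323, 140e5, default_solubility_table())
  a_inf <- max_loading(323)
  q_inf <- adsorption_limit(a_inf, s, rho, ys)
  om <- which(g$region == "omega")
  A <- total_loading(rep(ys, length(om)), rep(q_inf, length(om)), g, s, rho)
  expect_equal(A, a_inf, tolerance = 1e-10)
})

test_that("field export has the documented long format", {
  g <- default_grid_8x32()
  sim <- simulate_adsorption(323, 140, aerogel_sample(),
                             default_coefficients(),
                             default_solubility_table(), g, t_end = 1800,
                             control = scad_control(n_snapshots = 3))
  df <- as_field_data(sim)
  expect_named(df, c("time_s", "r_m", "z_m", "region", "y2", "q"))
  expect_true(all(is.na(df$q[df$region == "theta"])))
  expect_true(all(!is.na(df$q[df$region == "omega"])))
  f <- tempfile(fileext = ".csv")
  write_loading_csv(sim, f)
  expect_identical(readLines(f, n = 1L), "time_h,loading_pct")
})
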