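# Shared fixtures and independent oracles for the test suite.

default_grid_8x32 <- function() build_grid(reactor_geometry(), 8, 32)

# independent Peng-Robinson pressure evaluation (used to cross-check the
# density root without going through the package's cubic solver)
pr_pressure_oracle <- function(v, T, Tc = 304.13, pc = 7.377e6, w = 0.2239) {
  Rg <- 8.314462618
  a <- 0.45723552892138218938 * Rg^2 * Tc^2 / pc
  b <- 0.07779607390388846832 * Rg * Tc / pc
  kap <- 0.37464 + 1.54226 * w - 0.26992 * w^2
  alp <- (1 + kap * (1 - sqrt(T / Tc)))^2
  Rg * T / (v - b) - a * alp / (v^2 + 2 * b * v - b^2)
}

# roots of the Bessel function J0, for the analytic cylinder-uptake series
j0_roots <- function(n) {
  vapply(seq_len(n), function(k) {
    guess <- (k - 0.25) * pi
    uniroot(function(x) besselJ(x, 0), c(guess - 1, guess + 1),
            tol = 1e-14)$root
  }, numeric(1))
}

# fractional uptake of an infinite cylinder with constant surface
# concentration: M(t)/M_inf = 1 - sum 4/a_n^2 exp(-a_n^2 Fo)
cylinder_uptake_series <- function(fo, nterms = 60) {
  a <- j0_roots(nterms)
  vapply(fo, function(f) 1 - sum(4 / a^2 * exp(-a^2 * f)), numeric(1))
}

# fractional uptake of a simulation relative to pore saturation (K = 0)
fractional_uptake <- function(sim, times_s) {
  g <- sim$grid
  s <- sim$sample
  v_om <- sum(g$volume[sim$omega_cells])
  m_inf <- sim$params$rho * s$porosity * v_om * sim$params$ys
  m_aero <- s$envelope_density * v_om
  A <- sim$loading_curve$loading_pct
  m_ibu <- A / (100 - A) * m_aero
  approx(sim$loading_curve$time_s, m_ibu / m_inf, xout = times_s)$y
}
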