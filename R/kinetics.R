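## Bespoke kinetic and equilibrium relations of the impregnation model:
## adsorption source term, kinetic-theory rate constant, adsorption limit,
## and the empirical effective-diffusivity / maximum-loading correlations.

#' Aerogel monolith sample description
#'
#' Geometric and structural properties of the cylindrical silica-aerogel
#' monolith.  Envelope density and porosity are derived from the specific
#' pore volume and the skeletal (silica) density unless given explicitly, in
#' which case they must satisfy
#' `envelope_density * (specific_pore_volume + 1/skeletal_density) = 1`
#' within 1e-6.
#'
#' Defaults describe the measured material: specific surface 975 m^2/g,
#' pore volume 1.45 cm^3/g, monolith diameter 10 mm, length 50 mm, silica
#' skeletal density 2200 kg/m^3 (giving envelope density ~525 kg/m^3 and
#' porosity ~0.761).
#'
#' @param specific_surface Internal specific surface area, m^2/kg.
#' @param specific_pore_volume Specific pore volume, m^3/kg.
#' @param skeletal_density Skeletal density of the solid phase, kg/m^3.
#' @param diameter,length Monolith dimensions, m.
#' @param envelope_density Optional envelope (bulk) density, kg/m^3.
#' @param porosity Optional porosity (fraction).
#'
#' @return An object of class `aerogel_sample`.
#' @export
aerogel_sample <- function(specific_surface = 975e3,
                           specific_pore_volume = 1.45e-3,
                           skeletal_density = 2200,
                           diameter = 0.010,
                           length = 0.050,
                           envelope_density = NULL,
                           porosity = NULL) {
  if (diameter <= 0 || length <= 0) stop_scad("diameter and length must be > 0")
  if (specific_surface <= 0 || specific_pore_volume <= 0 || skeletal_density <= 0)
    stop_scad("structural properties must be > 0")
  rho_env <- envelope_density %||%
    (1 / (specific_pore_volume + 1 / skeletal_density))
  eps <- porosity %||% (specific_pore_volume * rho_env)
  if (eps <= 0 || eps >= 1)
    stop_scad("porosity must lie strictly in (0, 1)")
  closure <- rho_env * (specific_pore_volume + 1 / skeletal_density)
  if (abs(closure - 1) > 1e-6)
    stop_scad(sprintf(
      "inconsistent structure: envelope_density*(pore_volume + 1/skeletal_density) = %.8f, expected 1",
      closure))
  structure(list(
    specific_surface = specific_surface,
    specific_pore_volume = specific_pore_volume,
    skeletal_density = skeletal_density,
    envelope_density = rho_env,
    porosity = eps,
    diameter = diameter,
    length = length
  ), class = "aerogel_sample")
}

#' @export
print.aerogel_sample <- function(x, ...) {
  cat("<aerogel_sample>\n")
  cat(sprintf("  S      = %.4g m^2/kg\n  Vpore  = %.4g m^3/kg\n",
              x$specific_surface, x$specific_pore_volume))
  cat(sprintf("  rho    = %.1f kg/m^3 (envelope), %.0f kg/m^3 (skeletal)\n",
              x$envelope_density, x$skeletal_density))
  cat(sprintf("  eps    = %.4f\n  size   = %.0f mm (dia) x %.0f mm\n",
              x$porosity, 1e3 * x$diameter, 1e3 * x$length))
  invisible(x)
}

#' Empirical coefficient set for the transport/equilibrium correlations
#'
#' Six coefficients of the effective-diffusivity and maximum-loading
#' correlations
#' \deqn{D_\Omega(T, p) = (a_1 p + a_2)\,e^{-(a_3 p + a_4)/T}}
#' \deqn{A_\infty(T) = (b_1 T + b_2) \cdot 100}
#' with p in bar and T in K at this interface (SI everywhere else in the
#' package; the conversion happens at the module boundary because the
#' coefficient units only make numerical sense with pressure in bar).
#' Units: a1 (m^2/s)/bar, a2 m^2/s, a3 K/bar, a4 K, b1 1/K, b2
#' dimensionless.  Fitted values may legitimately be negative (a2, b2).
#'
#' @param a1,a2,a3,a4,b1,b2 Numeric coefficients.
#' @return An object of class `coefficient_set`.
#' @seealso [default_coefficients()], [effective_diffusivity()],
#'   [max_loading()]
#' @export
coefficient_set <- function(a1, a2, a3, a4, b1, b2) {
  vals <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4, b1 = b1, b2 = b2)
  if (any(!is.finite(vals))) stop_scad("all coefficients must be finite")
  structure(as.list(vals), class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set> (pressure in bar)\n")
  cat(sprintf("  a1 = %#.5g (m^2/s)/bar   a2 = %#.5g m^2/s\n", x$a1, x$a2))
  cat(sprintf("  a3 = %#.5g K/bar         a4 = %#.5g K\n", x$a3, x$a4))
  cat(sprintf("  b1 = %#.5g 1/K           b2 = %#.5g\n", x$b1, x$b2))
  invisible(x)
}

#' Reference coefficients for the ibuprofen / silica-aerogel system
#'
#' The bundled reference calibration of the effective-diffusivity and
#' maximum-loading correlations for RS-ibuprofen impregnated into silica
#' aerogel from supercritical CO2: a1 = 0.0125 (m^2/s)/bar, a2 = -0.74
#' m^2/s, a3 = 7.50 K/bar, a4 = 4800 K, b1 = 0.007 1/K, b2 = -1.802.
#'
#' @return A [coefficient_set()].
#' @export
default_coefficients <- function() {
  coefficient_set(a1 = 0.0125, a2 = -0.74, a3 = 7.50, a4 = 4800,
                  b1 = 0.007, b2 = -1.802)
}

#' Read / write a coefficient set as flat JSON
#'
#' Serialization format: a flat JSON object with keys `a1`..`b2` and a
#' `pressure_unit: "bar"` marker.
#'
#' @param path File path.
#' @return [read_coefficients()] returns a [coefficient_set()];
#'   `write_coefficients()` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$pressure_unit) && !identical(obj$pressure_unit, "bar"))
    stop_scad("coefficient file must declare pressure_unit \"bar\"")
  coefficient_set(obj$a1, obj$a2, obj$a3, obj$a4, obj$b1, obj$b2)
}

#' @rdname read_coefficients
#' @param coeffs A [coefficient_set()].
#' @export
write_coefficients <- function(coeffs, path) {
  obj <- c(unclass(coeffs), list(pressure_unit = "bar"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Effective diffusivity correlation
#'
#' \deqn{D_\Omega(T, p) = (a_1 p + a_2)\,e^{-(a_3 p + a_4)/T}}
#' Lumped transport coefficient for solute migration inside the porous
#' monolith, Arrhenius-type in temperature with pressure-dependent
#' prefactor and apparent activation temperature.
#'
#' @param T Temperature, K.
#' @param p_bar Pressure, bar (note: bar, not Pa, at this interface).
#' @param coeffs A [coefficient_set()].
#' @return Effective diffusivity, m^2/s.
#' @examples
#' effective_diffusivity(323, 140)  # ~1.38e-8 m^2/s with the defaults
#' @export
effective_diffusivity <- function(T, p_bar, coeffs = default_coefficients()) {
  pref <- coeffs$a1 * p_bar + coeffs$a2
  if (any(pref <= 0))
    stop_scad(sprintf(
      "effective-diffusivity prefactor a1*p + a2 is non-positive at p = %g bar",
      p_bar[which(pref <= 0)[1L]]), class = "scad_domain_error")
  pref * exp(-(coeffs$a3 * p_bar + coeffs$a4) / T)
}

#' Maximum-loading correlation
#'
#' \deqn{A_\infty(T) = (b_1 T + b_2) \cdot 100}
#' Equilibrium loading of the monolith in mass percent (adsorbed plus
#' pore-dissolved solute over total solute-plus-aerogel mass), linear in
#' temperature.  Values outside (0, 100) indicate the correlation has been
#' extrapolated beyond its meaningful range and raise an error.
#'
#' @param T Temperature, K.
#' @param coeffs A [coefficient_set()].
#' @return Maximum loading, mass percent.
#' @examples
#' max_loading(323)  # 45.9 % with the defaults
#' @export
max_loading <- function(T, coeffs = default_coefficients()) {
  A <- (coeffs$b1 * T + coeffs$b2) * 100
  if (any(A <= 0 | A >= 100))
    stop_scad(sprintf(
      "maximum loading %.3g%% at T = %g K lies outside (0, 100): correlation extrapolated too far",
      A[which(A <= 0 | A >= 100)[1L]], T[which(A <= 0 | A >= 100)[1L]]),
      class = "scad_domain_error")
  A
}

#' Adsorption limit from the maximum loading
#'
#' Converts the equilibrium loading percentage A_inf into the adsorption
#' limit per unit mixture mass,
#' \deqn{q_\infty = \frac{A_\infty \rho_{aer}}{(100 - A_\infty)\,\rho\,\varepsilon} - Y_p,}
#' subtracting the pore-dissolved fraction Y_p: inside the monolith part of
#' the solute is dissolved in the pore CO2 and only the remainder is bound
#' to the internal surface.
#'
#' @param A_inf Maximum loading, mass percent, in (0, 100).
#' @param sample An [aerogel_sample()].
#' @param co2_density CO2 density at process conditions, kg/m^3.
#' @param y_p Solubility at process conditions, kg/kg.
#' @return Adsorption limit, kg solute / kg mixture.
#' @export
adsorption_limit <- function(A_inf, sample, co2_density, y_p) {
  if (A_inf <= 0 || A_inf >= 100) stop_scad("A_inf must lie in (0, 100)")
  if (co2_density <= 0) stop_scad("co2_density must be > 0")
  q_inf <- A_inf * sample$envelope_density /
    ((100 - A_inf) * co2_density * sample$porosity) - y_p
  if (q_inf <= 0)
    stop_scad(sprintf(
      "adsorption limit %.4g <= 0: loading target below the solubility capacity",
      q_inf), class = "scad_domain_error")
  q_inf
}

#' Adsorption rate constant from molecular-kinetic theory
#'
#' Hertz-Knudsen impingement form: the molar flux p / sqrt(2 pi M_a R T)
#' striking the internal surface S per unit aerogel mass, converted to the
#' mixture-mass basis,
#' \deqn{K = \frac{p\,S\,M_a}{2\,q_\infty\,M_{mix}\sqrt{2\pi M_a R T}}.}
#' This correlation is typeset ambiguously in the literature; the
#' alternative reading with a squared solute molar mass and no factor 2 is
#' available via `variant = "molar-mass-squared"`.  K is large at process conditions
#' (adsorption is locally fast and the uptake is diffusion-limited), so the
#' simulated loading kinetics are insensitive to the variant.
#'
#' @param T Temperature, K.
#' @param p Pressure, Pa.
#' @param sample An [aerogel_sample()].
#' @param solute,solvent [substance_parameters()].
#' @param q_inf Adsorption limit, kg/kg (must be > 0).
#' @param variant `"canonical"` (default) or `"molar-mass-squared"`.
#' @return Rate constant K, 1/s per unit solute mass fraction.
#' @export
adsorption_rate_constant <- function(T, p, sample,
                                     solute = ibuprofen_parameters(),
                                     solvent = co2_parameters(),
                                     q_inf,
                                     variant = c("canonical",
                                                 "molar-mass-squared")) {
  variant <- match.arg(variant)
  if (any(c(T, p, q_inf) <= 0))
    stop_scad("T, p and q_inf must all be > 0")
  Ma <- solute$molar_mass
  Mmix <- solvent$molar_mass
  flux <- p / sqrt(2 * pi * Ma * .R_GAS * T)   # molar impingement flux
  S <- sample$specific_surface
  switch(variant,
         "canonical" = flux * S * Ma / (2 * q_inf * Mmix),
         "molar-mass-squared" = flux * S * Ma^2 / (q_inf * Mmix))
}

#' Adsorption state
#'
#' Pointwise state of the adsorbed phase: current adsorption `q`, limit
#' `q_inf` (both kg solute per kg mixture) and rate constant.
#'
#' @param q Current adsorption, kg/kg.
#' @param q_inf Adsorption limit, kg/kg.
#' @param rate_constant Rate constant K, 1/s per unit mass fraction.
#' @return An object of class `adsorption_state`.
#' @export
adsorption_state <- function(q, q_inf, rate_constant) {
  if (q_inf < 0) stop_scad("q_inf must be >= 0")
  if (any(q < 0) || any(q > q_inf * (1 + 1e-12)))
    stop_scad("q must satisfy 0 <= q <= q_inf",
              class = "scad_invariant_error")
  structure(list(q = q, q_inf = q_inf, rate_constant = rate_constant),
            class = "adsorption_state")
}

#' Langmuir-kinetics adsorption source term
#'
#' Mass exchange between the pore fluid and the adsorbed phase:
#' \deqn{S_q = -K Y_2 (q_\infty - q), \qquad dq/dt = -S_q,}
#' a sink in the fluid species balance and the exactly antisymmetric gain of
#' the adsorbed phase (no desorption term: single-site Langmuir kinetics far
#' from desorption equilibrium).
#'
#' @param y2 Solute mass fraction in the pore fluid, in \[0, 1\].
#' @param state An [adsorption_state()].
#' @return A list with components `S_q` (1/s-scaled mass-fraction sink,
#'   <= 0) and `dq_dt` (kg/kg/s, >= 0).
#' @export
adsorption_source <- function(y2, state) {
  stopifnot(inherits(state, "adsorption_state"))
  if (any(y2 < 0) || any(y2 > 1)) stop_scad("y2 must lie in [0, 1]")
  if (any(state$q > state$q_inf * (1 + 1e-12)))
    stop_scad("q exceeds q_inf on entry", class = "scad_invariant_error")
  rate <- state$rate_constant * y2 * pmax(state$q_inf - state$q, 0)
  list(S_q = -rate, dq_dt = rate)
}

#' Exact integration of the coupled adsorption exchange over a time step
#'
#' Advances the pointwise fluid/adsorbed pair (Y2, q) under
#' dq/dt = K Y2 (q_inf - q), dY2/dt = -dq/dt for a step dt, using the
#' closed-form solution of the coupled system (the sum c = Y2 + q is an
#' exact invariant).  This is unconditionally stable and positivity- and
#' bound-preserving for arbitrarily large K dt, which matters because the
#' kinetic-theory rate constant makes the exchange locally very stiff.
#'
#' @param y2,q Current fluid mass fraction and adsorption (vectors allowed).
#' @param q_inf Adsorption limit, kg/kg.
#' @param K Rate constant, 1/s per unit mass fraction.
#' @param dt Time step, s.
#' @return A list with updated `y2` and `q`.
#' @export
adsorption_step <- function(y2, q, q_inf, K, dt) {
  if (dt < 0) stop_scad("dt must be >= 0")
  n <- max(length(y2), length(q))
  y2 <- rep_len(y2, n)
  q <- pmin(rep_len(q, n), q_inf)
  if (K == 0 || dt == 0) return(list(y2 = y2, q = q))
  cc <- y2 + q
  qn <- q
  act <- y2 > 0 & q < q_inf
  if (any(act)) {
    c_a <- cc[act]; q0 <- q[act]
    deg <- abs(c_a - q_inf) < 1e-14 * max(1, q_inf)
    qa <- numeric(length(q0))
    if (any(deg)) {   # c == q_inf: dq/dt = K (q_inf - q)^2
      u0 <- q_inf - q0[deg]
      qa[deg] <- q_inf - u0 / (1 + K * u0 * dt)
    }
    if (any(!deg)) {
      cnd <- c_a[!deg]; q0n <- q0[!deg]
      ex <- K * (q_inf - cnd) * dt
      big <- ex > 500
      r <- (q_inf - q0n) / (cnd - q0n) * exp(pmin(ex, 500))
      qq <- (r * cnd - q_inf) / (r - 1)
      # overflow branch: fluid fully stripped, q -> c (< q_inf)
      qq[big] <- cnd[big]
      qa[!deg] <- qq
    }
    qa <- pmin(pmax(qa, q0), pmin(c_a, q_inf))
    qn[act] <- qa
  }
  list(y2 = cc - qn, q = qn)
}
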