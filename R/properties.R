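#' Substance parameters
#'
#' Container for the pure-component constants used by the equation of state
#' and the diffusivity correlation.  All quantities are SI.
#'
#' @param name Character name of the substance.
#' @param molar_mass Molar mass, kg/mol.
#' @param critical_temperature Critical temperature, K.
#' @param critical_pressure Critical pressure, Pa.
#' @param acentric_factor Pitzer acentric factor (dimensionless).
#' @param critical_molar_volume Critical molar volume, m^3/mol.  Required by
#'   the He-Yu diffusivity correlation for the solvent; may be `NA` otherwise.
#'
#' @return An object of class `substance_parameters`.
#' @seealso [co2_parameters()], [ibuprofen_parameters()]
#' @export
substance_parameters <- function(name, molar_mass, critical_temperature,
                                 critical_pressure, acentric_factor,
                                 critical_molar_volume = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop_scad("molar_mass must be > 0")
  if (!is.finite(critical_temperature) || critical_temperature <= 0)
    stop_scad("critical_temperature must be > 0")
  if (!is.finite(critical_pressure) || critical_pressure <= 0)
    stop_scad("critical_pressure must be > 0")
  structure(list(
    name = name,
    molar_mass = molar_mass,
    critical_temperature = critical_temperature,
    critical_pressure = critical_pressure,
    acentric_factor = acentric_factor,
    critical_molar_volume = critical_molar_volume
  ), class = "substance_parameters")
}

#' @export
print.substance_parameters <- function(x, ...) {
  cat(sprintf("<substance_parameters> %s\n", x$name))
  cat(sprintf("  M  = %.5f kg/mol\n  Tc = %.2f K\n  pc = %.4g Pa\n  w  = %.4f\n",
              x$molar_mass, x$critical_temperature, x$critical_pressure,
              x$acentric_factor))
  invisible(x)
}

#' Carbon dioxide constants
#'
#' Standard critical constants of CO2: Tc = 304.13 K, pc = 7.377 MPa,
#' acentric factor 0.2239, molar mass 0.04401 kg/mol, critical molar volume
#' 9.412e-5 m^3/mol (from the critical density 467.6 kg/m^3).
#'
#' @return A [substance_parameters()] object for CO2.
#' @export
co2_parameters <- function() {
  substance_parameters(
    name = "carbon dioxide",
    molar_mass = 0.04401,
    critical_temperature = 304.13,
    critical_pressure = 7.377e6,
    acentric_factor = 0.2239,
    critical_molar_volume = 9.412e-5
  )
}

#' Racemic ibuprofen constants
#'
#' Molar mass 0.20628 kg/mol; critical constants from group-contribution
#' estimates (Tc ~ 750 K, pc ~ 2.95 MPa).  Only the molar mass enters the
#' transport and kinetics calculations; the critical constants are provided
#' for completeness.
#'
#' @return A [substance_parameters()] object for RS-ibuprofen.
#' @export
ibuprofen_parameters <- function() {
  substance_parameters(
    name = "RS-ibuprofen",
    molar_mass = 0.20628,
    critical_temperature = 749.7,
    critical_pressure = 2.95e6,
    acentric_factor = 0.818
  )
}

#' Fluid state
#'
#' Temperature, pressure, density, and composition of the CO2/solute mixture
#' at a point or in a compartment.  Mass fractions must sum to one.
#'
#' @param temperature K. @param pressure Pa. @param density kg/m^3.
#' @param y2_solute Solute mass fraction, kg/kg; the solvent fraction is
#'   `1 - y2_solute`.
#' @return An object of class `fluid_state`.
#' @export
fluid_state <- function(temperature, pressure, density, y2_solute = 0) {
  if (!is.finite(temperature) || temperature <= 0)
    stop_scad("temperature must be > 0")
  if (!is.finite(density) || density <= 0) stop_scad("density must be > 0")
  if (y2_solute < 0 || y2_solute > 1)
    stop_scad("y2_solute must lie in [0, 1]")
  y1 <- 1 - y2_solute
  if (abs(y1 + y2_solute - 1) > 1e-12)
    stop_scad("mass fractions must sum to 1 within 1e-12")
  structure(list(temperature = temperature, pressure = pressure,
                 density = density, y1_solvent = y1, y2_solute = y2_solute),
            class = "fluid_state")
}

## ---- Peng-Robinson equation of state ----------------------------------

# Dimensionless omega constants of the Peng-Robinson cubic, to full
# precision so that the critical isotherm has a clean triple root:
#   Omega_a = 0.45723552892138218938
#   Omega_b = 0.07779607390388846832
.PR_OMEGA_A <- 0.45723552892138218938
.PR_OMEGA_B <- 0.07779607390388846832

# Cubic in compressibility Z:
#   Z^3 - (1 - B) Z^2 + (A - 3 B^2 - 2 B) Z - (A B - B^2 - B^3) = 0
pr_ab <- function(T, p, params) {
  Tc <- params$critical_temperature
  pc <- params$critical_pressure
  w <- params$acentric_factor
  a <- .PR_OMEGA_A * .R_GAS^2 * Tc^2 / pc
  b <- .PR_OMEGA_B * .R_GAS * Tc / pc
  kappa <- 0.37464 + 1.54226 * w - 0.26992 * w^2
  alpha <- (1 + kappa * (1 - sqrt(T / Tc)))^2
  list(a_alpha = a * alpha, b = b,
       A = a * alpha * p / (.R_GAS * T)^2,
       B = b * p / (.R_GAS * T))
}

pr_pressure <- function(v, T, a_alpha, b) {
  .R_GAS * T / (v - b) - a_alpha / (v^2 + 2 * b * v - b^2)
}

# ln(fugacity coefficient) for a root Z; used for root selection below Tc.
pr_ln_phi <- function(Z, A, B) {
  s2 <- sqrt(2)
  Z - 1 - log(Z - B) -
    A / (2 * s2 * B) * log((Z + (1 + s2) * B) / (Z + (1 - s2) * B))
}

pr_compressibility <- function(T, p, params) {
  ab <- pr_ab(T, p, params)
  A <- ab$A
  B <- ab$B
  cf <- c(-(A * B - B^2 - B^3), A - 3 * B^2 - 2 * B, -(1 - B), 1)
  rts <- polyroot(cf)
  scale <- max(Mod(rts))
  real <- Re(rts[abs(Im(rts)) < 1e-6 * scale])
  real <- real[real > B]
  if (length(real) == 0L) {
    # fall back: accept the least-complex root of a near-degenerate cluster
    k <- which.min(abs(Im(rts)))
    if (abs(Im(rts[k])) < 1e-3 * scale && Re(rts[k]) > B) {
      real <- Re(rts[k])
    } else {
      stop_scad(sprintf(
        "Peng-Robinson EOS has no physical root at T = %g K, p = %g Pa", T, p),
        class = "scad_domain_error")
    }
  }
  Z <- if (T > params$critical_temperature || length(real) == 1L) {
    # supercritical isotherm: single physical root (pick the largest of a
    # numerically split near-triple cluster at the critical point itself)
    if (T > params$critical_temperature) real[which.max(real)] else real
  } else {
    # below Tc both vapour and liquid roots can occur; take the root with
    # the lower Gibbs energy (smaller fugacity coefficient)
    cand <- c(min(real), max(real))
    cand[which.min(vapply(cand, pr_ln_phi, numeric(1), A = A, B = B))]
  }
  if (T <= params$critical_temperature && length(real) > 1L) {
    # mean of a near-degenerate cluster at/near the critical point
    if (diff(range(real)) < 1e-3) Z <- mean(real)
  }
  # Newton polish on the cubic for a machine-accurate root
  for (it in 1:3) {
    fz <- ((Z + cf[3]) * Z + cf[2]) * Z + cf[1]
    dfz <- (3 * Z + 2 * cf[3]) * Z + cf[2]
    if (abs(dfz) < 1e-14) break
    step <- fz / dfz
    if (!is.finite(step) || abs(step) > 0.5) break
    Z <- Z - step
  }
  list(Z = Z, A = A, B = B, a_alpha = ab$a_alpha, b = ab$b)
}

#' CO2 density from the Peng-Robinson equation of state
#'
#' Solves the Peng-Robinson cubic for the compressibility factor and returns
#' the mass density of the selected root.  Above the critical temperature the
#' single physical root is taken; below it the root with the lower Gibbs
#' energy (fugacity) is selected, so the function is total over the whole
#' (T, p) plane even though production runs stay supercritical.
#'
#' The returned molar volume reproduces the input pressure through the EOS to
#' a relative residual below 1e-10 (checked internally).
#'
#' @param T Temperature, K (vectorised).
#' @param p Pressure, Pa (vectorised).
#' @param params [substance_parameters()]; defaults to [co2_parameters()].
#'
#' @return Density, kg/m^3.
#' @examples
#' co2_density(323, 14e6)          # supercritical CO2, ~626 kg/m^3
#' co2_density(313, 1e5)           # near ideal-gas, ~1.7 kg/m^3
#' @export
co2_density <- function(T, p, params = co2_parameters()) {
  n <- max(length(T), length(p))
  T <- rep_len(T, n)
  p <- rep_len(p, n)
  vapply(seq_len(n), function(i) {
    if (!is.finite(T[i]) || T[i] <= 0 || !is.finite(p[i]) || p[i] <= 0)
      stop_scad("T and p must be positive and finite")
    sol <- pr_compressibility(T[i], p[i], params)
    v <- sol$Z * .R_GAS * T[i] / p[i]
    if (v <= sol$b)
      stop_scad(sprintf("no physical Peng-Robinson root at T = %g K, p = %g Pa",
                        T[i], p[i]), class = "scad_domain_error")
    p_back <- pr_pressure(v, T[i], sol$a_alpha, sol$b)
    # at the critical point dp/dv = 0, so the pressure residual is benign;
    # elsewhere require machine-level closure
    if (abs(p_back / p[i] - 1) > 1e-8)
      stop_scad(sprintf(
        "Peng-Robinson root failed the pressure residual check at T = %g K, p = %g Pa",
        T[i], p[i]), class = "scad_domain_error")
    params$molar_mass / v
  }, numeric(1))
}

## ---- He-Yu molecular diffusivity --------------------------------------

# Constants of the He-Yu correlation for infinite-dilution binary diffusion
# in supercritical solvents:
#   D12 [cm^2/s] = alpha * 1e-5 * sqrt(T / M2) * exp(-0.3887 / (Vr - 0.23))
#   alpha = 14.882 + 5.908e-3 * k + 2.0821e-6 * k^2,  k = Tc1 Vc1 / M1
# with T in K, M in g/mol, Vc1 in cm^3/mol and Vr = V1/Vc1 the reduced molar
# volume of the solvent.  The correlation is singular at Vr = 0.23.
.HEYU_PREF <- 1e-5
.HEYU_EXP <- 0.3887
.HEYU_VR0 <- 0.23
.HEYU_A0 <- 14.882
.HEYU_A1 <- 5.908e-3
.HEYU_A2 <- 2.0821e-6

#' Molecular diffusivity of a dilute solute in supercritical CO2 (He-Yu)
#'
#' Evaluates the He-Yu correlation for the infinite-dilution binary
#' diffusion coefficient of a solute in a dense solvent.  The result
#' increases with temperature at fixed solvent density and decreases with
#' solvent density at fixed temperature, and scales as the inverse square
#' root of the solute molar mass.
#'
#' @param T Temperature, K.
#' @param solvent_density Solvent density, kg/m^3.
#' @param solute,solvent [substance_parameters()] of the two components;
#'   the solvent must carry a `critical_molar_volume`.
#'
#' @return Diffusion coefficient, m^2/s.
#' @examples
#' molecular_diffusivity(323, co2_density(323, 14e6))  # ~1.2e-8 m^2/s
#' @export
molecular_diffusivity <- function(T, solvent_density,
                                  solute = ibuprofen_parameters(),
                                  solvent = co2_parameters()) {
  if (!is.finite(T) || T <= 0) stop_scad("T must be > 0")
  if (!is.finite(solvent_density) || solvent_density <= 0)
    stop_scad("solvent_density must be > 0")
  Vc1 <- solvent$critical_molar_volume
  if (!is.finite(Vc1))
    stop_scad("solvent must carry a finite critical_molar_volume")
  M1 <- solvent$molar_mass * 1e3   # g/mol
  M2 <- solute$molar_mass * 1e3    # g/mol
  Vc1_cm3 <- Vc1 * 1e6             # cm^3/mol
  V1 <- M1 / (solvent_density * 1e-3)   # cm^3/mol
  Vr <- V1 / Vc1_cm3
  if (Vr <= .HEYU_VR0)
    stop_scad(sprintf(
      "reduced solvent volume %.4f is at or below the He-Yu singularity (%.2f)",
      Vr, .HEYU_VR0), class = "scad_domain_error")
  k <- solvent$critical_temperature * Vc1_cm3 / M1
  alpha <- .HEYU_A0 + .HEYU_A1 * k + .HEYU_A2 * k^2
  d_cm2 <- alpha * .HEYU_PREF * sqrt(T / M2) * exp(-.HEYU_EXP / (Vr - .HEYU_VR0))
  d_cm2 * 1e-4
}
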