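---
title: "Modelling supercritical drug impregnation of aerogel monoliths"
author: "scadsorb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling supercritical drug impregnation of aerogel monoliths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scadsorb)
```

## The process and the model

Supercritical adsorption (impregnation) loads an active pharmaceutical
ingredient (API) dissolved in supercritical CO~2~ into a porous carrier.
Here the system is RS-ibuprofen and a cylindrical silica-aerogel monolith
(Ø10 mm × 50 mm, specific surface ~975 m²/g, pore volume 1.45 cm³/g)
standing in a 60 mL batch reactor.  Excess solid drug in a permeable
envelope keeps the fluid near saturation; the solute diffuses into the
monolith and adsorbs on its internal surface.  Loading kinetics are
measured destructively: one run per time point (1--5 h), duplicated, at
temperatures 313--333 K and pressures 120--200 bar.

`scadsorb` implements a reduced continuum model of this process and the
calibration workflow that extracts its two empirical material functions
from loading-kinetics curves.

### Species balances

Two regions are distinguished: the free reactor volume $\Theta$ and the
porous body $\Omega$.  The operating reactor is unstirred and isothermal
at the wall temperature, so the momentum and energy balances reduce to
$\vec v \equiv 0$ and $T \equiv T_w$; the CO~2~ density $\rho$ is then a
per-run constant evaluated from the Peng--Robinson equation of state.
The solute mass fraction $Y_2$ obeys

$$\partial_t(\rho Y_2) = \nabla\!\cdot(\rho D_\Theta \nabla Y_2)
  \quad\text{in } \Theta,$$
$$\varepsilon\,\partial_t(\rho Y_2) =
  \nabla\!\cdot(\rho D_\Omega \nabla Y_2) + \varepsilon\rho S_q
  \quad\text{in } \Omega,$$

with $Y_2 = Y_s$ (the solubility) on the source surface, zero flux at the
walls, continuity of $Y_2$ and flux across the $\Theta/\Omega$ interface,
and $Y_2 = q = 0$ initially.  The porosity $\varepsilon$ multiplies the
storage and exchange terms so that pore-fluid mass is $\rho\varepsilon V
Y_2$, consistent with the equilibrium relation below; the flux keeps the
lumped effective coefficient $D_\Omega$.  One consequence worth noting:
the apparent diffusivity of the porous balance is $D_\Omega/\varepsilon$,
and the Fourier number used in the analytic benchmark is
$(D_\Omega/\varepsilon)\,t/R^2$.

### Adsorption kinetics and equilibrium

Adsorption follows single-site Langmuir kinetics without desorption,

$$S_q = -K\,Y_2\,(q_\infty - q), \qquad \dot q = -S_q,$$

an exactly antisymmetric sink/gain pair.  The rate constant comes from the
kinetic-theory impingement flux,

$$K = \frac{p\,S\,M_a}{2\,q_\infty M_{mix}\sqrt{2\pi M_a R T}},$$

a correlation typeset ambiguously in the literature; the alternative
reading (squared solute molar mass, no factor 2) is available through
`eq3_variant`.  Either way $K \sim 10^{11}\,$s⁻¹ at process conditions:
adsorption is locally instantaneous and the uptake is entirely
diffusion-limited, so simulated kinetics are insensitive to the variant.

The adsorption limit converts the equilibrium loading percentage
$A_\infty$ (adsorbed *plus* pore-dissolved solute over total
solute-plus-aerogel mass) to a per-mixture-mass capacity:

$$q_\infty = \frac{A_\infty\,\rho_{aer}}{(100 - A_\infty)\,\rho\,\varepsilon}
  - Y_p .$$

The two empirical material functions --- the point of the calibration ---
are

$$D_\Omega(T, p) = (a_1 p + a_2)\,e^{-(a_3 p + a_4)/T}, \qquad
  A_\infty(T) = (b_1 T + b_2)\cdot 100,$$

with $p$ in bar and $T$ in K at this interface (the bundled reference
coefficients only make numerical sense with pressure in bar; everything
else in the package is strictly SI).  $A_\infty$ is temperature-only:
pressure was observed to affect the maximum loading only slightly, and the
model follows that.  By construction the long-time plateau of a simulation
equals $A_\infty(T)$ exactly whenever the source concentration equals the
$Y_p$ used in $q_\infty$ --- the equilibrium-closure test exploits this.

### Treatment of the free volume

The free volume admits two treatments (`scad_control(theta_model = ...)`):

* `"well_mixed"` (default): $\Theta$ is a saturated bath and the exposed
  monolith faces carry $Y_2 = Y_s$.  Rationale: with molecular
  diffusivity ~10⁻⁸ m²/s, a purely quiescent free volume would deliver
  the ~1.7 g of solute needed for saturation over weeks, whereas the
  experiments saturate within about five hours --- in the real reactor
  natural convection (driven by solute-induced density gradients)
  homogenises the free volume quickly.  The bath assumption replaces that
  unresolved convection.
* `"diffusive"`: the free volume is discretised and fed by a Dirichlet
  source patch on the top face, with molecular diffusion only.  This
  mirrors a fully quiescent reactor; it is retained for verification
  (maximum principle, conservation) and for sensitivity studies, and it
  is strongly transport-limited by design.

This is the package's main declared deviation from a full CFD treatment
(no Navier--Stokes, no buoyancy, no energy equation).

## Numerical scheme

The solver uses cell-centred finite volumes on an axisymmetric $(r, z)$
grid whose edges conform exactly to the monolith radius and length
(uniform spacing within each sub-block; $z = 0$ at the reactor bottom).
Interface conductances combine the two half-cell resistances in series
(harmonic mean), which enforces flux continuity across the
$\Theta/\Omega$ boundary.  Time integration is operator-split:

1. a $\theta$-scheme diffusion step (backward Euler by default,
   Crank--Nicolson or stability-bounded forward Euler by option); the
   iteration operator is factorised once per run (dense propagator below
   1500 unknowns, sparse Cholesky above);
2. pointwise integration of the adsorption exchange using the closed-form
   solution of the coupled pair $(\dot q = K Y_2 (q_\infty - q),\;
   \dot Y_2 = -\dot q)$, whose sum $c = Y_2 + q$ is an exact invariant.
   With $K\,Y_2\,\Delta t \sim 10^{12}$ this exchange is very stiff; the
   closed form is unconditionally stable, positivity- and
   bound-preserving, and transfers mass between phases exactly.

The discrete scheme is conservative by construction: at every step the
cumulative release through the source boundary equals the change in fluid
plus adsorbed inventory up to round-off (observed $\lesssim 10^{-14}$
relative; the contract is 0.1%).  Spatial accuracy is first order or
better in the presence of the sharp adsorption front (observed order
≈ 1.1 on nested grids); against the Bessel-series solution for radial
diffusion into a cylinder the solver is within 1% of fractional uptake
down to Fo = 0.01 on a 48-cell radial grid with Crank--Nicolson stepping.

Step-size policy for `dt = "auto"`: 0.4× the explicit
positivity/stability bound for the explicit scheme; `t_end`/240 capped at
900 s for the implicit schemes.  The default production grid is 8 × 32
cells over the reactor (3 × 19 inside the monolith) --- deliberately
coarse, because the calibration loop runs thousands of forward
simulations and its closed-loop consistency does not depend on grid
resolution (generator and fitter share the discretisation).

Degenerate inputs are handled explicitly: `ys = 0` (null forcing) keeps
all fields identically zero; `k_rate = 0` disables adsorption; a
non-positive diffusivity prefactor $a_1 p + a_2$, a loading target below
the solubility capacity ($q_\infty \le 0$), or an $A_\infty$ outside
(0, 100) raise domain errors; an unstable explicit step is reduced
automatically with a warning; non-finite fields abort with a diagnostic.

## Property layer

* **CO~2~ density**: Peng--Robinson cubic, solved via `polyroot` with a
  Newton polish; every returned root reproduces the input pressure to
  better than 10⁻¹⁰ relative.  Above $T_c$ the single real root is taken;
  below $T_c$ the root with the lower fugacity (Gibbs energy) --- the
  policy is total even though production runs stay supercritical.  The
  dimensionless constants are carried at full precision
  ($\Omega_a = 0.4572355289\ldots$, $\Omega_b = 0.0777960739\ldots$) so
  that the critical isotherm has a clean triple root and the critical
  density matches the closed form $Z_c = (1-\Omega_b)/3 \approx 0.3074$;
  the textbook-rounded constants would shift the critical root by several
  percent.  CO~2~: $T_c$ = 304.13 K, $p_c$ = 7.377 MPa, ω = 0.2239,
  M = 0.04401 kg/mol.
* **Molecular diffusivity**: the He--Yu correlation
  $D = \alpha\,10^{-5}\sqrt{T/M_2}\,\exp(-0.3887/(V_r - 0.23))$ cm²/s,
  $\alpha = 14.882 + 5.908\times10^{-3}k + 2.0821\times10^{-6}k^2$,
  $k = T_{c1}V_{c1}/M_1$ (g/mol, cm³/mol units internally; SI at the
  interface).  Singular at $V_r = 0.23$; queries at or below it are
  domain errors.  For ibuprofen in CO~2~ at 323 K, 140 bar this gives
  1.16 × 10⁻⁸ m²/s.
* **Solubility**: tabulated, exact-entry lookup with bilinear
  interpolation inside the rectangular hull (`pracma::interp2`);
  extrapolation is an error unless explicitly clamped.  The bundled table
  is a clearly-labelled synthetic placeholder (see below).

## Calibration

Per condition, the discrepancy objective is the RMS *relative* deviation
between simulated and observed loadings at the observation times,
replicates averaged first (chosen to match the relative-error metric used
for validation; among discrepancy norms this is the package's own choice).
The effective diffusivity is found by golden-section search in
$\log_{10} D_\Omega$ over a default bracket of 10⁻¹⁰--10⁻⁶ m²/s
(termination width 2 × 10⁻⁴, i.e. ~0.05% in $D$); diffusivities spread
over orders of magnitude, hence the log scale.  The plateau $A_\infty$ is
taken as the largest-time loading when the curve has flattened to below
1%/h, and otherwise estimated by profile minimisation: an outer
golden-section search over $A_\infty$ (termination 0.02 percentage
points) scoring each trial value by its best-fitting $D_\Omega$.  An
8-point deterministic pre-scan brackets the basin first, because over a
wide plateau bracket the profile need not be unimodal.  Identifiability
caveat: when the data stop far short of saturation, the early uptake
depends on $D_\Omega$ and $q_\infty$ mainly through their product and the
plateau is weakly identified; the fit warns when the profile is nearly
flat.

Across conditions, $(a_1\ldots a_4)$ are fitted by least squares on
$\log D_\Omega$: a moment-based initial guess (per-pressure van 't
Hoff-type slopes of $\ln D$ vs $1/T$, then linear regressions in $p$) is
refined by BFGS from a deterministic 3×3×3×3 lattice of scale
perturbations --- no randomness anywhere in the fit.  $(b_1, b_2)$ come
from ordinary least squares of $A_\infty/100$ on $T$, pooled over
pressures.  Rank-deficient designs (fewer than four distinct conditions,
a single temperature or pressure) are rejected with explicit messages;
identical diffusivities return the degenerate pressure-free fit with a
warning.  The held-out condition (323 K, 140 bar) is excluded from all
fitting and reserved for validation via the mean relative error.

## Synthetic data

`generate_kinetics()` emulates the experiment design: loadings at
1--5 h, duplicate replicates, conditions spanning
{323, 333} K × {120, 160, 200} bar for fitting plus (323 K, 140 bar) for
validation (313 K conditions are generable but excluded by default: there
the solute is in its solid state and the loading data are not comparable).
Noise is multiplicative lognormal per observation with unit mean and
default coefficient of variation 0.02 --- replicate scatter of positive
loadings is roughly proportional.  A fixed seed reproduces the dataset
byte for byte, and the caller's RNG stream is left untouched.

What the generator does *not* emulate: depressurisation/precipitation
artifacts, the HPLC measurement chain, pressurisation transients,
condition-dependent error structure, or any model-misspecification error.
Passing closed-loop tests therefore demonstrates the *internal*
consistency of solver and calibration (an "inverse crime" by design), not
agreement with independent measurements --- for that, users must supply
their own kinetics CSV and solubility table.

The bundled solubility table is synthetic.  Its values (2.2--4.8% by
mass) carry the qualitative structure reported for ibuprofen/scCO~2~
(increasing with pressure, increasing with temperature at 140--200 bar,
nearly temperature-independent at 120 bar) and their magnitude --- the
upper range of published solubilities --- is set so that the forward model
saturates the monolith within the ~5 h observed experimentally.  Lower
placeholder values would slow the simulated uptake several-fold and make
the plateau unidentifiable from 1--5 h samples.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `a1, a2, a3, a4` | 0.0125, −0.74, 7.50, 4800 | (m²/s)/bar, m²/s, K/bar, K | effective-diffusivity correlation |
| `b1, b2` | 0.007, −1.802 | 1/K, -- | maximum-loading line |
| `specific_surface` | 9.75 × 10⁵ | m²/kg | aerogel internal surface |
| `specific_pore_volume` | 1.45 × 10⁻³ | m³/kg | aerogel pore volume |
| `skeletal_density` | 2200 | kg/m³ | silica skeleton; gives ρ~aer~ ≈ 525 kg/m³, ε ≈ 0.761 |
| `reactor_volume` | 60 × 10⁻⁶ | m³ | working volume |
| `reactor_radius` | 0.015 | m | sets the reactor height (~85 mm) |
| `source_area` | full top face | m² | saturated source patch (diffusive mode) |
| `noise_cv` | 0.02 | -- | replicate scatter of the generator |
| `nr, nz` | 8, 32 | -- | grid cells (radial × axial) |

The envelope density and porosity are not independent: they are derived
from the pore volume and skeletal density and must satisfy
$\rho_{aer}(v_{pore} + 1/\rho_{skel}) = 1$ when overridden.

## Worked example

```{r example, eval = FALSE}
scad_props(323, 140)                     # derived property chain
g   <- build_grid(reactor_geometry(), 8, 32)
sim <- simulate_adsorption(323, 140, aerogel_sample(),
                           default_coefficients(),
                           default_solubility_table(), g, t_end = 5 * 3600)
tail(sim$loading_curve)                  # 45.899 % at 5 h: at the plateau

data <- generate_kinetics(fit_conditions(), noise_cv = 0, grid = g)
fit  <- fit_kinetics(data, grid = g, exclude = NULL)
fit$coefficients                         # recovers the defaults within 1 %
```

## Limitations

* No convection is resolved; the well-mixed bath stands in for it, and
  the diffusive mode bounds the opposite extreme.  Geometries in which
  the free volume is a genuine resistance need an external CFD treatment.
* Single-site Langmuir kinetics without desorption; no Dubinin--Astakhov
  or multicomponent potential isotherms.
* Mixture properties equal pure-CO~2~ properties; the solute enters only
  through transport and adsorption, so the model is restricted to dilute
  solutions.
* The maximum loading is temperature-only; a pressure dependence, if
  present, is absorbed into the per-condition scatter.
* Depressurisation (and the precipitation it causes) is outside the model
  horizon: simulated loadings describe the state before pressure release.
* The bundled solubility and the generated kinetics are synthetic;
  quantitative conclusions require user-supplied measurements.

## Problem sizes used by the test suite

The suite runs the closed loop at the 8 × 32 production grid (57 monolith
cells), the analytic-benchmark comparisons on a 48-cell radial grid, grid
convergence on 6 × 17 / 12 × 34 / 24 × 68 grids, equilibrium closure to
3 × 10⁵ s horizons, and the stochastic-recovery study over 20 seeds at
each of the six fit conditions --- sizes chosen to keep the full suite in
the minutes range while exercising every code path.
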