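## Reduced-order finite-volume solver for the coupled species balances:
## diffusive transport of the solute from the saturated source through the
## free reactor volume (Theta) into the porous monolith (Omega), with the
## Langmuir-kinetics adsorption sink.  Quiescent, isothermal, constant
## density: the momentum and energy balances reduce to v = 0 and T = Twall,
## so the CO2 density is evaluated once per run from the equation of state.

#' Solver control settings
#'
#' @param theta_model Treatment of the free reactor volume.
#'   `"well_mixed"` (default): the free volume is a saturated, well-mixed
#'   bath at the solubility value Ys, imposed as a Dirichlet condition on
#'   the exposed monolith faces; only the monolith block is discretised.
#'   This reflects that in the unstirred reactor natural convection (not
#'   modelled explicitly) homogenises the free volume much faster than the
#'   monolith fills.  `"diffusive"`: the free volume is resolved and solute
#'   spreads from the source patch by molecular diffusion only; supply to
#'   the monolith is then strongly transport-limited.
#' @param scheme Time integration of the diffusion operator: `"implicit"`
#'   (backward Euler, default), `"cn"` (Crank-Nicolson), `"explicit"`
#'   (forward Euler, stability-bounded).
#' @param bath_faces Monolith faces exposed to the bath in `"well_mixed"`
#'   mode: subset of `c("lateral", "top")`.
#' @param d_omega,d_theta,a_inf,q_inf,k_rate,ys Optional overrides of the
#'   derived physical inputs (effective diffusivity m^2/s, molecular
#'   diffusivity m^2/s, maximum loading %, adsorption limit kg/kg, rate
#'   constant 1/s, boundary/source mass fraction kg/kg).  `k_rate = 0`
#'   switches adsorption off; `ys = 0` switches the source off.
#' @param eq3_variant Rate-constant variant, see
#'   [adsorption_rate_constant()].
#' @param n_snapshots Number of stored field snapshots (the loading curve is
#'   recorded at every step regardless).
#' @param safety Fraction of the explicit stability bound used by
#'   `dt = "auto"` with the explicit scheme (default 0.4).
#' @param max_cells_dense Below this number of unknowns the stepping
#'   operator is precomputed as a dense propagator; above it, a sparse
#'   Cholesky factorisation is reused at every step.
#' @return A list of class `scad_control`.
#' @export
scad_control <- function(theta_model = c("well_mixed", "diffusive"),
                         scheme = c("implicit", "cn", "explicit"),
                         bath_faces = c("lateral", "top"),
                         d_omega = NULL, d_theta = NULL, a_inf = NULL,
                         q_inf = NULL, k_rate = NULL, ys = NULL,
                         eq3_variant = "canonical",
                         n_snapshots = 25L,
                         safety = 0.4,
                         max_cells_dense = 1500L) {
  theta_model <- match.arg(theta_model)
  scheme <- match.arg(scheme)
  bath_faces <- match.arg(bath_faces, c("lateral", "top"), several.ok = TRUE)
  structure(list(theta_model = theta_model, scheme = scheme,
                 bath_faces = bath_faces, d_omega = d_omega,
                 d_theta = d_theta, a_inf = a_inf, q_inf = q_inf,
                 k_rate = k_rate, ys = ys, eq3_variant = eq3_variant,
                 n_snapshots = as.integer(n_snapshots), safety = safety,
                 max_cells_dense = as.integer(max_cells_dense)),
            class = "scad_control")
}

# Assemble the conservative FV system on the unknown cells.
# Returns capacity vector C (kg of mixture per unit mass fraction), the
# symmetric conductance operator M (kg/s per unit mass-fraction difference,
# including the Dirichlet diagonal), the Dirichlet conductance vector gvec,
# and index bookkeeping.
assemble_system <- function(grid, control, rho, d_theta, d_omega, eps) {
  nr <- grid$nr; nz <- grid$nz
  nr_in <- grid$nr_in; nz_in <- grid$nz_in
  re <- grid$r_edges; ze <- grid$z_edges
  rc <- grid$r_centers; zc <- grid$z_centers
  dz <- diff(ze)
  well_mixed <- control$theta_model == "well_mixed"

  if (well_mixed) {
    keep <- which(grid$region == "omega")
  } else {
    keep <- seq_along(grid$volume)
  }
  pos <- match(seq_along(grid$volume), keep)   # full index -> unknown index
  n <- length(keep)
  is_omega <- grid$region[keep] == "omega"
  phi <- ifelse(is_omega, eps, 1)
  Cap <- rho * phi * grid$volume[keep]
  Dcell <- ifelse(grid$region == "omega", d_omega, d_theta)

  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  gvec <- numeric(n)

  kof <- function(i, j) (j - 1L) * nr + i
  add_face <- function(ka, kb, area, da, db) {
    ua <- pos[ka]; ub <- pos[kb]
    if (is.na(ua) || is.na(ub)) return(invisible())
    g <- area / (da / (rho * Dcell[ka]) + db / (rho * Dcell[kb]))
    ii <<- c(ii, ua, ub); jj <<- c(jj, ub, ua); gg <<- c(gg, g, g)
    invisible()
  }

  # radial interior faces
  for (j in seq_len(nz)) {
    for (i in seq_len(nr - 1L)) {
      ka <- kof(i, j); kb <- kof(i + 1L, j)
      if (well_mixed && (is.na(pos[ka]) || is.na(pos[kb]))) next
      area <- 2 * pi * re[i + 1L] * dz[j]
      add_face(ka, kb, area, re[i + 1L] - rc[i], rc[i + 1L] - re[i + 1L])
    }
  }
  # axial interior faces
  for (j in seq_len(nz - 1L)) {
    for (i in seq_len(nr)) {
      ka <- kof(i, j); kb <- kof(i, j + 1L)
      if (well_mixed && (is.na(pos[ka]) || is.na(pos[kb]))) next
      area <- grid$ring_area[i]
      add_face(ka, kb, area, ze[j + 1L] - zc[j], zc[j + 1L] - ze[j + 1L])
    }
  }

  if (well_mixed) {
    # Dirichlet bath on the exposed monolith faces
    if ("lateral" %in% control$bath_faces) {
      r_m <- re[nr_in + 1L]
      d_half <- r_m - rc[nr_in]
      for (j in seq_len(nz_in)) {
        u <- pos[kof(nr_in, j)]
        gvec[u] <- gvec[u] + (2 * pi * r_m * dz[j]) / (d_half / (rho * d_omega))
      }
    }
    if ("top" %in% control$bath_faces) {
      d_half <- ze[nz_in + 1L] - zc[nz_in]
      for (i in seq_len(nr_in)) {
        u <- pos[kof(i, nz_in)]
        gvec[u] <- gvec[u] + grid$ring_area[i] / (d_half / (rho * d_omega))
      }
    }
  } else {
    # Dirichlet source patch on the reactor top face: include whole rings
    # from the axis outward until the source area is covered
    cum <- cumsum(grid$ring_area)
    n_src <- max(1L, sum(cum <= grid$geometry$source_area * (1 + 1e-9)))
    d_half <- ze[nz + 1L] - zc[nz]
    for (i in seq_len(n_src)) {
      u <- pos[kof(i, nz)]
      gvec[u] <- gvec[u] + grid$ring_area[i] / (d_half / (rho * d_theta))
    }
  }

  M <- Matrix::sparseMatrix(i = ii, j = jj, x = -gg, dims = c(n, n))
  diag_terms <- Matrix::rowSums(Matrix::sparseMatrix(
    i = ii, j = jj, x = gg, dims = c(n, n))) + gvec
  M <- M + Matrix::Diagonal(n, diag_terms)

  list(keep = keep, n = n, is_omega = is_omega, Cap = Cap, M = M,
       gvec = gvec, row_conductance = diag_terms)
}

#' Simulate the supercritical adsorption run
#'
#' Time-marches the coupled solute species balances: Fickian diffusion with
#' the molecular diffusivity in the free reactor volume and the effective
#' diffusivity in the monolith, plus the Langmuir-kinetics adsorption
#' exchange in the monolith.  Operator splitting is used: a theta-scheme
#' finite-volume diffusion step followed by pointwise exact integration of
#' the (stiff) adsorption exchange.  All physical inputs are evaluated once
#' per run (isothermal, constant density); see [scad_control()] for
#' overrides and solver switches.
#'
#' The discrete scheme is conservative by construction: at every step the
#' cumulative solute release through the source boundary equals the change
#' of fluid plus adsorbed inventory up to round-off, and the reported
#' conservation error must stay below 0.1 percent of the released mass.
#'
#' @param T_K Temperature, K.
#' @param p_bar Pressure, bar.
#' @param sample An [aerogel_sample()].
#' @param coeffs A [coefficient_set()].
#' @param soltab A [solubility_table()].
#' @param grid A [build_grid()] grid.
#' @param t_end End time, s.
#' @param dt Time step, s, or `"auto"`.
#' @param control A [scad_control()].
#' @param solute,solvent [substance_parameters()].
#'
#' @return An object of class `scad_simulation`: snapshot fields `y2_field`
#'   (cells x snapshots, with free-volume cells held at the bath value in
#'   well-mixed mode), `q_field` (monolith cells x snapshots), the
#'   per-step `loading_curve` (time_s, time_h, loading_pct), a
#'   `conservation` table, and the derived physical parameters in `params`.
#' @examples
#' \donttest{
#' g <- build_grid(reactor_geometry(), nr = 8, nz = 32)
#' sim <- simulate_adsorption(323, 140, aerogel_sample(),
#'                            default_coefficients(),
#'                            default_solubility_table(), g,
#'                            t_end = 5 * 3600)
#' tail(sim$loading_curve)
#' }
#' @export
simulate_adsorption <- function(T_K, p_bar, sample, coeffs, soltab, grid,
                                t_end, dt = "auto",
                                control = scad_control(),
                                solute = ibuprofen_parameters(),
                                solvent = co2_parameters()) {
  stopifnot(inherits(grid, "scad_grid"), inherits(sample, "aerogel_sample"))
  if (t_end <= 0) stop_scad("t_end must be > 0")
  p_pa <- bar_to_pa(p_bar)
  eps <- sample$porosity

  rho <- co2_density(T_K, p_pa, solvent)
  ys <- control$ys %||% solubility(T_K, p_pa, soltab)
  d_theta <- control$d_theta %||%
    molecular_diffusivity(T_K, rho, solute, solvent)
  d_omega <- control$d_omega %||% effective_diffusivity(T_K, p_bar, coeffs)
  a_inf <- control$a_inf %||% max_loading(T_K, coeffs)
  q_inf <- control$q_inf %||% adsorption_limit(a_inf, sample, rho, ys)
  k_rate <- control$k_rate %||%
    adsorption_rate_constant(T_K, p_pa, sample, solute, solvent, q_inf,
                             variant = control$eq3_variant)

  sys <- assemble_system(grid, control, rho, d_theta, d_omega, eps)
  n <- sys$n

  # time step
  stab <- min(sys$Cap / pmax(sys$row_conductance, .Machine$double.xmin))
  if (identical(dt, "auto")) {
    dt <- if (control$scheme == "explicit") control$safety * stab
          else min(t_end / 240, 900)
  }
  if (control$scheme == "explicit" && dt > control$safety * stab) {
    warning(sprintf(
      "explicit step %.3g s exceeds the diffusion stability limit; reduced to %.3g s",
      dt, control$safety * stab))
    dt <- control$safety * stab
  }
  n_steps <- max(1L, ceiling(t_end / dt))
  dt <- t_end / n_steps

  theta <- switch(control$scheme, implicit = 1, cn = 0.5, explicit = 0)
  Cdt <- sys$Cap / dt
  b_const <- sys$gvec * ys
  use_dense <- n <= control$max_cells_dense
  if (theta > 0) {
    A1 <- Matrix::Diagonal(n, Cdt) + theta * sys$M
    if (use_dense) {
      A1d <- as.matrix(A1)
      Pmat <- solve(A1d, diag(Cdt, n) - (1 - theta) * as.matrix(sys$M))
      svec <- solve(A1d, b_const)
    } else {
      fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A1), "CsparseMatrix"))
    }
  }

  y <- numeric(n)
  q <- numeric(sum(sys$is_omega))
  omega_idx <- which(sys$is_omega)
  cap_omega <- sys$Cap[omega_idx]

  # outputs
  snap_steps <- sort(unique(c(
    round(seq(0, n_steps, length.out = max(2L, control$n_snapshots))),
    n_steps)))
  times <- numeric(0)
  y_snap <- list(); q_snap <- list()
  loading <- numeric(n_steps + 1L)
  cons_rel <- numeric(n_steps + 1L)
  released <- 0
  inv0 <- sum(sys$Cap * y) + sum(cap_omega * q)

  m_aero <- sample$envelope_density * sum(grid$volume[sys$keep[omega_idx]])
  load_of <- function(yv, qv) {
    m_ibu <- sum(cap_omega * (yv[omega_idx] + qv))
    100 * m_ibu / (m_ibu + m_aero)
  }
  loading[1L] <- load_of(y, q)

  store <- function(step) {
    times <<- c(times, step * dt)
    y_snap[[length(y_snap) + 1L]] <<- y
    q_snap[[length(q_snap) + 1L]] <<- q
  }
  if (0 %in% snap_steps) store(0L)

  for (step in seq_len(n_steps)) {
    y_old <- y
    if (theta > 0) {
      y <- if (use_dense) drop(Pmat %*% y + svec)
           else as.numeric(Matrix::solve(
             fac, Cdt * y - (1 - theta) * as.numeric(sys$M %*% y) + b_const))
    } else {
      y <- y + (b_const - as.numeric(sys$M %*% y)) / Cdt
    }
    ybar <- theta * y + (1 - theta) * y_old
    released <- released + sum(sys$gvec * (ys - ybar)) * dt

    if (k_rate > 0 && q_inf > 0) {
      upd <- adsorption_step(y[omega_idx], q, q_inf, k_rate, dt)
      y[omega_idx] <- upd$y2
      q <- upd$q
    }

    if (any(!is.finite(y)) || any(!is.finite(q)))
      stop_scad(sprintf(
        "non-finite field at t = %.4g s (step %d): y2 range [%g, %g], q range [%g, %g]",
        step * dt, step, suppressWarnings(min(y)), suppressWarnings(max(y)),
        suppressWarnings(min(q)), suppressWarnings(max(q))))

    loading[step + 1L] <- load_of(y, q)
    inv <- sum(sys$Cap * y) + sum(cap_omega * q) - inv0
    cons_rel[step + 1L] <- if (released > 0) (inv - released) / released else 0
    if (step %in% snap_steps) store(step)
  }

  t_all <- seq(0, t_end, by = dt)
  n_cells <- length(grid$volume)
  y_fields <- matrix(ys, nrow = n_cells, ncol = length(times))
  q_fields <- matrix(0, nrow = length(omega_idx), ncol = length(times))
  for (s in seq_along(times)) {
    col <- rep(if (control$theta_model == "well_mixed") ys else NA_real_,
               n_cells)
    col[sys$keep] <- y_snap[[s]]
    y_fields[, s] <- col
    q_fields[, s] <- q_snap[[s]]
  }

  structure(list(
    times = times,
    y2_field = y_fields,
    q_field = q_fields,
    omega_cells = sys$keep[omega_idx],
    loading_curve = data.frame(time_s = t_all, time_h = t_all / 3600,
                               loading_pct = loading),
    conservation = data.frame(time_s = t_all, rel_error = cons_rel),
    released = released,
    params = list(T_K = T_K, p_bar = p_bar, rho = rho, ys = ys,
                  d_theta = d_theta, d_omega = d_omega, a_inf = a_inf,
                  q_inf = q_inf, k_rate = k_rate, dt = dt,
                  n_steps = n_steps, eps = eps),
    grid = grid,
    sample = sample,
    control = control
  ), class = "scad_simulation")
}

#' @export
print.scad_simulation <- function(x, ...) {
  p <- x$params
  cat(sprintf("<scad_simulation> T = %g K, p = %g bar (%s, %s)\n",
              p$T_K, p$p_bar, x$control$theta_model, x$control$scheme))
  cat(sprintf("  rho = %.1f kg/m^3, Ys = %.4g, D_theta = %.3g, D_omega = %.3g m^2/s\n",
              p$rho, p$ys, p$d_theta, p$d_omega))
  cat(sprintf("  A_inf = %.1f %%, q_inf = %.3g kg/kg, K = %.3g\n",
              p$a_inf, p$q_inf, p$k_rate))
  cat(sprintf("  %d steps of %.3g s; final loading %.2f %% (max |cons. err| %.2g)\n",
              p$n_steps, p$dt, tail(x$loading_curve$loading_pct, 1L),
              max(abs(x$conservation$rel_error))))
  invisible(x)
}

#' Total loading of the monolith
#'
#' Loading in mass percent from the solute fields on the monolith cells:
#' \deqn{A = 100\, m_{ibu} / (m_{ibu} + m_{aero}),}
#' with the solute mass `m_ibu = sum(rho (y2 + q) eps V_cell)` over the
#' monolith cells (pore-dissolved plus adsorbed) and the aerogel mass
#' `m_aero = rho_aer V_monolith`.
#'
#' @param y2 Solute mass fraction on the monolith cells (or on all grid
#'   cells, in which case the monolith cells are extracted).
#' @param q Adsorption on the monolith cells, kg/kg.
#' @param grid A [build_grid()] grid.
#' @param sample An [aerogel_sample()].
#' @param co2_density CO2 density, kg/m^3.
#' @return Loading, mass percent.
#' @export
total_loading <- function(y2, q, grid, sample, co2_density) {
  om <- which(grid$region == "omega")
  if (length(y2) == length(grid$volume)) y2 <- y2[om]
  if (length(y2) != length(om) || length(q) != length(om))
    stop_scad("y2 and q must be defined on the monolith cells")
  v <- grid$volume[om]
  m_ibu <- sum(co2_density * (y2 + q) * sample$porosity * v)
  m_aero <- sample$envelope_density * sum(v)
  100 * m_ibu / (m_ibu + m_aero)
}

#' Interpolate the simulated loading curve at given times
#'
#' @param sim A `scad_simulation`.
#' @param times_h Times in hours.
#' @return Loading, mass percent, linearly interpolated (constant beyond
#'   the simulated horizon).
#' @export
loading_at <- function(sim, times_h) {
  stopifnot(inherits(sim, "scad_simulation"))
  approx(sim$loading_curve$time_h, sim$loading_curve$loading_pct,
         xout = times_h, rule = 2)$y
}

#' Export field snapshots as a long-format data frame
#'
#' Columns: `time_s, r_m, z_m, region, y2, q` (q is `NA` outside the
#' monolith).
#'
#' @param sim A `scad_simulation`.
#' @return A data frame.
#' @export
as_field_data <- function(sim) {
  g <- sim$grid
  n_cells <- length(g$volume)
  out <- do.call(rbind, lapply(seq_along(sim$times), function(s) {
    q_full <- rep(NA_real_, n_cells)
    q_full[sim$omega_cells] <- sim$q_field[, s]
    data.frame(time_s = sim$times[s],
               r_m = g$r_centers[g$i_index],
               z_m = g$z_centers[g$j_index],
               region = g$region,
               y2 = sim$y2_field[, s],
               q = q_full)
  }))
  rownames(out) <- NULL
  out
}

#' Write simulation outputs as CSV
#'
#' `write_loading_csv()` writes the loading curve as `time_h,loading_pct`;
#' `write_fields_csv()` writes the long-format field snapshots of
#' [as_field_data()].
#'
#' @param sim A `scad_simulation`. @param path Output file.
#' @return `path`, invisibly.
#' @export
write_loading_csv <- function(sim, path) {
  write.csv(sim$loading_curve[, c("time_h", "loading_pct")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_loading_csv
#' @export
write_fields_csv <- function(sim, path) {
  write.csv(as_field_data(sim), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
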