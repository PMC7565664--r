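## Configuration, pipeline entry points, and structured logging.  The
## exported scad_* functions are the programmatic interface; a thin
## command-line dispatcher over them ships in inst/cli/scadsorb.

#' Read a run configuration
#'
#' YAML configuration tying a pipeline run together.  All fields are
#' optional and fall back to the package defaults; recognised top-level
#' keys:
#' \describe{
#'   \item{conditions}{list of \{temperature_K, pressure_bar\}}
#'   \item{geometry}{reactor_volume, reactor_radius, monolith_diameter,
#'     monolith_length, source_area (SI units)}
#'   \item{grid}{nr, nz}
#'   \item{sample}{arguments of [aerogel_sample()]}
#'   \item{coefficients_file}{JSON file of [read_coefficients()]}
#'   \item{solubility_file}{CSV file of [read_solubility_table()]}
#'   \item{solver}{theta_model, scheme, dt}
#'   \item{times_h, replicates, noise_cv, seed}{synthetic-data settings}
#'   \item{kinetics_file}{CSV of [read_kinetics()] (for fit/validate)}
#' }
#' Pressures are in bar in all user-facing files; conversion to Pa happens
#' at the module boundaries.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return An object of class `scad_config`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_scad(sprintf("config file not found: %s", path),
                class = "scad_config_error")
    raw <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop_scad(sprintf("malformed config %s: %s", path, conditionMessage(e)),
                class = "scad_config_error"))
    if (!is.list(raw))
      stop_scad(sprintf("malformed config %s: top level must be a mapping", path),
                class = "scad_config_error")
  }
  known <- c("conditions", "geometry", "grid", "sample", "coefficients_file",
             "solubility_file", "solver", "times_h", "replicates", "noise_cv",
             "seed", "kinetics_file", "validation")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L)
    stop_scad(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
              class = "scad_config_error")

  geometry <- do.call(reactor_geometry, raw$geometry %||% list())
  grid_spec <- modifyList(list(nr = 8L, nz = 32L), raw$grid %||% list())
  sample <- do.call(aerogel_sample, raw$sample %||% list())
  for (f in c("coefficients_file", "solubility_file", "kinetics_file")) {
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]]))
      stop_scad(sprintf("%s does not exist: %s", f, raw[[f]]),
                class = "scad_config_error")
  }
  coeffs <- if (is.null(raw$coefficients_file)) default_coefficients()
            else read_coefficients(raw$coefficients_file)
  soltab <- if (is.null(raw$solubility_file)) default_solubility_table()
            else read_solubility_table(raw$solubility_file)
  conditions <- if (is.null(raw$conditions)) default_conditions() else {
    do.call(rbind, lapply(raw$conditions, function(cc)
      data.frame(temperature_K = cc$temperature_K,
                 pressure_bar = cc$pressure_bar)))
  }
  solver <- raw$solver %||% list()
  control <- scad_control(
    theta_model = solver$theta_model %||% "well_mixed",
    scheme = solver$scheme %||% "implicit")
  structure(list(
    path = path,
    conditions = conditions,
    geometry = geometry,
    grid = build_grid(geometry, grid_spec$nr, grid_spec$nz),
    sample = sample,
    coefficients = coeffs,
    solubility = soltab,
    control = control,
    dt = solver$dt %||% "auto",
    times_h = raw$times_h %||% 1:5,
    replicates = raw$replicates %||% 2L,
    noise_cv = raw$noise_cv %||% 0.02,
    seed = raw$seed,
    kinetics_file = raw$kinetics_file,
    validation = if (is.null(raw$validation)) validation_condition() else
      data.frame(temperature_K = raw$validation$temperature_K,
                 pressure_bar = raw$validation$pressure_bar)
  ), class = "scad_config")
}

append_log <- function(out_dir, command, config, seed = NULL, extra = list()) {
  rec <- c(list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = command,
    package_version = as.character(packageVersion("scadsorb")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_file = config$path %||% "<defaults>",
    config_md5 = if (!is.null(config$path))
      unname(tools::md5sum(config$path)) else NA,
    seed = seed
  ), extra)
  con <- file(file.path(out_dir, "scadsorb.log"), open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  invisible(rec)
}

#' Thermophysical and kinetic property report for one condition
#'
#' Evaluates the full derived-property chain at one (T, p): CO2 density,
#' molecular and effective diffusivity, maximum loading, adsorption limit,
#' and adsorption rate constant.
#'
#' @param T_K Temperature, K.
#' @param p_bar Pressure, bar.
#' @param config A `scad_config` (or `NULL` for defaults).
#' @return An object of class `scad_props` (a named list with units in the
#'   print method).
#' @examples
#' scad_props(323, 140)
#' @export
scad_props <- function(T_K, p_bar, config = read_run_config()) {
  p_pa <- bar_to_pa(p_bar)
  rho <- co2_density(T_K, p_pa)
  ys <- solubility(T_K, p_pa, config$solubility)
  d_theta <- molecular_diffusivity(T_K, rho)
  d_omega <- effective_diffusivity(T_K, p_bar, config$coefficients)
  a_inf <- max_loading(T_K, config$coefficients)
  q_inf <- adsorption_limit(a_inf, config$sample, rho, ys)
  k_rate <- adsorption_rate_constant(T_K, p_pa, config$sample, q_inf = q_inf)
  structure(list(T_K = T_K, p_bar = p_bar, rho = rho, y_s = ys,
                 d_theta = d_theta, d_omega = d_omega, a_inf = a_inf,
                 q_inf = q_inf, k_rate = k_rate), class = "scad_props")
}

#' @export
print.scad_props <- function(x, ...) {
  cat(sprintf("Condition: T = %g K, p = %g bar\n", x$T_K, x$p_bar))
  cat(sprintf("  CO2 density (Peng-Robinson)    rho     = %10.2f kg/m^3\n", x$rho))
  cat(sprintf("  solubility                     Ys      = %10.4g kg/kg\n", x$y_s))
  cat(sprintf("  molecular diffusivity (He-Yu)  D_theta = %10.4g m^2/s\n", x$d_theta))
  cat(sprintf("  effective diffusivity          D_omega = %10.4g m^2/s\n", x$d_omega))
  cat(sprintf("  maximum loading                A_inf   = %10.2f %%\n", x$a_inf))
  cat(sprintf("  adsorption limit               q_inf   = %10.4g kg/kg\n", x$q_inf))
  cat(sprintf("  adsorption rate constant       K       = %10.4g 1/s\n", x$k_rate))
  invisible(x)
}

#' Pipeline commands
#'
#' Programmatic equivalents of the shell subcommands: `scad_synth()`
#' generates a synthetic kinetics dataset, `scad_simulate()` writes loading
#' curves and field snapshots for every configured condition, `scad_fit()`
#' calibrates the correlations from a kinetics CSV, and `scad_validate()`
#' scores the calibrated model against a held-out condition with the mean
#' relative error.  Every command appends a structured JSON line to
#' `scadsorb.log` in the output directory (timestamp, config hash,
#' versions, seed), which is sufficient to re-run the artifact.
#'
#' @param config A `scad_config` from [read_run_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed overriding the config seed.
#' @return The main result of the step, invisibly for the file-writing
#'   commands: `scad_synth()` the dataset, `scad_simulate()` the list of
#'   simulations, `scad_fit()` the `scad_fit` object, `scad_validate()` the
#'   relative error in percent.
#' @export
scad_synth <- function(config, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed
  if (config$noise_cv > 0 && is.null(seed))
    stop_scad("a seed is required (config key `seed` or argument)",
              class = "scad_config_error")
  data <- generate_kinetics(config$conditions, config$coefficients,
                            config$sample, config$solubility, config$grid,
                            times_h = config$times_h,
                            replicates = config$replicates,
                            noise_cv = config$noise_cv, seed = seed,
                            control = config$control)
  write_kinetics(data, file.path(out_dir, "kinetics.csv"))
  append_log(out_dir, "synth", config, seed,
             list(rows = nrow(data), out = "kinetics.csv"))
  invisible(data)
}

#' @rdname scad_synth
#' @export
scad_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sims <- lapply(seq_len(nrow(config$conditions)), function(k) {
    T_K <- config$conditions$temperature_K[k]
    p_bar <- config$conditions$pressure_bar[k]
    sim <- simulate_adsorption(T_K, p_bar, config$sample,
                               config$coefficients, config$solubility,
                               config$grid, t_end = max(config$times_h) * 3600,
                               dt = config$dt, control = config$control)
    tag <- sprintf("T%03.0fK_p%03.0fbar", T_K, p_bar)
    write_loading_csv(sim, file.path(out_dir, paste0("loading_", tag, ".csv")))
    write_fields_csv(sim, file.path(out_dir, paste0("fields_", tag, ".csv")))
    sim
  })
  append_log(out_dir, "simulate", config, NULL,
             list(n_conditions = nrow(config$conditions)))
  invisible(sims)
}

#' @rdname scad_synth
#' @export
scad_fit <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$kinetics_file))
    stop_scad("config key `kinetics_file` is required for fitting",
              class = "scad_config_error")
  data <- read_kinetics(config$kinetics_file)
  fit <- fit_kinetics(data, sample = config$sample,
                      soltab = config$solubility, grid = config$grid,
                      exclude = config$validation, control = config$control)
  write_coefficients(fit$coefficients, file.path(out_dir, "coefficients.json"))
  jsonlite::write_json(
    list(coefficients = unclass(fit$coefficients),
         per_condition = fit$per_condition,
         diagnostics = fit$diagnostics),
    file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  # residuals of the recalibrated model at the fitted conditions
  res <- do.call(rbind, lapply(seq_len(nrow(fit$per_condition)), function(k) {
    row <- fit$per_condition[k, ]
    d <- subset_condition(data, row$temperature_K, row$pressure_bar)
    avg <- average_replicates(d)
    ctl <- config$control
    ctl$d_omega <- row$d_omega_hat
    ctl$a_inf <- row$a_inf_hat
    sim <- simulate_adsorption(row$temperature_K, row$pressure_bar,
                               config$sample, config$coefficients,
                               config$solubility, config$grid,
                               t_end = max(avg$time_h) * 3600, control = ctl)
    data.frame(temperature_K = row$temperature_K,
               pressure_bar = row$pressure_bar, time_h = avg$time_h,
               observed_pct = avg$loading_pct,
               model_pct = loading_at(sim, avg$time_h))
  }))
  res$residual_pct <- res$model_pct - res$observed_pct
  write.csv(res, file.path(out_dir, "residuals.csv"), row.names = FALSE,
            quote = FALSE)
  append_log(out_dir, "fit", config, NULL,
             list(n_conditions = fit$diagnostics$n_conditions))
  invisible(fit)
}

#' @rdname scad_synth
#' @param coeffs Optional [coefficient_set()] to validate (default: the
#'   configured coefficients, i.e. typically the output of a previous fit).
#' @export
scad_validate <- function(config, out_dir, coeffs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$kinetics_file))
    stop_scad("config key `kinetics_file` is required for validation",
              class = "scad_config_error")
  data <- read_kinetics(config$kinetics_file)
  coeffs <- coeffs %||% config$coefficients
  vc <- config$validation
  d <- subset_condition(data, vc$temperature_K[1L], vc$pressure_bar[1L])
  sim <- simulate_adsorption(vc$temperature_K[1L], vc$pressure_bar[1L],
                             config$sample, coeffs, config$solubility,
                             config$grid, t_end = max(d$time_h) * 3600,
                             control = config$control)
  err <- relative_error(sim, d)
  jsonlite::write_json(
    list(temperature_K = vc$temperature_K[1L],
         pressure_bar = vc$pressure_bar[1L],
         relative_error_pct = err),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
  append_log(out_dir, "validate", config, NULL,
             list(relative_error_pct = err))
  invisible(err)
}
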