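## Synthetic loading-kinetics datasets with the structure of the batch
## impregnation experiments: loading vs time at several (T, p) conditions,
## duplicate measurements, multiplicative replicate scatter.

#' Study condition sets
#'
#' `fit_conditions()` returns the six calibration conditions
#' \{323, 333\} K x \{120, 160, 200\} bar; `validation_condition()` the
#' held-out condition (323 K, 140 bar); `default_conditions()` both.  The
#' 313 K experiments are generable but excluded from the default sets: at
#' that temperature the solid-state solute changes the adsorption/solubility
#' relationship and the loading data are not comparable.
#'
#' @return A data frame with columns `temperature_K`, `pressure_bar`.
#' @export
fit_conditions <- function() {
  expand.grid(temperature_K = c(323, 333), pressure_bar = c(120, 160, 200),
              KEEP.OUT.ATTRS = FALSE)
}

#' @rdname fit_conditions
#' @export
validation_condition <- function() {
  data.frame(temperature_K = 323, pressure_bar = 140)
}

#' @rdname fit_conditions
#' @export
default_conditions <- function() {
  rbind(fit_conditions(), validation_condition())
}

#' Generate a synthetic loading-kinetics dataset
#'
#' Runs the forward model at each condition, samples the loading curve at
#' the requested times, and multiplies each observation by an independent
#' lognormal factor with unit mean and coefficient of variation `noise_cv`
#' (replicate scatter in loading measurements is roughly proportional, and
#' loadings are positive).  `noise_cv = 0` returns the exact forward-model
#' values; a fixed `seed` makes the dataset fully reproducible.
#'
#' @param conditions Data frame with columns `temperature_K`,
#'   `pressure_bar`.
#' @param coeffs A [coefficient_set()].
#' @param sample An [aerogel_sample()].
#' @param soltab A [solubility_table()].
#' @param grid A [build_grid()] grid (default 8 x 32 on the default
#'   geometry).
#' @param times_h Sampling times, hours (default 1..5).
#' @param replicates Replicates per point (default 2).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (default 0.02).
#' @param seed Integer seed (required when `noise_cv > 0`).
#' @param control A [scad_control()].
#'
#' @return A data frame of class `kinetics_dataset` with columns
#'   `temperature_K, pressure_bar, time_h, loading_pct, replicate`.
#' @export
generate_kinetics <- function(conditions = default_conditions(),
                              coeffs = default_coefficients(),
                              sample = aerogel_sample(),
                              soltab = default_solubility_table(),
                              grid = build_grid(reactor_geometry(), 8, 32),
                              times_h = 1:5,
                              replicates = 2L,
                              noise_cv = 0.02,
                              seed = NULL,
                              control = scad_control()) {
  stopifnot(is.data.frame(conditions),
            all(c("temperature_K", "pressure_bar") %in% names(conditions)))
  if (noise_cv < 0) stop_scad("noise_cv must be >= 0")
  if (replicates < 1L) stop_scad("replicates must be >= 1")
  if (noise_cv > 0 && is.null(seed))
    stop_scad("a seed is required when noise_cv > 0")

  rows <- lapply(seq_len(nrow(conditions)), function(k) {
    T_K <- conditions$temperature_K[k]
    p_bar <- conditions$pressure_bar[k]
    sim <- simulate_adsorption(T_K, p_bar, sample, coeffs, soltab, grid,
                               t_end = max(times_h) * 3600, dt = "auto",
                               control = control)
    a <- loading_at(sim, times_h)
    if (any(diff(a) < -1e-12))
      stop_scad("forward-model loading curve is not non-decreasing")
    data.frame(temperature_K = T_K, pressure_bar = p_bar,
               time_h = rep(times_h, each = replicates),
               loading_pct = rep(a, each = replicates),
               replicate = rep(seq_len(replicates), times = length(times_h)))
  })
  out <- do.call(rbind, rows)

  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    out$loading_pct <- out$loading_pct * with_seed(seed, {
      rlnorm(nrow(out), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  }
  class(out) <- c("kinetics_dataset", "data.frame")
  out
}

# evaluate expr under a fixed RNG seed without disturbing the caller's
# random-number stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write a kinetics dataset CSV
#'
#' CSV format: header
#' `temperature_K,pressure_bar,time_h,loading_pct,replicate`, UTF-8,
#' '.' decimal separator.
#'
#' @param path File path.
#' @return [read_kinetics()] returns a `kinetics_dataset` data frame;
#'   `write_kinetics()` returns `path` invisibly.
#' @export
read_kinetics <- function(path) {
  df <- read.csv(path)
  need <- c("temperature_K", "pressure_bar", "time_h", "loading_pct",
            "replicate")
  if (!all(need %in% names(df)))
    stop_scad(sprintf("kinetics CSV must have columns %s",
                      paste(need, collapse = ", ")))
  class(df) <- c("kinetics_dataset", "data.frame")
  df
}

#' @rdname read_kinetics
#' @param data A `kinetics_dataset` data frame.
#' @export
write_kinetics <- function(data, path) {
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
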