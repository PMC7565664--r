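## Parameter-estimation workflow: golden-section search for the
## per-condition effective diffusivity that minimises the model/data
## discrepancy, profile estimation of the per-condition plateau loading,
## regression of the correlation coefficients across conditions, and the
## model-validation error metric.

#' Golden-section minimisation of a unimodal scalar function
#'
#' Derivative-free bracket contraction at the inverse golden ratio.  The
#' caller is responsible for unimodality of `f` on `[lo, hi]`; `f` is never
#' evaluated outside the bracket.  Terminates when the bracket width drops
#' to `tol` and returns the bracket midpoint.
#'
#' @param f Scalar function.
#' @param lo,hi Bracket, `lo < hi`.
#' @param tol Positive termination width.
#' @param max_iter Iteration cap.
#' @return A list: `minimum` (bracket midpoint), `objective` (`f` there),
#'   `iterations`, `evaluations`, and `interior` (`FALSE` when the minimum
#'   sits at a bracket end, i.e. the true minimiser was probably not
#'   bracketed).
#' @examples
#' golden_section_minimize(function(x) (x - 2)^2, 0, 5, tol = 1e-8)$minimum
#' @export
golden_section_minimize <- function(f, lo, hi, tol = 1e-6, max_iter = 1000L) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop_scad("need finite lo < hi")
  if (tol <= 0) stop_scad("tol must be > 0")
  invphi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - invphi * (b - a)
  x2 <- a + invphi * (b - a)
  eval_f <- function(x) {
    v <- f(x)
    if (!is.finite(v))
      stop_scad(sprintf("non-finite objective value at x = %g", x))
    v
  }
  f1 <- eval_f(x1); f2 <- eval_f(x2)
  n_eval <- 2L; iter <- 0L
  while ((b - a) > tol && iter < max_iter) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - invphi * (b - a)
      f1 <- eval_f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + invphi * (b - a)
      f2 <- eval_f(x2)
    }
    n_eval <- n_eval + 1L
    iter <- iter + 1L
  }
  xm <- (a + b) / 2
  list(minimum = xm, objective = eval_f(xm), iterations = iter,
       evaluations = n_eval + 1L,
       interior = (xm - lo) > 2 * tol && (hi - xm) > 2 * tol)
}

# replicate-averaged loading curve of one condition, ordered by time
average_replicates <- function(data) {
  agg <- aggregate(loading_pct ~ time_h, data = as.data.frame(data), FUN = mean)
  agg[order(agg$time_h), ]
}

subset_condition <- function(data, T_K, p_bar) {
  d <- data[abs(data$temperature_K - T_K) < 1e-9 &
              abs(data$pressure_bar - p_bar) < 1e-9, , drop = FALSE]
  if (nrow(d) == 0L)
    stop_scad(sprintf("no observations at (T = %g K, p = %g bar)", T_K, p_bar))
  d
}

# RMS relative deviation between the simulated and observed loadings at the
# observation times (replicates averaged before the objective, so the
# objective is invariant to time-point duplication)
discrepancy_objective <- function(sim, data_avg) {
  model <- loading_at(sim, data_avg$time_h)
  ok <- data_avg$loading_pct > 0
  sqrt(mean(((model[ok] - data_avg$loading_pct[ok]) /
               data_avg$loading_pct[ok])^2))
}

#' Fit the effective diffusivity at one condition
#'
#' Golden-section search in log10(D_Omega) for the diffusivity that
#' minimises the root-mean-square relative deviation between the simulated
#' and observed loading curves at one (T, p) condition.  The plateau
#' loading `a_inf` (hence the adsorption limit) is held fixed during the
#' search; see [estimate_max_loading()] for its data-driven estimation.
#'
#' @param data A `kinetics_dataset` (may contain several conditions; the
#'   relevant one is extracted).
#' @param T_K,p_bar Condition.
#' @param a_inf Maximum loading used for the forward runs, mass percent.
#' @param sample,soltab,grid,control Forward-model inputs as in
#'   [simulate_adsorption()].
#' @param bracket Search interval for D_Omega, m^2/s (default spans
#'   1e-10..1e-6; the search itself runs in log10 space).
#' @param tol Termination width in log10(D_Omega) (default 2e-4, i.e.
#'   ~0.05 percent in D).
#' @return A list: `d_omega_hat`, `objective`, `interior`, `iterations`,
#'   `evaluations`.
#' @export
fit_effective_diffusivity <- function(data, T_K, p_bar, a_inf,
                                      sample = aerogel_sample(),
                                      soltab = default_solubility_table(),
                                      grid = build_grid(reactor_geometry(), 8, 32),
                                      bracket = c(1e-10, 1e-6),
                                      tol = 2e-4,
                                      control = scad_control()) {
  d <- subset_condition(data, T_K, p_bar)
  avg <- average_replicates(d)
  if (nrow(avg) < 3L)
    stop_scad("at least 3 distinct time points are required")
  if (bracket[2] / bracket[1] < 100)
    stop_scad("bracket must span at least 2 orders of magnitude")
  t_end <- max(avg$time_h) * 3600
  obj <- function(log10_d) {
    ctl <- control
    ctl$d_omega <- 10^log10_d
    ctl$a_inf <- a_inf
    sim <- simulate_adsorption(T_K, p_bar, sample, coeffs = NULL,
                               soltab = soltab, grid = grid, t_end = t_end,
                               control = ctl)
    discrepancy_objective(sim, avg)
  }
  res <- golden_section_minimize(obj, log10(bracket[1]), log10(bracket[2]),
                                 tol = tol)
  if (!res$interior)
    warning(sprintf(
      "discrepancy minimum at (T = %g K, p = %g bar) is not interior to the bracket",
      T_K, p_bar))
  list(d_omega_hat = 10^res$minimum, objective = res$objective,
       interior = res$interior, iterations = res$iterations,
       evaluations = res$evaluations)
}

#' Estimate the plateau (maximum) loading at one condition
#'
#' If the observed curve has flattened (relative change below `flat_tol`
#' per hour over the last interval), the largest-time loading is taken as
#' the plateau.  Otherwise the plateau is estimated by profile
#' minimisation: an outer golden-section search over A_inf in which each
#' trial plateau is scored by the best-fitting effective diffusivity
#' ([fit_effective_diffusivity()]).  The kinetics experiments sample 1-5 h
#' while full saturation of the monolith takes longer, so the profile
#' branch is the common path.
#'
#' @inheritParams fit_effective_diffusivity
#' @param flat_tol Flatness threshold, relative change per hour (default
#'   0.01).
#' @param a_bracket Search interval for A_inf, mass percent; default
#'   `[A_last, min(3 A_last, 95)]`.
#' @param a_tol Termination width for the outer search, mass percent.
#' @return A list: `a_inf_hat`, `d_omega_hat`, `objective`, `flattened`,
#'   `evaluations`.
#' @export
estimate_max_loading <- function(data, T_K, p_bar,
                                 sample = aerogel_sample(),
                                 soltab = default_solubility_table(),
                                 grid = build_grid(reactor_geometry(), 8, 32),
                                 bracket = c(1e-10, 1e-6),
                                 tol = 2e-4,
                                 flat_tol = 0.01,
                                 a_bracket = NULL,
                                 a_tol = 0.02,
                                 control = scad_control()) {
  d <- subset_condition(data, T_K, p_bar)
  avg <- average_replicates(d)
  n <- nrow(avg)
  if (n < 3L) stop_scad("at least 3 distinct time points are required")
  a_last <- avg$loading_pct[n]
  slope <- abs(a_last - avg$loading_pct[n - 1L]) /
    max(a_last, .Machine$double.eps) / (avg$time_h[n] - avg$time_h[n - 1L])
  if (slope < flat_tol) {
    fit <- fit_effective_diffusivity(d, T_K, p_bar, a_inf = a_last,
                                     sample = sample, soltab = soltab,
                                     grid = grid, bracket = bracket,
                                     tol = tol, control = control)
    return(list(a_inf_hat = a_last, d_omega_hat = fit$d_omega_hat,
                objective = fit$objective, flattened = TRUE,
                evaluations = fit$evaluations))
  }
  a_bracket <- a_bracket %||% c(a_last, min(3 * a_last, 95))
  evals <- 0L
  prof <- function(a_inf, inner_tol = tol) {
    fit <- suppressWarnings(
      fit_effective_diffusivity(d, T_K, p_bar, a_inf = a_inf,
                                sample = sample, soltab = soltab,
                                grid = grid, bracket = bracket,
                                tol = inner_tol, control = control))
    evals <<- evals + fit$evaluations
    fit$objective
  }
  # coarse pre-scan to locate the basin (the profile need not be unimodal
  # over a wide plateau bracket), then golden-section refinement inside it
  a_grid <- seq(a_bracket[1], a_bracket[2], length.out = 8L)
  scan <- vapply(a_grid, prof, numeric(1), inner_tol = 10 * tol)
  k <- which.min(scan)
  if ((max(scan) - min(scan)) < 1e-3 * max(scan, .Machine$double.eps))
    warning(sprintf(
      "plateau loading is weakly identified at (T = %g K, p = %g bar): profile objective is nearly flat",
      T_K, p_bar))
  lo <- a_grid[max(1L, k - 1L)]
  hi <- a_grid[min(length(a_grid), k + 1L)]
  res <- golden_section_minimize(prof, lo, hi, tol = a_tol)
  fit <- fit_effective_diffusivity(d, T_K, p_bar, a_inf = res$minimum,
                                   sample = sample, soltab = soltab,
                                   grid = grid, bracket = bracket, tol = tol,
                                   control = control)
  list(a_inf_hat = res$minimum, d_omega_hat = fit$d_omega_hat,
       objective = fit$objective, flattened = FALSE,
       evaluations = evals + fit$evaluations)
}

#' Regress the correlation coefficients from per-condition estimates
#'
#' Fits the effective-diffusivity correlation
#' `D = (a1 p + a2) exp(-(a3 p + a4)/T)` by nonlinear least squares on
#' log(D) (moment-based initial guess from the per-pressure temperature
#' slopes, refined from a deterministic 3x3x3x3 lattice of scale
#' perturbations), and the maximum-loading line `A_inf/100 = b1 T + b2` by
#' ordinary least squares pooled over pressures.
#'
#' @param per_condition Data frame with columns `temperature_K`,
#'   `pressure_bar`, `d_omega_hat` and (for the b-fit) `a_inf_hat`.
#' @return A [coefficient_set()] with attributes `ss_log_d` (residual sum
#'   of squares on log D) and `degenerate` (`TRUE` when the diffusivities
#'   carry no pressure information and a1 = a3 = 0 was imposed).
#' @export
fit_correlations <- function(per_condition) {
  pc <- as.data.frame(per_condition)
  need <- c("temperature_K", "pressure_bar", "d_omega_hat")
  if (!all(need %in% names(pc)))
    stop_scad(sprintf("per_condition must have columns %s",
                      paste(need, collapse = ", ")))
  Ts <- pc$temperature_K; Ps <- pc$pressure_bar; D <- pc$d_omega_hat
  if (any(D <= 0)) stop_scad("all d_omega_hat must be > 0")
  if (length(unique(paste(Ts, Ps))) < 4L)
    stop_scad("at least 4 distinct (T, p) conditions are required for the 4-parameter diffusivity fit")
  if (length(unique(Ts)) < 2L)
    stop_scad("rank-deficient design: need at least 2 distinct temperatures")
  if (length(unique(Ps)) < 2L)
    stop_scad("rank-deficient design: need at least 2 distinct pressures")

  lnD <- log(D)
  degenerate <- diff(range(lnD)) < 1e-10

  if (degenerate) {
    # all diffusivities identical: no (T, p) information; a1 = a3 = a4 = 0
    a <- c(a1 = 0, a2 = exp(mean(lnD)), a3 = 0, a4 = 0)
    warning("per-condition diffusivities are identical: returning the degenerate pressure- and temperature-independent fit")
    ss <- 0
  } else {
    # moment initialisation: for each pressure present at >= 2 temperatures
    # the slope of ln D vs 1/T gives (a3 p + a4); regress those on p
    slopes <- lapply(split(seq_along(D), Ps), function(idx) {
      if (length(unique(Ts[idx])) < 2L) return(NULL)
      fit <- lm(lnD[idx] ~ I(1 / Ts[idx]))
      c(p = Ps[idx][1L], s = -unname(coef(fit)[2L]))
    })
    slopes <- do.call(rbind, Filter(Negate(is.null), slopes))
    if (is.null(slopes) || nrow(slopes) < 1L)
      stop_scad("rank-deficient design: no pressure is observed at two temperatures")
    if (nrow(slopes) >= 2L) {
      sf <- lm(slopes[, "s"] ~ slopes[, "p"])
      a3_0 <- unname(coef(sf)[2L]); a4_0 <- unname(coef(sf)[1L])
    } else {
      a3_0 <- 0; a4_0 <- unname(slopes[1L, "s"])
    }
    w <- D * exp((a3_0 * Ps + a4_0) / Ts)
    pf <- lm(w ~ Ps)
    a1_0 <- unname(coef(pf)[2L]); a2_0 <- unname(coef(pf)[1L])
    start <- c(a1_0, a2_0, a3_0, a4_0)

    ssq <- function(par) {
      pref <- par[1L] * Ps + par[2L]
      if (any(pref <= 0)) return(1e10)
      r <- log(pref) - (par[3L] * Ps + par[4L]) / Ts - lnD
      sum(r^2)
    }
    # deterministic multi-start lattice of scale perturbations
    fac <- c(0.7, 1, 1.4)
    best <- NULL
    for (f1 in fac) for (f2 in fac) for (f3 in fac) for (f4 in fac) {
      p0 <- start * c(f1, f2, f3, f4)
      if (ssq(p0) >= 1e10) next
      fit <- optim(p0, ssq, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best))
      stop_scad("no admissible starting point for the diffusivity fit (a1 p + a2 <= 0 everywhere)")
    a <- setNames(best$par, c("a1", "a2", "a3", "a4"))
    ss <- best$value
  }

  if (!"a_inf_hat" %in% names(pc))
    stop_scad("per_condition must carry a_inf_hat for the maximum-loading fit")
  bt <- unique(data.frame(T = Ts, A = pc$a_inf_hat))
  if (length(unique(bt$T)) < 2L)
    stop_scad("rank-deficient design: need at least 2 distinct temperatures for the maximum-loading line")
  bf <- lm(I(A / 100) ~ T, data = bt)
  out <- coefficient_set(a1 = unname(a["a1"]), a2 = unname(a["a2"]),
                         a3 = unname(a["a3"]), a4 = unname(a["a4"]),
                         b1 = unname(coef(bf)[2L]), b2 = unname(coef(bf)[1L]))
  attr(out, "ss_log_d") <- ss
  attr(out, "degenerate") <- degenerate
  out
}

#' Full calibration workflow over a kinetics dataset
#'
#' For every condition in `data` except the held-out validation
#' condition(s): estimate the plateau loading and effective diffusivity
#' ([estimate_max_loading()]), then regress the correlation coefficients
#' ([fit_correlations()]).
#'
#' @inheritParams fit_effective_diffusivity
#' @param exclude Conditions excluded from fitting (default the
#'   validation condition 323 K / 140 bar); `NULL` to use everything.
#' @param ... Passed on to [estimate_max_loading()].
#' @return An object of class `scad_fit`: `per_condition` data frame
#'   (temperature_K, pressure_bar, d_omega_hat, a_inf_hat, objective,
#'   flattened, evaluations), `coefficients` ([coefficient_set()]), and
#'   `diagnostics`.
#' @export
fit_kinetics <- function(data,
                         sample = aerogel_sample(),
                         soltab = default_solubility_table(),
                         grid = build_grid(reactor_geometry(), 8, 32),
                         exclude = validation_condition(),
                         control = scad_control(),
                         ...) {
  conds <- unique(as.data.frame(data)[, c("temperature_K", "pressure_bar")])
  if (!is.null(exclude)) {
    drop <- interaction(conds$temperature_K, conds$pressure_bar) %in%
      interaction(exclude$temperature_K, exclude$pressure_bar)
    conds <- conds[!drop, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(conds)), function(k) {
    est <- estimate_max_loading(data, conds$temperature_K[k],
                                conds$pressure_bar[k], sample = sample,
                                soltab = soltab, grid = grid,
                                control = control, ...)
    data.frame(temperature_K = conds$temperature_K[k],
               pressure_bar = conds$pressure_bar[k],
               d_omega_hat = est$d_omega_hat,
               a_inf_hat = est$a_inf_hat,
               objective = est$objective,
               flattened = est$flattened,
               evaluations = est$evaluations)
  })
  per_condition <- do.call(rbind, rows)
  coeffs <- fit_correlations(per_condition)
  structure(list(per_condition = per_condition,
                 coefficients = coeffs,
                 diagnostics = list(
                   ss_log_d = attr(coeffs, "ss_log_d"),
                   degenerate = attr(coeffs, "degenerate"),
                   n_conditions = nrow(per_condition),
                   total_evaluations = sum(per_condition$evaluations))),
            class = "scad_fit")
}

#' @export
print.scad_fit <- function(x, ...) {
  cat(sprintf("<scad_fit> %d conditions, %d forward evaluations\n",
              x$diagnostics$n_conditions, x$diagnostics$total_evaluations))
  print(x$per_condition, digits = 4)
  cat("\n")
  print(x$coefficients)
  invisible(x)
}

#' Mean relative error between a model curve and observations
#'
#' Mean over observation points of |model - data|/data x 100, with
#' replicates averaged per time point and the model curve interpolated
#' linearly to the observation times.  Zero-valued observations are
#' excluded with a warning.
#'
#' @param model_curve Either a `scad_simulation` or a data frame with
#'   columns `time_h`, `loading_pct`.
#' @param data A `kinetics_dataset` restricted to one condition, or a full
#'   dataset plus `T_K`/`p_bar` to select it.
#' @param T_K,p_bar Optional condition selector.
#' @return Relative error, percent.
#' @export
relative_error <- function(model_curve, data, T_K = NULL, p_bar = NULL) {
  if (!is.null(T_K) && !is.null(p_bar))
    data <- subset_condition(data, T_K, p_bar)
  avg <- average_replicates(data)
  model <- if (inherits(model_curve, "scad_simulation")) {
    loading_at(model_curve, avg$time_h)
  } else {
    approx(model_curve$time_h, model_curve$loading_pct, xout = avg$time_h,
           rule = 2)$y
  }
  zero <- avg$loading_pct == 0
  if (any(zero)) {
    warning(sprintf("%d zero-valued observation(s) excluded from the relative error",
                    sum(zero)))
    model <- model[!zero]
    avg <- avg[!zero, , drop = FALSE]
  }
  if (nrow(avg) == 0L) stop_scad("no usable observations")
  mean(abs(model - avg$loading_pct) / avg$loading_pct) * 100
}
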