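#' Solubility table
#'
#' Tabulated solubility of the solute in supercritical CO2, as mass of
#' solute per mass of mixture, on a (temperature, pressure) grid.  Entries
#' must be unique per (T, p) and strictly inside (0, 1).
#'
#' @param temperature_K Temperatures, K.
#' @param pressure_bar Pressures, bar.
#' @param y_p Solubility, kg solute / kg mixture.
#' @return An object of class `solubility_table` wrapping a data frame with
#'   columns `temperature_K`, `pressure_bar`, `y_p_kg_per_kg`.
#' @seealso [solubility()], [read_solubility_table()]
#' @export
solubility_table <- function(temperature_K, pressure_bar, y_p) {
  n <- length(y_p)
  if (n < 1L) stop_scad("at least one solubility entry is required")
  if (length(temperature_K) != n || length(pressure_bar) != n)
    stop_scad("temperature_K, pressure_bar and y_p must have equal length")
  if (any(y_p <= 0 | y_p >= 1))
    stop_scad("solubility values must lie strictly in (0, 1)")
  key <- paste(signif(temperature_K, 10), signif(pressure_bar, 10))
  if (anyDuplicated(key))
    stop_scad("duplicate (temperature, pressure) entries in solubility table")
  entries <- data.frame(temperature_K = temperature_K,
                        pressure_bar = pressure_bar,
                        y_p_kg_per_kg = y_p)
  entries <- entries[order(entries$temperature_K, entries$pressure_bar), ]
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "solubility_table")
}

#' @export
print.solubility_table <- function(x, ...) {
  cat(sprintf("<solubility_table> %d entries, T %g-%g K, p %g-%g bar\n",
              nrow(x$entries), min(x$entries$temperature_K),
              max(x$entries$temperature_K), min(x$entries$pressure_bar),
              max(x$entries$pressure_bar)))
  print(x$entries, ...)
  invisible(x)
}

#' Read / write a solubility table CSV
#'
#' CSV format: header `temperature_K,pressure_bar,y_p_kg_per_kg`, UTF-8,
#' '.' decimal separator.
#'
#' @param path File path.
#' @return [read_solubility_table()] returns a [solubility_table()];
#'   `write_solubility_table()` returns `path` invisibly.
#' @export
read_solubility_table <- function(path) {
  df <- read.csv(path)
  need <- c("temperature_K", "pressure_bar", "y_p_kg_per_kg")
  if (!all(need %in% names(df)))
    stop_scad(sprintf("solubility CSV must have columns %s",
                      paste(need, collapse = ", ")))
  solubility_table(df$temperature_K, df$pressure_bar, df$y_p_kg_per_kg)
}

#' @rdname read_solubility_table
#' @param table A [solubility_table()].
#' @export
write_solubility_table <- function(table, path) {
  write.csv(table$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled placeholder solubility table for ibuprofen in scCO2
#'
#' A synthetic, literature-informed placeholder covering
#' \{313, 323, 333\} K x \{120, 140, 160, 200\} bar.  The values (2.2-4.8
#' percent by mass) have the qualitative structure reported for
#' ibuprofen/scCO2 (increasing with pressure; increasing with temperature
#' at 140-200 bar; nearly temperature-independent at 120 bar) and are
#' scaled so that the forward model saturates the monolith within the
#' roughly five hours observed in batch impregnation experiments, but they
#' are not measured data: supply your own table via
#' [read_solubility_table()] for quantitative work.
#'
#' @return A [solubility_table()].
#' @export
default_solubility_table <- function() {
  path <- system.file("extdata", "ibuprofen_scco2_solubility_synthetic.csv",
                      package = "scadsorb", mustWork = TRUE)
  read_solubility_table(path)
}

#' Solubility lookup with bilinear interpolation
#'
#' Returns the tabulated solubility at an exact (T, p) entry, or bilinear
#' interpolation in (T, p) between the four surrounding grid entries.
#' Queries outside the table's rectangular hull raise an error unless
#' `extrapolate = TRUE`, in which case the query is clamped to the hull
#' boundary.
#'
#' @param T Temperature, K.
#' @param p Pressure, Pa.
#' @param table A [solubility_table()].
#' @param extrapolate Allow out-of-hull queries (clamped)?  Default `FALSE`.
#'
#' @return Solubility, kg solute / kg mixture.
#' @export
solubility <- function(T, p, table = default_solubility_table(),
                       extrapolate = FALSE) {
  stopifnot(inherits(table, "solubility_table"))
  e <- table$entries
  p_bar <- pa_to_bar(p)
  hit <- abs(e$temperature_K - T) < 1e-9 * max(1, T) &
    abs(e$pressure_bar - p_bar) < 1e-9 * max(1, p_bar)
  if (any(hit)) return(e$y_p_kg_per_kg[which(hit)[1L]])
  Ts <- sort(unique(e$temperature_K))
  Ps <- sort(unique(e$pressure_bar))
  inside <- T >= min(Ts) && T <= max(Ts) && p_bar >= min(Ps) && p_bar <= max(Ps)
  if (!inside && !extrapolate)
    stop_scad(sprintf(
      "(T = %g K, p = %g bar) is outside the solubility table hull; set extrapolate = TRUE to clamp",
      T, p_bar), class = "scad_domain_error")
  Tq <- min(max(T, min(Ts)), max(Ts))
  Pq <- min(max(p_bar, min(Ps)), max(Ps))
  if (length(Ts) == 1L || length(Ps) == 1L) {
    # degenerate grid: 1-D linear interpolation along the varying axis
    if (length(Ts) == 1L && length(Ps) == 1L) return(e$y_p_kg_per_kg[1L])
    if (length(Ts) == 1L)
      return(approx(e$pressure_bar, e$y_p_kg_per_kg, xout = Pq)$y)
    return(approx(e$temperature_K, e$y_p_kg_per_kg, xout = Tq)$y)
  }
  # full rectilinear grid required for bilinear interpolation
  Z <- matrix(NA_real_, nrow = length(Ts), ncol = length(Ps))
  iT <- match(signif(e$temperature_K, 10), signif(Ts, 10))
  iP <- match(signif(e$pressure_bar, 10), signif(Ps, 10))
  Z[cbind(iT, iP)] <- e$y_p_kg_per_kg
  # restrict to the 2x2 cell surrounding the query; all four corners needed
  i1 <- min(max(findInterval(Tq, Ts), 1L), length(Ts) - 1L); i2 <- i1 + 1L
  j1 <- min(max(findInterval(Pq, Ps), 1L), length(Ps) - 1L); j2 <- j1 + 1L
  corners <- Z[c(i1, i2), c(j1, j2)]
  if (anyNA(corners))
    stop_scad(sprintf(
      "solubility table is missing grid entries around (T = %g K, p = %g bar)",
      Tq, Pq), class = "scad_domain_error")
  # pracma::interp2 expects Z with rows along y and columns along x
  pracma::interp2(x = Ps, y = Ts, Z = Z, xp = Pq, yp = Tq, method = "linear")
}
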