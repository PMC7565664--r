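#' Reactor geometry
#'
#' Axisymmetric batch-reactor geometry: a vertical cylinder of working
#' volume `reactor_volume` with the aerogel monolith standing on the bottom
#' (region Omega) and the solute source (an envelope holding excess solid
#' drug) at the top.  The reactor height follows from the volume and radius.
#'
#' @param reactor_volume Working volume, m^3 (default 60 mL).
#' @param reactor_radius Internal radius, m (default 15 mm).
#' @param monolith_diameter,monolith_length Monolith dimensions, m.
#' @param source_area Area of the saturated source patch on the top face,
#'   m^2; `NULL` (default) uses the full top face.
#' @return An object of class `reactor_geometry`.
#' @export
reactor_geometry <- function(reactor_volume = 60e-6,
                             reactor_radius = 0.015,
                             monolith_diameter = 0.010,
                             monolith_length = 0.050,
                             source_area = NULL) {
  if (any(c(reactor_volume, reactor_radius, monolith_diameter,
            monolith_length) <= 0))
    stop_scad("all geometry dimensions must be > 0")
  height <- reactor_volume / (pi * reactor_radius^2)
  r_mono <- monolith_diameter / 2
  v_mono <- pi * r_mono^2 * monolith_length
  if (r_mono >= reactor_radius)
    stop_scad("monolith radius must be smaller than the reactor radius")
  if (monolith_length >= height)
    stop_scad(sprintf(
      "monolith length %.3g m does not fit the reactor height %.3g m",
      monolith_length, height))
  if (v_mono >= reactor_volume)
    stop_scad("monolith volume must be smaller than the reactor volume")
  a_top <- pi * reactor_radius^2
  source_area <- source_area %||% a_top
  if (source_area <= 0 || source_area > a_top * (1 + 1e-12))
    stop_scad("source_area must lie in (0, top-face area]")
  structure(list(
    reactor_volume = reactor_volume,
    reactor_radius = reactor_radius,
    height = height,
    monolith_diameter = monolith_diameter,
    monolith_length = monolith_length,
    monolith_volume = v_mono,
    source_area = source_area,
    monolith_position = "bottom",
    source_position = "top"
  ), class = "reactor_geometry")
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat("<reactor_geometry>\n")
  cat(sprintf("  reactor : %.1f mL, radius %.1f mm, height %.1f mm\n",
              1e6 * x$reactor_volume, 1e3 * x$reactor_radius, 1e3 * x$height))
  cat(sprintf("  monolith: %.1f mm dia x %.1f mm (bottom)\n",
              1e3 * x$monolith_diameter, 1e3 * x$monolith_length))
  cat(sprintf("  source  : %.3g m^2 patch (top)\n", x$source_area))
  invisible(x)
}

#' Build an axisymmetric finite-volume grid
#'
#' Cell-centred axisymmetric (r, z) grid over the reactor with region labels
#' per cell (`"omega"` for the porous monolith, `"theta"` for the free
#' volume).  Radial and axial cell edges conform exactly to the monolith
#' boundary so that the Omega cells tile the monolith cylinder; spacing is
#' uniform within each sub-block.  z = 0 is the reactor bottom.
#'
#' @param geometry A [reactor_geometry()].
#' @param nr Number of radial cells across the reactor radius (>= 4).
#' @param nz Number of axial cells across the reactor height (>= 8).
#' @return An object of class `scad_grid` with cell edges, centres, volumes
#'   and region labels.
#' @examples
#' g <- build_grid(reactor_geometry(), nr = 8, nz = 32)
#' sum(g$volume[g$region == "omega"])   # monolith volume
#' @export
build_grid <- function(geometry, nr, nz) {
  stopifnot(inherits(geometry, "reactor_geometry"))
  if (nr < 4L) stop_scad("nr must be >= 4")
  if (nz < 8L) stop_scad("nz must be >= 8")
  R <- geometry$reactor_radius
  H <- geometry$height
  r_m <- geometry$monolith_diameter / 2
  L_m <- geometry$monolith_length
  nr_in <- round(nr * r_m / R)
  if (nr_in < 2L)
    stop_scad(sprintf(
      "monolith not resolvable: %d radial cells would fall inside it; increase nr",
      nr_in))
  nr_in <- min(nr_in, nr - 1L)
  nz_in <- min(max(round(nz * L_m / H), 2L), nz - 1L)
  r_edges <- c(seq(0, r_m, length.out = nr_in + 1L),
               seq(r_m, R, length.out = nr - nr_in + 1L)[-1L])
  z_edges <- c(seq(0, L_m, length.out = nz_in + 1L),
               seq(L_m, H, length.out = nz - nz_in + 1L)[-1L])
  r_c <- (r_edges[-1L] + r_edges[-(nr + 1L)]) / 2
  z_c <- (z_edges[-1L] + z_edges[-(nz + 1L)]) / 2
  ring_area <- pi * (r_edges[-1L]^2 - r_edges[-(nr + 1L)]^2)
  dz <- diff(z_edges)
  # flattened index k = (j - 1) * nr + i, i radial, j axial (0-based faces
  # live on the half-integer edge positions)
  vol <- as.vector(outer(ring_area, dz))
  i_idx <- rep(seq_len(nr), times = nz)
  j_idx <- rep(seq_len(nz), each = nr)
  region <- ifelse(i_idx <= nr_in & j_idx <= nz_in, "omega", "theta")
  structure(list(
    geometry = geometry,
    nr = nr, nz = nz, nr_in = nr_in, nz_in = nz_in,
    r_edges = r_edges, z_edges = z_edges,
    r_centers = r_c, z_centers = z_c,
    ring_area = ring_area,
    volume = vol,
    i_index = i_idx, j_index = j_idx,
    region = region
  ), class = "scad_grid")
}

#' @export
print.scad_grid <- function(x, ...) {
  cat(sprintf("<scad_grid> %d x %d cells (%d in the monolith block)\n",
              x$nr, x$nz, sum(x$region == "omega")))
  cat(sprintf("  reactor volume %.4g mL (cells sum to %.4g mL)\n",
              1e6 * x$geometry$reactor_volume, 1e6 * sum(x$volume)))
  invisible(x)
}
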