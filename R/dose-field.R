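# Microbeam/broad-beam absorbed-dose fields and dosimetric summaries.
#
# The lateral profile is periodic with period `pitch`: a peak stripe of width
# `slit_width` at relative dose 1, valleys at 1/PVDR, optional linear ramps of
# width `penumbra` joining them. A peak is centered on the rotation center
# (s = 0) for every angle, which pins "overlapping MRT" (all fractions share
# phase and angle) exactly. Rotated patterns are evaluated analytically at the
# rotated coordinate s = x cos(angle) + y sin(angle) — no raster resampling,
# so rotation introduces no interpolation error.

# signed distance to the nearest peak center, folded into [-pitch/2, pitch/2]
fold_offset <- function(s_um, pitch_um) {
  ((s_um + pitch_um / 2) %% pitch_um) - pitch_um / 2
}

# relative dose (peak = 1) of the periodic stripe profile; vectorized
profile_unit <- function(geometry, s_um) {
  half_slit <- geometry$slit_width_um / 2
  pen <- geometry$penumbra_um
  valley <- 1 / geometry$pvdr
  d <- abs(fold_offset(s_um, geometry$pitch_um))
  if (pen == 0) {
    out <- ifelse(d <= half_slit, 1, valley)
  } else {
    ramp <- 1 - (d - half_slit) / pen * (1 - valley)
    out <- ifelse(d <= half_slit, 1, ifelse(d >= half_slit + pen, valley, ramp))
  }
  out
}

#' Lateral microbeam dose profile
#'
#' Evaluates the periodic peak/valley profile at lateral offsets from a peak
#' center. Peaks of width `slit_width_um` receive `peak_dose_gy`; valleys
#' receive `peak_dose_gy / pvdr`; if the geometry has a nonzero penumbra,
#' linear ramps of that width join peak and valley.
#'
#' @param geometry A [microbeam_geometry()].
#' @param peak_dose_gy Peak dose in Gy, >= 0.
#' @param offsets_um Numeric vector of lateral positions in micrometers
#'   (0 = center of a peak stripe).
#' @return A numeric vector of doses in Gy, one per offset.
#' @examples
#' g <- microbeam_geometry(slit_width_um = 30, pitch_um = 300, pvdr = 45.77)
#' lateral_profile(g, 1, c(0, 150)) # peak center, valley center
#' @export
lateral_profile <- function(geometry, peak_dose_gy, offsets_um) {
  stopifnot(inherits(geometry, "microbeam_geometry"))
  check_number(peak_dose_gy, "peak_dose_gy", lower = 0)
  if (!is.numeric(offsets_um) || any(!is.finite(offsets_um))) {
    abort("`offsets_um` must be finite numeric offsets in micrometers.")
  }
  peak_dose_gy * profile_unit(geometry, offsets_um)
}

new_dose_map <- function(values, domain, geometry = NULL, angle_deg = NULL,
                         peak_dose_gy = NULL) {
  structure(
    list(values = values, resolution_um = domain$resolution_um,
         center_mm = domain$center_mm, mask = domain_mask(domain),
         domain = domain, geometry = geometry, angle_deg = angle_deg,
         peak_dose_gy = peak_dose_gy),
    class = "dose_map"
  )
}

#' @export
print.dose_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<dose_map> %d x %d grid @ %g um | dose range [%.4g, %.4g] Gy\n",
              nrow(x$values), ncol(x$values), x$resolution_um, min(v), max(v)))
  invisible(x)
}

# unit-peak relative dose grid for one microbeam fraction (rows = y, cols = x)
fraction_unit_grid <- function(geometry, angle_deg, domain) {
  ax <- domain_axes_um(domain)
  th <- angle_deg * pi / 180
  # s = x cos + y sin, evaluated on the grid by outer sum
  s <- outer(ax$y * sin(th), ax$x * cos(th), "+")
  profile_unit(geometry, s)
}

#' Single-fraction microbeam dose map
#'
#' Rasterizes one rotated stripe pattern on the integration domain. The dose
#' at grid point (x, y) is the lateral profile evaluated at the rotated
#' coordinate s = x cos(angle) + y sin(angle), measured from the domain
#' center; the pattern phase puts a peak center at s = 0 for every angle.
#'
#' @param geometry A [microbeam_geometry()].
#' @param peak_dose_gy Peak dose in Gy.
#' @param angle_deg In-plane rotation of the stripe pattern, degrees
#'   (interpreted modulo 180).
#' @param domain An [integration_domain()]; its resolution must give at least
#'   6 samples per slit and it must lie inside the field footprint.
#' @return A `dose_map` (grid of absorbed dose in Gy plus grid metadata).
#' @export
fraction_dose_map <- function(geometry, peak_dose_gy, angle_deg, domain) {
  stopifnot(inherits(geometry, "microbeam_geometry"),
            inherits(domain, "integration_domain"))
  check_number(peak_dose_gy, "peak_dose_gy", lower = 0)
  check_number(angle_deg, "angle_deg")
  check_domain_in_field(domain, geometry)
  check_resolution_for_geometry(domain, geometry)
  angle_deg <- angle_deg %% 180
  vals <- peak_dose_gy * fraction_unit_grid(geometry, angle_deg, domain)
  new_dose_map(vals, domain, geometry, angle_deg, peak_dose_gy)
}

#' Uniform broad-beam dose map
#'
#' @param dose_gy Uniform dose in Gy, >= 0.
#' @param domain An [integration_domain()].
#' @param geometry Optional [microbeam_geometry()] recorded for field-footprint
#'   checking.
#' @return A `dose_map` with constant dose.
#' @export
broad_beam_map <- function(dose_gy, domain, geometry = NULL) {
  stopifnot(inherits(domain, "integration_domain"))
  check_number(dose_gy, "dose_gy", lower = 0)
  if (!is.null(geometry)) check_domain_in_field(domain, geometry)
  ax <- domain_axes_um(domain)
  vals <- matrix(dose_gy, nrow = ax$n, ncol = ax$n)
  new_dose_map(vals, domain, geometry, angle_deg = 0, peak_dose_gy = dose_gy)
}

#' Peak-to-valley dose ratio of a dose map
#'
#' Classifies grid points from the geometry and stripe angle, then returns
#' the mean dose over the central 50 % of each peak stripe divided by the
#' mean dose over the central 50 % of each valley stripe — the ratio a film
#' dosimetry analysis would extract from stripe-core regions.
#'
#' @param map A `dose_map` from a single-fraction stripe pattern.
#' @param geometry The collimator geometry; defaults to the one stored in the
#'   map. A constant map without geometry returns 1.
#' @return The PVDR as a single number; `Inf` (with a warning) if the valley
#'   mean is zero.
#' @export
pvdr_of_map <- function(map, geometry = NULL) {
  stopifnot(inherits(map, "dose_map"))
  geometry <- geometry %||% map$geometry
  vals <- map$values[map$mask]
  if (is.null(geometry)) {
    if (max(vals) - min(vals) < 1e-12 * max(max(vals), 1)) return(1)
    abort("A geometry is required to classify peak and valley regions of a non-uniform map.")
  }
  angle <- (map$angle_deg %||% 0) * pi / 180
  ax <- domain_axes_um(map$domain)
  s <- outer(ax$y * sin(angle), ax$x * cos(angle), "+")
  d <- abs(fold_offset(s, geometry$pitch_um))
  valley_width <- geometry$pitch_um - geometry$slit_width_um - 2 * geometry$penumbra_um
  peak_core <- d <= geometry$slit_width_um / 4
  valley_core <- d >= geometry$pitch_um / 2 - valley_width / 4
  pk <- mean(map$values[peak_core & map$mask])
  vl <- mean(map$values[valley_core & map$mask])
  if (vl == 0) {
    warn("Valley mean dose is zero: PVDR is infinite.")
    return(Inf)
  }
  pk / vl
}

#' Valley dose (rate) from peak dose (rate) and PVDR
#'
#' @param peak_rate Peak dose or dose rate (Gy or Gy/min), >= 0.
#' @param pvdr Peak-to-valley dose ratio, >= 1.
#' @return `peak_rate / pvdr`, in the units of `peak_rate`.
#' @examples
#' valley_from_peak(4.31, 45.77) # ~0.09 Gy/min
#' @export
valley_from_peak <- function(peak_rate, pvdr) {
  check_number(peak_rate, "peak_rate", lower = 0)
  check_number(pvdr, "pvdr", lower = 1)
  peak_rate / pvdr
}

#' Export / import a dose map as a CSV matrix with a JSON sidecar
#'
#' The CSV holds the raw dose grid (rows = y, columns = x, no header); the
#' sidecar `<path>.json` records resolution, center, angle and geometry so the
#' map can be reloaded losslessly.
#'
#' @param map A `dose_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dose_map <- function(map, path) {
  stopifnot(inherits(map, "dose_map"))
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(
    resolution_um = map$resolution_um,
    center_mm = map$center_mm,
    shape = map$domain$shape,
    extent_mm = map$domain$extent_mm,
    angle_deg = map$angle_deg,
    peak_dose_gy = map$peak_dose_gy,
    geometry = if (!is.null(map$geometry)) unclass(map$geometry),
    origin = "grid center = rotation center; axes mm; rows = y, cols = x"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dose_map
#' @export
read_dose_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(vals) <- NULL
  domain <- integration_domain(shape = meta$shape, extent_mm = meta$extent_mm,
                               resolution_um = meta$resolution_um,
                               center_mm = meta$center_mm)
  geometry <- if (!is.null(meta$geometry)) do.call(microbeam_geometry, meta$geometry)
  new_dose_map(vals, domain, geometry, meta$angle_deg, meta$peak_dose_gy)
}

#' Dose map raster plot
#'
#' @param object A `dose_map`.
#' @param ... Unused.
#' @return A ggplot raster of the dose field (mm axes, Gy fill).
#' @export
autoplot.dose_map <- function(object, ...) {
  ax <- domain_axes_um(object$domain)
  df <- tibble::tibble(
    x_mm = rep(ax$x / 1000, each = ax$n),
    y_mm = rep(ax$y / 1000, times = ax$n),
    dose_gy = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$dose_gy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Dose (Gy)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}
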