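#' Microbeam collimator geometry
#'
#' Describes the periodic peak/valley lateral dose profile produced by a
#' multi-slit collimator: planar microbeams of width `slit_width_um` repeating
#' at center-to-center distance `pitch_um`, with peak-to-valley dose ratio
#' `pvdr`, inside a square field of edge `field_size_mm`. An optional linear
#' penumbra of width `penumbra_um` joins each peak to the adjacent valley;
#' the default 0 gives an ideal rectangular profile.
#'
#' Defaults correspond to a small-animal-irradiator MRT setup: 30 um slits,
#' 300 um pitch, PVDR 45.77, 2 x 2 cm field.
#'
#' @param slit_width_um Microbeam (peak stripe) width in micrometers, > 0.
#' @param pitch_um Center-to-center stripe spacing in micrometers, > slit width.
#' @param pvdr Peak-to-valley dose ratio, >= 1.
#' @param field_size_mm Square field edge length in millimeters, > 0.
#' @param penumbra_um Linear ramp width joining peak and valley, >= 0 and
#'   smaller than the half gap `(pitch - slit_width)/2`.
#' @return An object of class `microbeam_geometry`.
#' @examples
#' geom <- microbeam_geometry()
#' lateral_profile(geom, peak_dose_gy = 1, offsets_um = c(0, 150))
#' @export
microbeam_geometry <- function(slit_width_um = 30, pitch_um = 300, pvdr = 45.77,
                               field_size_mm = 20, penumbra_um = 0) {
  check_number(slit_width_um, "slit_width_um", lower = 0, allow_equal_lower = FALSE)
  check_number(pitch_um, "pitch_um", lower = slit_width_um, allow_equal_lower = FALSE)
  check_number(pvdr, "pvdr", lower = 1)
  check_number(field_size_mm, "field_size_mm", lower = 0, allow_equal_lower = FALSE)
  check_number(penumbra_um, "penumbra_um",
               lower = 0, upper = (pitch_um - slit_width_um) / 2,
               allow_equal_upper = FALSE)
  structure(
    list(slit_width_um = slit_width_um, pitch_um = pitch_um, pvdr = pvdr,
         field_size_mm = field_size_mm, penumbra_um = penumbra_um),
    class = "microbeam_geometry"
  )
}

#' @export
print.microbeam_geometry <- function(x, ...) {
  cat(sprintf(
    "<microbeam_geometry> slit %g um | pitch %g um | PVDR %g | field %g mm | penumbra %g um\n",
    x$slit_width_um, x$pitch_um, x$pvdr, x$field_size_mm, x$penumbra_um
  ))
  invisible(x)
}

#' Spatial integration domain
#'
#' The region of the cell-culture dish over which survival is integrated,
#' discretized on a regular grid. Coordinates are continuous millimeters with
#' the domain center at the rotation center; each grid point sits at the
#' center of its cell.
#'
#' @param shape `"square"` (edge = `extent_mm`) or `"disc"` (diameter =
#'   `extent_mm`).
#' @param extent_mm Edge length or diameter in millimeters, > 0.
#' @param resolution_um Grid step in micrometers, > 0. When used with a
#'   microbeam geometry the step must not exceed `slit_width/6` (at least 6
#'   samples per slit).
#' @param center_mm Length-2 numeric, domain center relative to the field
#'   center, millimeters.
#' @return An object of class `integration_domain`.
#' @export
integration_domain <- function(shape = c("square", "disc"), extent_mm = 10,
                               resolution_um = 5, center_mm = c(0, 0)) {
  shape <- match.arg(shape)
  check_number(extent_mm, "extent_mm", lower = 0, allow_equal_lower = FALSE)
  check_number(resolution_um, "resolution_um", lower = 0, allow_equal_lower = FALSE)
  if (!is.numeric(center_mm) || length(center_mm) != 2L || any(!is.finite(center_mm))) {
    abort("`center_mm` must be a length-2 finite numeric vector (x, y) in mm.")
  }
  structure(
    list(shape = shape, extent_mm = extent_mm, resolution_um = resolution_um,
         center_mm = as.numeric(center_mm)),
    class = "integration_domain"
  )
}

#' @export
print.integration_domain <- function(x, ...) {
  cat(sprintf("<integration_domain> %s | extent %g mm | resolution %g um | center (%g, %g) mm\n",
              x$shape, x$extent_mm, x$resolution_um, x$center_mm[1], x$center_mm[2]))
  invisible(x)
}

# grid axes in micrometers (cell centers, symmetric about the domain center)
domain_axes_um <- function(domain) {
  res <- domain$resolution_um
  n <- max(1L, round(domain$extent_mm * 1000 / res))
  offs <- (seq_len(n) - (n + 1) / 2) * res
  list(x = offs + domain$center_mm[1] * 1000,
       y = offs + domain$center_mm[2] * 1000,
       n = n)
}

# logical matrix, TRUE inside the domain (rows = y, cols = x)
domain_mask <- function(domain) {
  ax <- domain_axes_um(domain)
  if (domain$shape == "square") {
    return(matrix(TRUE, nrow = ax$n, ncol = ax$n))
  }
  r_um <- domain$extent_mm * 1000 / 2
  dx <- ax$x - domain$center_mm[1] * 1000
  dy <- ax$y - domain$center_mm[2] * 1000
  outer(dy^2, dx^2, "+") <= r_um^2
}

check_domain_in_field <- function(domain, geometry) {
  half_field <- geometry$field_size_mm / 2
  reach <- max(abs(domain$center_mm)) + domain$extent_mm / 2
  if (reach > half_field + 1e-9) {
    abort(sprintf(
      "Integration domain (reach %g mm from field center) extends beyond the %g x %g mm field footprint.",
      reach, geometry$field_size_mm, geometry$field_size_mm))
  }
  invisible(TRUE)
}

check_resolution_for_geometry <- function(domain, geometry) {
  if (domain$resolution_um > geometry$slit_width_um / 6 + 1e-12) {
    abort(sprintf(
      paste0("Grid resolution %g um is too coarse for a %g um slit: at least 6 ",
             "samples per slit are required (resolution <= slit_width/6 = %g um)."),
      domain$resolution_um, geometry$slit_width_um, geometry$slit_width_um / 6))
  }
  invisible(TRUE)
}

#' Fractionated treatment plan
#'
#' An ordered sequence of dose fractions sharing one collimator geometry.
#' Each fraction is either a uniform broad-beam exposure or a microbeam
#' exposure whose stripe pattern is rotated in-plane about the domain center.
#' Stripe patterns are invariant under 180 degree rotation, so angles are
#' interpreted modulo 180.
#'
#' @param geometry A [microbeam_geometry()].
#' @param fractions A data frame with columns `modality` (`"broad_beam"` or
#'   `"microbeam"`), `peak_dose_gy` (>= 0) and `angle_deg`.
#' @param interval_hours Time between fractions (metadata only; full repair of
#'   sublethal damage between fractions is assumed).
#' @return An object of class `fraction_plan`.
#' @seealso [study_plan()] for the three canonical treatment arms.
#' @export
fraction_plan <- function(geometry, fractions, interval_hours = 24) {
  stopifnot(inherits(geometry, "microbeam_geometry"))
  fractions <- tibble::as_tibble(fractions)
  needed <- c("modality", "peak_dose_gy", "angle_deg")
  if (!all(needed %in% names(fractions))) {
    abort(sprintf("`fractions` must have columns %s.", paste0("`", needed, "`", collapse = ", ")))
  }
  if (nrow(fractions) < 1L) abort("A plan needs at least one fraction.")
  bad <- setdiff(unique(fractions$modality), c("broad_beam", "microbeam"))
  if (length(bad)) abort(sprintf("Unknown modality: %s.", paste(bad, collapse = ", ")))
  check_nonneg_vector(fractions$peak_dose_gy, "peak_dose_gy")
  if (any(!is.finite(fractions$angle_deg))) abort("`angle_deg` must be finite.")
  check_number(interval_hours, "interval_hours", lower = 0)
  fractions$angle_deg <- fractions$angle_deg %% 180
  structure(
    list(geometry = geometry, fractions = fractions, interval_hours = interval_hours),
    class = "fraction_plan"
  )
}

#' @export
print.fraction_plan <- function(x, ...) {
  cat(sprintf("<fraction_plan> %d fraction(s), %g h interval\n",
              nrow(x$fractions), x$interval_hours))
  print(x$fractions)
  invisible(x)
}

#' Canonical treatment-arm plans
#'
#' Builds the three temporally fractionated treatment arms compared in the
#' study: `"BB"` (uniform broad beam), `"MRT"` (overlapping microbeam fields,
#' all fractions at the same angle) and `"MRT+R"` (microbeam fields rotated
#' 45 degrees per fraction: 0, 45, 90, 135). `dose_gy` is the per-fraction
#' dose: the uniform dose for BB, the peak dose for the microbeam arms.
#'
#' @param modality One of `"BB"`, `"MRT"`, `"MRT+R"`.
#' @param dose_gy Per-fraction (peak) dose in Gy.
#' @param geometry A [microbeam_geometry()].
#' @param n_fractions Number of fractions (default 4).
#' @param interval_hours Inter-fraction interval (metadata).
#' @return A [fraction_plan()].
#' @examples
#' study_plan("MRT+R", dose_gy = 8, geometry = microbeam_geometry())
#' @export
study_plan <- function(modality = c("BB", "MRT", "MRT+R"), dose_gy,
                       geometry = microbeam_geometry(), n_fractions = 4,
                       interval_hours = 24) {
  modality <- match.arg(modality)
  check_number(dose_gy, "dose_gy", lower = 0)
  if (n_fractions < 1) abort("`n_fractions` must be >= 1.")
  angles <- switch(modality,
    "BB"    = rep(0, n_fractions),
    "MRT"   = rep(0, n_fractions),
    "MRT+R" = (seq_len(n_fractions) - 1) * 45
  )
  beam <- if (modality == "BB") "broad_beam" else "microbeam"
  fraction_plan(
    geometry,
    tibble::tibble(modality = beam, peak_dose_gy = dose_gy, angle_deg = angles),
    interval_hours = interval_hours
  )
}
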