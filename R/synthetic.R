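# Synthetic colony-formation-assay generator reproducing the study design:
# three treatment arms (BB, overlapping MRT, MRT rotated 45 deg/fraction),
# four daily fractions, 3 biological x 6 technical replicates, Poisson colony
# counts with LQ-governed survival.

#' Synthetic clonogenic-study design
#'
#' Describes a factorial colony-formation study: cell lines with true LQ
#' parameters and plating efficiencies, treatment arms, a per-fraction dose
#' ladder, and the replication structure. [simulate_study()] turns a design
#' into CFA records.
#'
#' @param cell_lines A data frame with columns `cell_line`, `alpha`, `beta`,
#'   `pe` (true plating efficiency as a fraction in (0, 1]).
#' @param modalities Character vector of arm labels understood by
#'   [study_plan()]: any of `"BB"`, `"MRT"`, `"MRT+R"`.
#' @param dose_levels_gy Per-fraction dose ladder, Gy, all > 0. With
#'   `match_bb = TRUE` (default) these are broad-beam fraction doses and the
#'   microbeam arms receive, per cell line, the peak dose whose spatial LQ
#'   survival equals the BB arm's at each ladder step — the equal-survival
#'   inverse planning used to set fraction sizes. With `match_bb = FALSE`
#'   the ladder is used directly as the per-fraction peak dose in every arm.
#' @param match_bb Match microbeam peak doses to the broad-beam ladder at
#'   equal planned survival (default `TRUE`).
#' @param n_bio,n_tech Biological and technical replicates per condition.
#' @param n_fractions Fractions per arm.
#' @param cells_seeded Optional fixed seeding count; by default a
#'   dose-dependent ladder is chosen so that the expected colony count stays
#'   near 120, clamped to \[100, 2000\] cells per well.
#' @param bio_sdlog Lognormal standard deviation of a per-biological-replicate
#'   multiplier on plating efficiency (0 = homogeneous replicates, default).
#' @param dispersion Optional negative-binomial size parameter; `NULL`
#'   (default) draws plain Poisson counts.
#' @param geometry A [microbeam_geometry()].
#' @param domain An [integration_domain()].
#' @param interval_hours Inter-fraction interval (metadata).
#' @param seed Master RNG seed (required, integer).
#' @return An object of class `study_design`.
#' @export
study_design <- function(cell_lines, modalities = c("BB", "MRT", "MRT+R"),
                         dose_levels_gy = c(0.5, 1, 1.5, 2), match_bb = TRUE,
                         n_bio = 3, n_tech = 6, n_fractions = 4,
                         cells_seeded = NULL, bio_sdlog = 0, dispersion = NULL,
                         geometry = microbeam_geometry(),
                         domain = integration_domain(),
                         interval_hours = 24, seed) {
  cell_lines <- tibble::as_tibble(cell_lines)
  needed <- c("cell_line", "alpha", "beta", "pe")
  if (!all(needed %in% names(cell_lines)) || nrow(cell_lines) == 0L) {
    abort("`cell_lines` must be a non-empty data frame with columns cell_line, alpha, beta, pe.")
  }
  if (any(cell_lines$pe <= 0 | cell_lines$pe > 1)) {
    abort("True plating efficiencies `pe` must lie in (0, 1].")
  }
  if (length(modalities) == 0L || length(dose_levels_gy) == 0L) {
    abort("`modalities` and `dose_levels_gy` must be non-empty.")
  }
  bad <- setdiff(modalities, c("BB", "MRT", "MRT+R"))
  if (length(bad)) abort(sprintf("Unknown modality label(s): %s.", paste(bad, collapse = ", ")))
  check_nonneg_vector(dose_levels_gy, "dose_levels_gy")
  if (any(dose_levels_gy == 0)) abort("`dose_levels_gy` are treated doses and must be > 0; 0 Gy controls are generated automatically.")
  if (n_bio < 1 || n_tech < 1) abort("`n_bio` and `n_tech` must be >= 1.")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("A single integer `seed` is required for reproducibility.")
  }
  structure(
    list(cell_lines = cell_lines, modalities = modalities,
         dose_levels_gy = dose_levels_gy, match_bb = isTRUE(match_bb),
         n_bio = n_bio, n_tech = n_tech,
         n_fractions = n_fractions, cells_seeded = cells_seeded,
         bio_sdlog = bio_sdlog, dispersion = dispersion,
         geometry = geometry, domain = domain,
         interval_hours = interval_hours, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d cell line(s) x %d arm(s) x %d dose(s) x %d bio x %d tech, %d fraction(s), seed %d\n",
    nrow(x$cell_lines), length(x$modalities), length(x$dose_levels_gy),
    x$n_bio, x$n_tech, x$n_fractions, x$seed))
  invisible(x)
}

#' Default study design: the two lung lines under the three arms
#'
#' A549 (alpha 0.29075, beta 0.01928) and MRC-5 (alpha 0.56606, beta 0.00004)
#' under BB, overlapping MRT and MRT+R; four fractions at 24 h; broad-beam
#' fraction ladder 0.5, 1, 1.5, 2 Gy with microbeam peak doses matched at
#' equal planned survival; 3 biological x 6 technical replicates. Plating
#' efficiencies default to 0.75 (A549) and 0.35 (MRC-5), typical clonogenic
#' values for these lines.
#'
#' @param seed Master RNG seed.
#' @param ... Overrides passed on to [study_design()].
#' @return A `study_design`.
#' @export
default_study_design <- function(seed, ...) {
  lines <- cell_line_params()
  lines$pe <- c(0.75, 0.35)
  args <- modifyList(list(cell_lines = lines, seed = seed), list(...))
  do.call(study_design, args)
}

#' Single-fraction broad-beam calibration design
#'
#' The uniform-exposure design used to calibrate LQ parameters: single
#' broad-beam fractions at 1, 2, 4, 6 and 8 Gy, 3 biological x 6 technical
#' replicates.
#'
#' @inheritParams default_study_design
#' @return A `study_design` with one BB arm and one fraction.
#' @export
lq_calibration_design <- function(seed, ...) {
  default_study_design(seed, modalities = "BB", n_fractions = 1,
                       dose_levels_gy = c(1, 2, 4, 6, 8), ...)
}

#' Planned conditions of a study design
#'
#' Expands a design into its treated conditions with the per-fraction dose
#' actually delivered in each arm and the planned (true) surviving fraction.
#' With `match_bb = TRUE`, microbeam arms carry the peak dose matched per
#' cell line to the broad-beam ladder at equal LQ survival.
#'
#' @param design A [study_design()].
#' @return A tibble: `cell_line`, `modality`, `ladder_gy` (BB ladder step),
#'   `dose_level_gy` (delivered per-fraction dose: BB dose or matched peak),
#'   `alpha`, `beta`, `pe`, `sf_true`.
#' @export
study_conditions <- function(design) {
  stopifnot(inherits(design, "study_design"))
  lines <- design$cell_lines
  conds <- tidyr::expand_grid(cell_line = lines$cell_line,
                              modality = design$modalities,
                              ladder_gy = design$dose_levels_gy) |>
    dplyr::inner_join(lines, by = "cell_line")
  n_fx <- design$n_fractions
  res <- purrr::pmap_dfr(
    conds[c("modality", "ladder_gy", "alpha", "beta")],
    function(modality, ladder_gy, alpha, beta) {
      pars <- lq_params(alpha, beta)
      if (modality != "BB" && design$match_bb) {
        target <- sf_uniform(pars, rep(ladder_gy, n_fx))
        angles <- if (modality == "MRT+R") (seq_len(n_fx) - 1) * 45
                  else rep(0, n_fx)
        peak <- peak_dose_for_target_sf(pars, design$geometry, angles, target,
                                        design$domain)
      } else {
        peak <- ladder_gy
      }
      sf <- sf_spatial(pars,
                       study_plan(modality, peak, design$geometry,
                                  n_fractions = n_fx,
                                  interval_hours = design$interval_hours),
                       design$domain)
      tibble::tibble(dose_level_gy = peak, sf_true = sf)
    })
  dplyr::bind_cols(conds, res)
}

# seeding ladder: aim at ~120 expected colonies, clamped to [100, 2000]
seeded_for_condition <- function(pe, sf) {
  raw <- 120 / (pe * sf)
  pmin(2000, pmax(100, 10 * ceiling(raw / 10)))
}

#' Simulate colony counts for one assay condition
#'
#' Colonies are drawn Poisson with mean
#' `seeded * pe_true * sf_spatial(truth, plan)` (or negative binomial with
#' the given dispersion). Uses the current RNG state; results are
#' deterministic given `set.seed()`.
#'
#' @param params True [lq_params()].
#' @param pe_true True plating efficiency, fraction in (0, 1].
#' @param plan A [fraction_plan()].
#' @param domain An [integration_domain()].
#' @param seeded Cells seeded per well (scalar or vector; one draw per
#'   element).
#' @param dispersion Optional negative-binomial size; `NULL` = Poisson.
#' @return Integer vector of simulated colony counts.
#' @export
simulate_cfa_counts <- function(params, pe_true, plan, domain, seeded,
                                dispersion = NULL) {
  check_number(pe_true, "pe_true", lower = 0, upper = 1, allow_equal_lower = FALSE)
  if (any(seeded <= 0)) abort("`seeded` must be positive.")
  sf <- sf_spatial(params, plan, domain)
  mu <- seeded * pe_true * sf
  if (is.null(dispersion)) rpois(length(mu), mu)
  else rnbinom(length(mu), size = dispersion, mu = mu)
}

#' Simulate a full clonogenic study
#'
#' Generates one CFA record per (cell line x modality x dose level x
#' biological x technical replicate) plus 0 Gy sham controls (modality
#' `"control"`) per cell line and biological replicate. Expected colony
#' counts follow the LQ spatial-survival model; counts are Poisson (or
#' negative binomial). Fully deterministic under the design's master seed:
#' the RNG stream is consumed in a documented canonical order
#' (per-biological-replicate PE effects first, then records ordered by cell
#' line, modality, dose, bio_rep, tech_rep).
#'
#' @param design A [study_design()].
#' @return A tibble of CFA records in the [read_cfa()] schema.
#' @examples
#' \donttest{
#' d <- default_study_design(seed = 1,
#'        domain = integration_domain(extent_mm = 1.5, resolution_um = 5))
#' records <- simulate_study(d)
#' }
#' @export
simulate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)

  lines <- design$cell_lines
  # biological-replicate PE multipliers, drawn first in canonical order
  bio <- tidyr::expand_grid(cell_line = lines$cell_line,
                            bio_rep = seq_len(design$n_bio))
  # mean-one lognormal multipliers so PE stays centered on its nominal value
  bio$pe_mult <- if (design$bio_sdlog > 0) {
    exp(rnorm(nrow(bio), -design$bio_sdlog^2 / 2, design$bio_sdlog))
  } else rep(1, nrow(bio))

  conds <- study_conditions(design)

  reps <- tidyr::expand_grid(bio_rep = seq_len(design$n_bio),
                             tech_rep = seq_len(design$n_tech))

  treated <- conds |>
    tidyr::expand_grid(reps) |>
    dplyr::left_join(bio, by = c("cell_line", "bio_rep")) |>
    dplyr::mutate(
      pe_eff = pmin(1, .data$pe * .data$pe_mult),
      cells_seeded = design$cells_seeded %||%
        seeded_for_condition(.data$pe, .data$sf_true)
    ) |>
    dplyr::arrange(.data$cell_line, .data$modality, .data$dose_level_gy,
                   .data$bio_rep, .data$tech_rep)

  controls <- tidyr::expand_grid(
    cell_line = lines$cell_line, bio_rep = seq_len(design$n_bio),
    tech_rep = seq_len(design$n_tech)
  ) |>
    dplyr::inner_join(lines, by = "cell_line") |>
    dplyr::left_join(bio, by = c("cell_line", "bio_rep")) |>
    dplyr::mutate(
      modality = "control", dose_level_gy = 0, sf_true = 1,
      pe_eff = pmin(1, .data$pe * .data$pe_mult),
      cells_seeded = design$cells_seeded %||% seeded_for_condition(.data$pe, 1)
    ) |>
    dplyr::arrange(.data$cell_line, .data$bio_rep, .data$tech_rep)

  all <- dplyr::bind_rows(controls, treated)
  mu <- all$cells_seeded * all$pe_eff * all$sf_true
  all$colonies <- if (is.null(design$dispersion)) {
    rpois(nrow(all), mu)
  } else {
    rnbinom(nrow(all), size = design$dispersion, mu = mu)
  }
  validate_cfa(all)
}
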