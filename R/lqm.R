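# Linear-quadratic survival of uniform and spatially modulated multi-fraction
# plans, and equivalent-uniform-dose (EUD) computation.
#
# Model: per-fraction cell kill exp(-(alpha d + beta d^2)), full repair of
# sublethal damage between 24 h fractions (the quadratic term acts per
# fraction), no migration or bystander coupling between fractions. For a
# spatially modulated plan the surviving fraction is the area-normalized mean
# over the dish of the per-point product over fractions.

# numerical contracts, used throughout
SF_TOL <- 1e-8    # |sf - target| tolerance for inverse planning
DOSE_TOL <- 1e-6  # Gy tolerance on dose roots

#' Linear-quadratic radiosensitivity parameters
#'
#' @param alpha Linear kill coefficient, per Gy, >= 0.
#' @param beta Quadratic kill coefficient, per Gy^2, >= 0. `alpha` and `beta`
#'   must not both be zero.
#' @return An object of class `lq_params`.
#' @export
lq_params <- function(alpha, beta) {
  check_number(alpha, "alpha", lower = 0)
  check_number(beta, "beta", lower = 0)
  if (alpha == 0 && beta == 0) abort("`alpha` and `beta` must not both be zero.")
  structure(list(alpha = alpha, beta = beta), class = "lq_params")
}

#' @export
print.lq_params <- function(x, ...) {
  cat(sprintf("<lq_params> alpha = %g /Gy, beta = %g /Gy^2 (alpha/beta = %g Gy)\n",
              x$alpha, x$beta, if (x$beta > 0) x$alpha / x$beta else Inf))
  invisible(x)
}

#' Reference LQ parameters for the two study cell lines
#'
#' Radiosensitivity of the lung adenocarcinoma line A549 and the normal lung
#' fibroblast line MRC-5, fitted from uniform single-dose clonogenic assays
#' at 1, 2, 4, 6 and 8 Gy.
#'
#' @return A tibble with columns `cell_line`, `alpha` (per Gy), `beta`
#'   (per Gy^2).
#' @examples
#' cell_line_params()
#' @export
cell_line_params <- function() {
  tibble::tibble(
    cell_line = c("A549", "MRC-5"),
    alpha = c(0.29075, 0.56606),
    beta = c(0.01928, 0.00004)
  )
}

#' Surviving fraction after uniform fractionated irradiation
#'
#' @param params An [lq_params()].
#' @param fraction_doses_gy Numeric vector of per-fraction uniform doses, Gy.
#' @return `exp(-sum(alpha d_i + beta d_i^2))`, in (0, 1].
#' @examples
#' sf_uniform(lq_params(0.29075, 0.01928), 2)
#' @export
sf_uniform <- function(params, fraction_doses_gy) {
  stopifnot(inherits(params, "lq_params"))
  check_nonneg_vector(fraction_doses_gy, "fraction_doses_gy")
  exp(-sum(params$alpha * fraction_doses_gy + params$beta * fraction_doses_gy^2))
}

# Per-plan dose moments on the grid: S1 = sum_i u_i, S2 = sum_i u_i^2 where
# D_i = p_i * u_i. With equal peak dose p across fractions the log-kill grid is
# alpha p S1 + beta p^2 S2, so dose sweeps and bisection reuse one rasterization.
plan_unit_moments <- function(geometry, modalities, angles, domain) {
  check_domain_in_field(domain, geometry)
  grids <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    if (modalities[i] == "broad_beam") {
      grids[[i]] <- 1
    } else {
      check_resolution_for_geometry(domain, geometry)
      key <- angles[i] %% 180
      prev <- which(modalities[seq_len(i - 1)] == "microbeam" &
                    (angles[seq_len(i - 1)] %% 180) == key)
      grids[[i]] <- if (length(prev)) grids[[prev[1]]] else
        fraction_unit_grid(geometry, key, domain)
    }
  }
  S1 <- Reduce(`+`, grids)
  S2 <- Reduce(`+`, lapply(grids, function(g) g^2))
  list(S1 = S1, S2 = S2)
}

#' Surviving fraction of a spatially modulated fractionated plan
#'
#' The area-normalized survival integral: the mean over grid points (x, y) of
#' `exp(-sum_i [alpha D_i(x,y) + beta D_i(x,y)^2])`, with the linear and
#' quadratic terms summed per fraction (full inter-fraction repair). Uniform
#' (broad-beam) plans reduce exactly to [sf_uniform()].
#'
#' @param params An [lq_params()].
#' @param plan A [fraction_plan()].
#' @param domain An [integration_domain()].
#' @return The surviving fraction, in (0, 1].
#' @export
sf_spatial <- function(params, plan, domain) {
  stopifnot(inherits(params, "lq_params"), inherits(plan, "fraction_plan"),
            inherits(domain, "integration_domain"))
  fr <- plan$fractions
  if (all(fr$modality == "broad_beam")) {
    return(sf_uniform(params, fr$peak_dose_gy))
  }
  check_domain_in_field(domain, plan$geometry)
  check_resolution_for_geometry(domain, plan$geometry)
  logkill <- 0
  unit_cache <- list()
  for (i in seq_len(nrow(fr))) {
    p <- fr$peak_dose_gy[i]
    if (fr$modality[i] == "broad_beam") {
      logkill <- logkill + (params$alpha * p + params$beta * p^2)
    } else {
      key <- sprintf("%.9f", fr$angle_deg[i] %% 180)
      if (is.null(unit_cache[[key]])) {
        unit_cache[[key]] <- fraction_unit_grid(plan$geometry, fr$angle_deg[i], domain)
      }
      u <- unit_cache[[key]]
      logkill <- logkill + params$alpha * p * u + params$beta * p^2 * u^2
    }
  }
  mask <- domain_mask(domain)
  if (!any(mask)) abort("Integration domain is empty.")
  if (length(logkill) == 1L) return(exp(-logkill))
  mean(exp(-logkill)[mask])
}

#' Equivalent uniform single-fraction dose for a surviving fraction
#'
#' Inverts the single-fraction LQ relation `sf = exp(-(alpha E + beta E^2))`:
#' the uniform dose that, delivered in one broad-beam fraction, gives the same
#' survival. With `L = -log(sf)` the nonnegative root of
#' `beta E^2 + alpha E - L = 0` is evaluated in the cancellation-stable form
#' `E = 2L / (alpha + sqrt(alpha^2 + 4 beta L))`, which passes continuously to
#' `L / alpha` as `beta -> 0` (MRC-5's beta of 4e-5 makes naive root formulas
#' ill-conditioned).
#'
#' @param params An [lq_params()].
#' @param sf Surviving fraction in (0, 1].
#' @return The equivalent uniform single-fraction dose in Gy.
#' @export
eud_single_fraction <- function(params, sf) {
  stopifnot(inherits(params, "lq_params"))
  if (!is.numeric(sf) || any(!is.finite(sf)) || any(sf <= 0) || any(sf > 1)) {
    abort("`sf` must lie in (0, 1].")
  }
  L <- -log(sf)
  2 * L / (params$alpha + sqrt(params$alpha^2 + 4 * params$beta * L))
}

#' Survival and equivalent uniform dose of a plan
#'
#' Composes [sf_spatial()] and [eud_single_fraction()]: the plan's surviving
#' fraction and the uniform single-fraction dose with the same survival.
#' Applies to broad-beam plans too, so a 4 x d Gy BB regime maps to its
#' single-fraction EUD.
#'
#' @param params An [lq_params()].
#' @param plan A [fraction_plan()].
#' @param domain An [integration_domain()].
#' @param plan_id Optional identifier carried into the output.
#' @return A one-row tibble: `plan_id`, `n_fractions`, `sf`,
#'   `eud_single_fraction_gy`.
#' @export
eud_of_plan <- function(params, plan, domain, plan_id = NA_character_) {
  sf <- sf_spatial(params, plan, domain)
  tibble::tibble(
    plan_id = plan_id,
    n_fractions = nrow(plan$fractions),
    sf = sf,
    eud_single_fraction_gy = eud_single_fraction(params, sf)
  )
}

#' Survival and EUD across a peak-dose sweep
#'
#' Evaluates an equal-peak-dose plan at many peak doses with a single
#' rasterization of the stripe pattern: the per-fraction unit-dose grids are
#' computed once and the LQ exponent rescaled per dose.
#'
#' @param params An [lq_params()].
#' @param geometry A [microbeam_geometry()].
#' @param angles_deg Per-fraction stripe angles, degrees (length = number of
#'   fractions).
#' @param peak_doses_gy Peak doses to evaluate, Gy.
#' @param domain An [integration_domain()].
#' @param modality `"microbeam"` (default) or `"broad_beam"`.
#' @return A tibble: `peak_dose_gy`, `sf`, `eud_single_fraction_gy`.
#' @export
eud_sweep <- function(params, geometry, angles_deg, peak_doses_gy, domain,
                      modality = "microbeam") {
  stopifnot(inherits(params, "lq_params"), inherits(geometry, "microbeam_geometry"))
  check_nonneg_vector(peak_doses_gy, "peak_doses_gy")
  mods <- rep(modality, length(angles_deg))
  mom <- plan_unit_moments(geometry, mods, angles_deg, domain)
  mask <- domain_mask(domain)
  sf <- vapply(peak_doses_gy, function(p) {
    lk <- params$alpha * p * mom$S1 + params$beta * p^2 * mom$S2
    if (length(lk) == 1L) exp(-lk) else mean(exp(-lk)[mask])
  }, numeric(1))
  tibble::tibble(peak_dose_gy = peak_doses_gy, sf = sf,
                 eud_single_fraction_gy = eud_single_fraction(params, sf))
}

#' Peak dose per fraction achieving a target survival
#'
#' Inverse planning: finds the equal per-fraction peak dose p such that the
#' n-fraction plan (stripe angles `angles_deg`, or uniform fields when
#' `modality = "broad_beam"`) has spatial survival equal to `target_sf`.
#' Solved by monotone bisection to `|sf - target| < 1e-8`; used to match the
#' microbeam arms to a broad-beam regime at equal cell survival.
#'
#' @param params An [lq_params()].
#' @param geometry A [microbeam_geometry()].
#' @param angles_deg Per-fraction stripe angles (degrees); its length sets the
#'   number of fractions.
#' @param target_sf Target surviving fraction, in (0, 1).
#' @param domain An [integration_domain()].
#' @param modality `"microbeam"` (default) or `"broad_beam"`.
#' @return The peak dose per fraction in Gy.
#' @export
peak_dose_for_target_sf <- function(params, geometry, angles_deg, target_sf,
                                    domain, modality = "microbeam") {
  stopifnot(inherits(params, "lq_params"), inherits(geometry, "microbeam_geometry"))
  check_number(target_sf, "target_sf", lower = 0, upper = 1,
               allow_equal_lower = FALSE, allow_equal_upper = FALSE)
  n <- length(angles_deg)
  if (n < 1) abort("At least one fraction angle is required.")
  mods <- rep(modality, n)
  mom <- plan_unit_moments(geometry, mods, angles_deg, domain)
  mask <- domain_mask(domain)
  sf_at <- function(p) {
    lk <- params$alpha * p * mom$S1 + params$beta * p^2 * mom$S2
    if (length(lk) == 1L) exp(-lk) else mean(exp(-lk)[mask])
  }
  hi <- 1
  while (sf_at(hi) > target_sf) {
    hi <- hi * 2
    if (hi > 1e6) abort("Target survival is not reachable at any finite peak dose.")
  }
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    s <- sf_at(mid)
    if (abs(s - target_sf) < SF_TOL || (hi - lo) < DOSE_TOL * 1e-3) break
    if (s > target_sf) lo <- mid else hi <- mid
  }
  mid
}
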