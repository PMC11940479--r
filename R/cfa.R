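# Colony-formation-assay reduction: plating efficiency, survival fraction,
# replicate aggregation and LQ parameter fitting.

CFA_COLUMNS <- c("cell_line", "modality", "dose_level_gy", "bio_rep",
                 "tech_rep", "cells_seeded", "colonies")

#' Plating efficiency
#'
#' Percentage of seeded cells that grow into colonies (a colony = at least 50
#' cells; the threshold is applied upstream, at counting).
#'
#' @param colonies Colonies counted, >= 0.
#' @param seeded Cells seeded, > 0.
#' @return `100 * colonies / seeded`, in percent. Vectorized.
#' @examples
#' plating_efficiency(30, 200) # 15 %
#' @export
plating_efficiency <- function(colonies, seeded) {
  if (any(!is.finite(seeded)) || any(seeded <= 0)) {
    abort("`seeded` must be positive counts.")
  }
  if (any(!is.finite(colonies)) || any(colonies < 0)) {
    abort("`colonies` must be nonnegative counts.")
  }
  100 * colonies / seeded
}

#' Survival fraction
#'
#' Colony yield after treatment normalized by seeding and by the unirradiated
#' control's plating efficiency:
#' `SF = colonies / (seeded * control_pe / 100)`.
#'
#' @param colonies Colonies counted after treatment.
#' @param seeded Cells seeded, > 0.
#' @param control_pe Plating efficiency of the matching unirradiated control,
#'   in percent, > 0.
#' @return The surviving fraction. Vectorized.
#' @examples
#' survival_fraction(20, 400, 50) # 0.1
#' @export
survival_fraction <- function(colonies, seeded, control_pe) {
  if (any(!is.finite(control_pe)) || any(control_pe <= 0)) {
    abort("`control_pe` must be positive (percent).")
  }
  plating_efficiency(colonies, seeded) / control_pe
}

#' Read / write colony-formation-assay records
#'
#' CSV schema (header required):
#' `cell_line,modality,dose_level_gy,bio_rep,tech_rep,cells_seeded,colonies`.
#' Rows with `dose_level_gy == 0` are unirradiated controls. Schema violations
#' are reported with row numbers.
#'
#' @param path CSV file path.
#' @return A tibble of CFA records.
#' @export
read_cfa <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE)
  validate_cfa(records)
}

#' @rdname read_cfa
#' @param records A tibble of CFA records.
#' @export
write_cfa <- function(records, path) {
  readr::write_csv(validate_cfa(records), path)
  invisible(path)
}

validate_cfa <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(CFA_COLUMNS, names(records))
  if (length(missing)) {
    abort(sprintf("CFA records are missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  bad_seed <- which(!is.finite(records$cells_seeded) | records$cells_seeded <= 0)
  if (length(bad_seed)) {
    abort(sprintf("`cells_seeded` must be > 0; offending row(s): %s.",
                  paste(utils::head(bad_seed, 5), collapse = ", ")))
  }
  bad_col <- which(!is.finite(records$colonies) | records$colonies < 0)
  if (length(bad_col)) {
    abort(sprintf("`colonies` must be >= 0; offending row(s): %s.",
                  paste(utils::head(bad_col, 5), collapse = ", ")))
  }
  bad_dose <- which(!is.finite(records$dose_level_gy) | records$dose_level_gy < 0)
  if (length(bad_dose)) {
    abort(sprintf("`dose_level_gy` must be >= 0; offending row(s): %s.",
                  paste(utils::head(bad_dose, 5), collapse = ", ")))
  }
  records[CFA_COLUMNS]
}

# per-(cell_line, bio_rep) control plating efficiency (mean over control wells)
control_pe_table <- function(records) {
  controls <- dplyr::filter(records, .data$dose_level_gy == 0)
  if (nrow(controls) == 0L) abort("No unirradiated (0 Gy) control rows found.")
  controls |>
    dplyr::group_by(.data$cell_line, .data$bio_rep) |>
    dplyr::summarise(
      control_pe = mean(plating_efficiency(.data$colonies, .data$cells_seeded)),
      .groups = "drop"
    )
}

#' Reduce CFA records to replicate-level survival observations
#'
#' Computes the plating efficiency of each biological replicate from its own
#' 0 Gy control wells, normalizes every treated well to its replicate's PE,
#' and attaches the equivalent uniform single-fraction dose of each
#' (cell line, modality, dose level) condition via the LQ model.
#'
#' @param records CFA records (see [read_cfa()] for the schema).
#' @param params LQ parameters per cell line: a data frame with columns
#'   `cell_line`, `alpha`, `beta` (default [cell_line_params()]).
#' @param geometry A [microbeam_geometry()] for the microbeam arms.
#' @param domain An [integration_domain()].
#' @param plan_for A function `(modality, dose_gy)` returning a
#'   [fraction_plan()]; defaults to [study_plan()] with 4 fractions, mapping
#'   labels `"BB"`, `"MRT"`, `"MRT+R"`.
#' @param n_fractions Fractions per arm for the default plan builder.
#' @return A tibble with one row per treated well: `cell_line`, `modality`,
#'   `dose_level_gy`, `bio_rep`, `tech_rep`, `sf`, `eud_gy`.
#' @export
reduce_cfa <- function(records, params = cell_line_params(),
                       geometry = microbeam_geometry(),
                       domain = integration_domain(),
                       plan_for = NULL, n_fractions = 4) {
  records <- validate_cfa(records)
  plan_for <- plan_for %||% function(modality, dose_gy) {
    study_plan(modality, dose_gy, geometry, n_fractions = n_fractions)
  }
  pe <- control_pe_table(records)
  treated <- dplyr::filter(records, .data$dose_level_gy > 0)
  if (nrow(treated) == 0L) abort("No treated (dose > 0) records found.")

  missing <- dplyr::anti_join(
    dplyr::distinct(treated, .data$cell_line, .data$bio_rep),
    pe, by = c("cell_line", "bio_rep")
  )
  if (nrow(missing)) {
    abort(sprintf(
      "Missing 0 Gy control for biological replicate(s): %s.",
      paste(sprintf("%s/bio_rep %s", missing$cell_line, missing$bio_rep),
            collapse = ", ")))
  }

  # EUD per condition (one spatial integral per modality x dose x cell line)
  conds <- dplyr::distinct(treated, .data$cell_line, .data$modality,
                           .data$dose_level_gy) |>
    dplyr::inner_join(tibble::as_tibble(params), by = "cell_line")
  if (nrow(conds) < dplyr::n_distinct(treated$cell_line, treated$modality,
                                      treated$dose_level_gy)) {
    abort("`params` must provide alpha/beta for every cell line in the records.")
  }
  conds <- conds |>
    dplyr::mutate(eud_gy = purrr::pmap_dbl(
      list(.data$modality, .data$dose_level_gy, .data$alpha, .data$beta),
      function(modality, dose, alpha, beta) {
        pl <- plan_for(modality, dose)
        eud_single_fraction(lq_params(alpha, beta), sf_spatial(lq_params(alpha, beta), pl, domain))
      })) |>
    dplyr::select("cell_line", "modality", "dose_level_gy", "eud_gy")

  treated |>
    dplyr::inner_join(pe, by = c("cell_line", "bio_rep")) |>
    dplyr::mutate(sf = survival_fraction(.data$colonies, .data$cells_seeded,
                                         .data$control_pe)) |>
    dplyr::inner_join(conds, by = c("cell_line", "modality", "dose_level_gy")) |>
    dplyr::select("cell_line", "modality", "dose_level_gy", "bio_rep",
                  "tech_rep", "sf", "eud_gy") |>
    dplyr::arrange(.data$cell_line, .data$modality, .data$dose_level_gy,
                   .data$bio_rep, .data$tech_rep)
}

#' Aggregate replicate-level survival into per-condition survival points
#'
#' @inheritParams reduce_cfa
#' @return A tibble with one row per (cell line, modality, dose level):
#'   `eud_gy`, `sf_mean`, `sf_sem`, `n`.
#' @export
summarize_replicates <- function(records, params = cell_line_params(),
                                 geometry = microbeam_geometry(),
                                 domain = integration_domain(),
                                 plan_for = NULL, n_fractions = 4) {
  reduce_cfa(records, params, geometry, domain, plan_for, n_fractions) |>
    dplyr::group_by(.data$cell_line, .data$modality, .data$dose_level_gy,
                    .data$eud_gy) |>
    dplyr::summarise(
      sf_mean = mean(.data$sf),
      sf_sem = if (dplyr::n() > 1) sd(.data$sf) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Fit linear-quadratic parameters to survival data
#'
#' Least-squares fit of `-log(sf) = alpha * dose + beta * dose^2` (no
#' intercept) with nonnegativity enforced by projection: if the unconstrained
#' estimate of one parameter is negative it is clamped to zero and the other
#' refitted. Standard errors and the covariance come from the unconstrained
#' fit.
#'
#' @param data A data frame of survival observations.
#' @param dose,sf Column names (tidy-eval) holding dose in Gy and surviving
#'   fraction; defaults `dose_gy` and `sf`.
#' @param weights Optional numeric vector of weights on the `-log(sf)` scale
#'   (e.g. `1/sem^2`); default unweighted.
#' @return An object of class `lq_fit` with elements `params` ([lq_params()]),
#'   `se_alpha`, `se_beta`, `unconstrained` (the pre-projection estimates),
#'   `cov` (2x2, unconstrained), `clamped`, `n`, and the underlying data.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- data.frame(dose_gy = c(1, 2, 4, 6, 8),
#'                 sf = exp(-(0.29 * c(1, 2, 4, 6, 8) + 0.019 * c(1, 2, 4, 6, 8)^2)))
#' fit_lq(d)
#' @export
fit_lq <- function(data, dose = dose_gy, sf = sf, weights = NULL) {
  df <- tibble::tibble(
    dose = dplyr::pull(data, {{ dose }}),
    sf = dplyr::pull(data, {{ sf }})
  )
  # noisy replicate-level SF can exceed 1 (a lucky well against a modest
  # control); such wells stay in the fit with a negative -log(sf)
  if (any(!is.finite(df$sf)) || any(df$sf <= 0)) {
    abort("All `sf` values must be > 0 for the log-linear LQ fit.")
  }
  check_nonneg_vector(df$dose, "dose")
  if (length(unique(df$dose[df$dose > 0])) < 2L) {
    abort("At least 2 distinct positive doses are required (fit is underdetermined).")
  }
  df$nlsf <- -log(df$sf)
  df$dose2 <- df$dose^2
  w <- weights %||% rep(1, nrow(df))
  fit <- lm(nlsf ~ 0 + dose + dose2, data = df, weights = w)
  est <- coef(fit)
  # vcov via summary.lm warns on an exactly interpolating (noiseless) fit
  cv <- suppressWarnings(vcov(fit))
  alpha <- unname(est["dose"]); beta <- unname(est["dose2"])
  clamped <- "none"
  if (beta < 0) {
    clamped <- "beta"
    beta <- 0
    alpha <- max(0, unname(coef(lm(nlsf ~ 0 + dose, data = df, weights = w))["dose"]))
  } else if (alpha < 0) {
    clamped <- "alpha"
    alpha <- 0
    beta <- max(0, unname(coef(lm(nlsf ~ 0 + dose2, data = df, weights = w))["dose2"]))
  }
  if (alpha == 0 && beta == 0) {
    abort("Degenerate fit: both alpha and beta are zero (no measurable kill).")
  }
  structure(
    list(params = lq_params(alpha, beta),
         se_alpha = sqrt(cv[1, 1]), se_beta = sqrt(cv[2, 2]),
         unconstrained = c(alpha = unname(est["dose"]),
                           beta = unname(est["dose2"])),
         cov = cv, clamped = clamped, n = nrow(df),
         sigma = sigma(fit), data = df),
    class = "lq_fit"
  )
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf(
    "<lq_fit> alpha = %.5f +/- %.5f /Gy, beta = %.5f +/- %.5f /Gy^2 (n = %d%s)\n",
    x$params$alpha, x$se_alpha, x$params$beta, x$se_beta, x$n,
    if (x$clamped != "none") paste0(", ", x$clamped, " clamped at 0") else ""))
  invisible(x)
}

#' @export
tidy.lq_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$params$alpha, x$params$beta),
    std.error = c(x$se_alpha, x$se_beta)
  )
}

#' @export
glance.lq_fit <- function(x, ...) {
  pred <- x$params$alpha * x$data$dose + x$params$beta * x$data$dose^2
  tibble::tibble(
    n = x$n,
    sigma = x$sigma,
    rmse_log = sqrt(mean((x$data$nlsf - pred)^2)),
    clamped = x$clamped
  )
}

#' @export
autoplot.lq_fit <- function(object, ...) {
  dd <- seq(0, max(object$data$dose), length.out = 200)
  curve <- tibble::tibble(
    dose = dd,
    sf = exp(-(object$params$alpha * dd + object$params$beta * dd^2))
  )
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dose, .data$sf)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, color = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Dose (Gy)", y = "Surviving fraction")
}
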