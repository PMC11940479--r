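# Reproducible simulate -> reduce -> fit -> EUD -> compare workflow driven by
# a single structured config file. Every artifact directory carries a
# manifest (config hash + seed + package version) so runs are a pure function
# of (config, seed).

#' Read and validate a run configuration
#'
#' The config is YAML or JSON with a versioned schema:
#' `schema_version`, `seed`, and blocks `geometry` (slit_width_um, pitch_um,
#' pvdr, field_size_mm, penumbra_um), `domain` (shape, extent_mm,
#' resolution_um, center_mm), `plan` (n_fractions, interval_hours), `design`
#' (cell_lines, modalities, dose_levels_gy, n_bio, n_tech, bio_sdlog,
#' cells_seeded) and `analysis` (response, dose_range, alpha_level, adjust).
#' Omitted keys fall back to package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return An object of class `run_config` holding the parsed blocks and the
#'   constructed [microbeam_geometry()], [integration_domain()] and
#'   [study_design()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build_run_config(raw)
}

build_run_config <- function(raw) {
  if (is.null(raw$schema_version)) abort("Config must carry a `schema_version` key.")
  if (is.null(raw$seed)) abort("Config must carry a master `seed` key.")

  geometry <- do.call(microbeam_geometry, raw$geometry %||% list())
  dom_args <- raw$domain %||% list()
  domain <- do.call(integration_domain, dom_args)

  plan_block <- raw$plan %||% list()
  n_fractions <- plan_block$n_fractions %||% 4
  interval_hours <- plan_block$interval_hours %||% 24

  dsn <- raw$design %||% list()
  cell_lines <- if (!is.null(dsn$cell_lines)) {
    dplyr::bind_rows(lapply(dsn$cell_lines, tibble::as_tibble))
  } else {
    cl <- cell_line_params(); cl$pe <- c(0.75, 0.35); cl
  }
  design <- study_design(
    cell_lines = cell_lines,
    modalities = dsn$modalities %||% c("BB", "MRT", "MRT+R"),
    dose_levels_gy = dsn$dose_levels_gy %||% c(0.5, 1, 1.5, 2),
    match_bb = dsn$match_bb %||% TRUE,
    n_bio = dsn$n_bio %||% 3, n_tech = dsn$n_tech %||% 6,
    n_fractions = n_fractions,
    cells_seeded = dsn$cells_seeded,
    bio_sdlog = dsn$bio_sdlog %||% 0,
    dispersion = dsn$dispersion,
    geometry = geometry, domain = domain,
    interval_hours = interval_hours,
    seed = raw$seed
  )
  ana <- raw$analysis %||% list()
  analysis <- list(
    response = ana$response %||% "log",
    dose_range = if (!is.null(ana$dose_range)) as.numeric(ana$dose_range),
    alpha_level = ana$alpha_level %||% 0.05,
    adjust = ana$adjust %||% "none"
  )
  structure(
    list(raw = raw, schema_version = raw$schema_version, seed = raw$seed,
         geometry = geometry, domain = domain, design = design,
         analysis = analysis, n_fractions = n_fractions),
    class = "run_config"
  )
}

#' Default run configuration
#'
#' The package's built-in configuration (the study's three arms with the
#' default design), useful as a template and for end-to-end tests.
#'
#' @param seed Master seed.
#' @param ... Top-level overrides merged into the raw config list.
#' @return A `run_config`.
#' @export
default_run_config <- function(seed = 1, ...) {
  raw <- modifyList(list(schema_version = 1, seed = seed), list(...))
  build_run_config(raw)
}

run_manifest <- function(config, files, seed) {
  list(
    schema_version = config$schema_version,
    config_hash = rlang::hash(config$raw),
    seed = seed,
    package = "mrtfrac",
    package_version = as.character(packageVersion("mrtfrac")),
    files = files
  )
}

write_manifest_log <- function(out_dir, manifest, log_lines) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))
}

prepare_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory: %s", out_dir))
  }
  if (file.access(out_dir, mode = 2) != 0) {
    abort(sprintf("Output directory is not writable: %s", out_dir))
  }
  invisible(out_dir)
}

#' Simulate a study and write its records
#'
#' Writes `cfa_records.csv`, `manifest.json` (config hash, seed, package
#' version) and `run.log` to `out_dir`. Byte-identical across runs for a
#' fixed config and seed.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override; defaults to the config's seed.
#' @param verbose Emit progress messages.
#' @return The records tibble, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  prepare_out_dir(out_dir)
  seed <- seed %||% config$seed
  design <- config$design
  design$seed <- as.integer(seed)
  records <- simulate_study(design)
  path <- file.path(out_dir, "cfa_records.csv")
  write_cfa(records, path)
  log_lines <- c(
    sprintf("simulate: seed %d", seed),
    sprintf("simulate: %d records (%d treated, %d controls)",
            nrow(records), sum(records$dose_level_gy > 0),
            sum(records$dose_level_gy == 0)),
    sprintf("simulate: wrote %s", path)
  )
  if (verbose) for (l in log_lines) message(l)
  write_manifest_log(out_dir, run_manifest(config, "cfa_records.csv", seed),
                     log_lines)
  invisible(records)
}

#' Analyze CFA records: reduction, LQ fit, EUD attachment, ANCOVA
#'
#' Runs the full reduction on a records file: replicate-level survival with
#' EUD (`survival_points.csv` holds the per-condition summary,
#' `survival_replicates.csv` the replicate level), LQ parameters fitted per
#' cell line from the broad-beam arm on the per-fraction survival scale
#' (`lq_fit.csv`), pairwise ANCOVA per cell line (`significance.csv`), and a
#' survival-curve figure (`survival_curves.png`).
#'
#' @param config A `run_config`.
#' @param records_path Path to a CFA records CSV (defaults to
#'   `cfa_records.csv` in `out_dir`).
#' @param out_dir Output directory.
#' @param verbose Emit progress messages.
#' @return A list with elements `points`, `summary`, `fits`, `comparison`,
#'   invisibly.
#' @export
run_analyze <- function(config, out_dir,
                        records_path = file.path(out_dir, "cfa_records.csv"),
                        verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  prepare_out_dir(out_dir)
  records <- read_cfa(records_path)
  params <- config$design$cell_lines[c("cell_line", "alpha", "beta")]

  points <- reduce_cfa(records, params, config$geometry, config$domain,
                       n_fractions = config$n_fractions)
  summary <- points |>
    dplyr::group_by(.data$cell_line, .data$modality, .data$dose_level_gy,
                    .data$eud_gy) |>
    dplyr::summarise(sf_mean = mean(.data$sf),
                     sf_sem = if (dplyr::n() > 1) sd(.data$sf) / sqrt(dplyr::n()) else 0,
                     n = dplyr::n(), .groups = "drop")
  readr::write_csv(points, file.path(out_dir, "survival_replicates.csv"))
  readr::write_csv(summary, file.path(out_dir, "survival_points.csv"))

  # LQ calibration from the broad-beam arm, reduced to per-fraction survival
  fits <- NULL
  bb <- dplyr::filter(points, .data$modality == "BB", .data$sf > 0)
  if (nrow(bb) > 0) {
    n_fx <- config$n_fractions
    fits <- bb |>
      dplyr::mutate(sf_fx = .data$sf^(1 / n_fx)) |>
      dplyr::group_by(.data$cell_line) |>
      dplyr::group_modify(function(df, key) {
        f <- fit_lq(df, dose = dose_level_gy, sf = sf_fx)
        tibble::tibble(alpha = f$params$alpha, beta = f$params$beta,
                       se_alpha = f$se_alpha, se_beta = f$se_beta,
                       n = f$n, clamped = f$clamped)
      }) |>
      dplyr::ungroup()
    readr::write_csv(fits, file.path(out_dir, "lq_fit.csv"))
  }

  # wells with zero colonies carry no information on the log scale
  n_zero <- sum(points$sf <= 0)
  cmp_points <- if (config$analysis$response == "log") {
    dplyr::filter(points, .data$sf > 0)
  } else points
  cmp <- NULL
  if (dplyr::n_distinct(cmp_points$modality) >= 2L) {
    cmp <- ancova_pairwise(cmp_points, response = config$analysis$response,
                           dose_range = config$analysis$dose_range,
                           alpha_level = config$analysis$alpha_level,
                           adjust = config$analysis$adjust)
    readr::write_csv(significance_table(cmp), file.path(out_dir, "significance.csv"))
  }

  fig <- plot_survival_curves(summary)
  ggplot2::ggsave(file.path(out_dir, "survival_curves.png"), fig,
                  width = 8, height = 4.5, dpi = 150)

  log_lines <- c(
    sprintf("analyze: %d replicate observations, %d conditions",
            nrow(points), nrow(summary)),
    if (!is.null(fits)) sprintf("analyze: LQ fit for %d cell line(s)", nrow(fits))
    else "analyze: no BB arm found, LQ fit skipped",
    if (!is.null(cmp))
      sprintf("analyze: %d pairwise ANCOVA test(s)%s", nrow(cmp$pairs),
              if (n_zero > 0)
                sprintf(" (%d zero-colony well(s) excluded from the log-scale model)", n_zero)
              else "")
    else "analyze: fewer than 2 arms, ANCOVA skipped",
    "analyze: wrote survival_replicates.csv, survival_points.csv, lq_fit.csv, significance.csv, survival_curves.png"
  )
  if (verbose) for (l in log_lines) message(l)
  write_manifest_log(
    out_dir,
    run_manifest(config, c("survival_replicates.csv", "survival_points.csv",
                           "lq_fit.csv", "significance.csv",
                           "survival_curves.png"), config$seed),
    log_lines)
  invisible(list(points = points, summary = summary, fits = fits,
                 comparison = cmp))
}

#' Match microbeam peak doses to a broad-beam regime at equal survival
#'
#' For each cell line and microbeam arm, finds the per-fraction peak dose
#' whose spatial LQ survival equals that of the broad-beam regime at each of
#' its dose levels (inverse planning at equal cell survival). Writes
#' `matched_peak_doses.csv`.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @param bb_doses_gy Per-fraction broad-beam doses to match; defaults to the
#'   design's dose ladder.
#' @param verbose Emit progress messages.
#' @return The matched-dose tibble, invisibly: `cell_line`, `modality`,
#'   `bb_dose_gy`, `target_sf`, `peak_dose_gy`, `eud_single_fraction_gy`.
#' @export
run_plan <- function(config, out_dir, bb_doses_gy = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  prepare_out_dir(out_dir)
  bb_doses_gy <- bb_doses_gy %||% config$design$dose_levels_gy
  mods <- setdiff(config$design$modalities, "BB")
  if (length(mods) == 0L) abort("No microbeam arm in the design to plan for.")
  n_fx <- config$n_fractions
  grid <- tidyr::expand_grid(
    cell_line = config$design$cell_lines$cell_line,
    modality = mods, bb_dose_gy = bb_doses_gy
  ) |>
    dplyr::inner_join(config$design$cell_lines[c("cell_line", "alpha", "beta")],
                      by = "cell_line")
  out <- grid |>
    dplyr::mutate(purrr::pmap_dfr(
      list(.data$modality, .data$bb_dose_gy, .data$alpha, .data$beta),
      function(modality, bb_dose, alpha, beta) {
        pars <- lq_params(alpha, beta)
        target <- sf_uniform(pars, rep(bb_dose, n_fx))
        angles <- if (modality == "MRT+R") (seq_len(n_fx) - 1) * 45 else rep(0, n_fx)
        peak <- peak_dose_for_target_sf(pars, config$geometry, angles, target,
                                        config$domain)
        tibble::tibble(target_sf = target, peak_dose_gy = peak,
                       eud_single_fraction_gy = eud_single_fraction(pars, target))
      })) |>
    dplyr::select("cell_line", "modality", "bb_dose_gy", "target_sf",
                  "peak_dose_gy", "eud_single_fraction_gy")
  readr::write_csv(out, file.path(out_dir, "matched_peak_doses.csv"))
  log_lines <- c(sprintf("plan: matched %d (cell line x arm x dose) combinations", nrow(out)),
                 "plan: wrote matched_peak_doses.csv")
  if (verbose) for (l in log_lines) message(l)
  write_manifest_log(out_dir, run_manifest(config, "matched_peak_doses.csv",
                                           config$seed), log_lines)
  invisible(out)
}

#' Run the full pipeline: simulate, analyze, plan
#'
#' @inheritParams run_simulate
#' @return The [run_analyze()] result list, invisibly.
#' @export
run_all <- function(config, out_dir, seed = NULL, verbose = FALSE) {
  run_simulate(config, out_dir, seed = seed, verbose = verbose)
  res <- run_analyze(config, out_dir, verbose = verbose)
  plan <- tryCatch(run_plan(config, out_dir, verbose = verbose),
                   error = function(e) NULL)
  invisible(c(res, list(plan = plan)))
}

#' Survival-curve figure
#'
#' Per-condition mean survival (log scale) against equivalent uniform
#' single-fraction dose, one panel per cell line, colored by treatment arm,
#' with standard-error bars.
#'
#' @param summary A per-condition summary as from [summarize_replicates()].
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(.data$eud_gy, .data$sf_mean,
                                        color = .data$modality)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sf_mean - .data$sf_sem,
                                        ymax = .data$sf_mean + .data$sf_sem),
                           width = 0.15) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~cell_line, scales = "free") +
    ggplot2::labs(x = "Equivalent uniform dose, single fraction (Gy)",
                  y = "Surviving fraction", color = "Arm")
}
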