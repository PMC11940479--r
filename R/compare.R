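# ANCOVA-style pairwise comparison of survival curves across treatment arms.
#
# For each pair of arms a common-slope linear model
#   response = b0 + b1 * EUD + b2 * arm
# is fitted on replicate-level observations (response = log SF by default,
# variance-stabilizing for survival curves) and the arm term is tested by a
# partial F test against the slope-only model. An interaction model gives a
# secondary p-value for a slope difference.

#' Pairwise ANCOVA comparison of survival curves
#'
#' @param points Replicate-level survival observations: a data frame with
#'   columns `cell_line`, `modality`, `eud_gy`, `sf` (as produced by
#'   [reduce_cfa()]). Each cell line is analyzed separately.
#' @param response `"log"` (default, models `log(sf)`) or `"identity"`.
#' @param dose_range Optional length-2 numeric: keep only observations with
#'   `eud_gy` inside `[dose_range[1], dose_range[2]]` before testing.
#' @param alpha_level Significance level used for starring (default 0.05).
#' @param adjust `"none"` (default; raw pairwise p-values) or `"holm"`,
#'   applied within cell line.
#' @return An object of class `mrt_ancova`; [tidy()] returns the pair table
#'   (`cell_line`, `group1`, `group2`, `n`, `f_statistic`, `df1`, `df2`,
#'   `p_value`, `p_slope`), [glance()] a one-row model descriptor,
#'   [significance_table()] the matrix layout with star markers.
#' @export
ancova_pairwise <- function(points, response = c("log", "identity"),
                            dose_range = NULL, alpha_level = 0.05,
                            adjust = c("none", "holm")) {
  response <- match.arg(response)
  adjust <- match.arg(adjust)
  points <- tibble::as_tibble(points)
  needed <- c("cell_line", "modality", "eud_gy", "sf")
  if (!all(needed %in% names(points))) {
    abort(sprintf("`points` must have columns %s.",
                  paste0("`", needed, "`", collapse = ", ")))
  }
  if (!is.null(dose_range)) {
    if (length(dose_range) != 2L) abort("`dose_range` must be length 2 (Gy).")
    points <- dplyr::filter(points, .data$eud_gy >= dose_range[1],
                            .data$eud_gy <= dose_range[2])
  }
  if (nrow(points) == 0L) {
    abort("No observations to compare (after any dose-range filtering).")
  }
  if (response == "log") {
    bad <- which(points$sf <= 0)
    if (length(bad)) {
      abort(sprintf(
        "log-scale response requires sf > 0; offending record(s) (row in `points`): %s.",
        paste(utils::head(bad, 5), collapse = ", ")))
    }
    points$y <- log(points$sf)
  } else {
    points$y <- points$sf
  }

  pairs <- points |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::group_modify(function(df, key) {
      mods <- unique(df$modality)
      if (length(mods) < 2L) {
        abort(sprintf("Cell line %s has fewer than 2 modalities.", key$cell_line))
      }
      combos <- utils::combn(sort(mods), 2, simplify = FALSE)
      purrr::map_dfr(combos, function(pr) {
        sub <- dplyr::filter(df, .data$modality %in% pr)
        counts <- table(sub$modality)
        if (any(counts < 3)) {
          abort(sprintf("Each modality needs >= 3 observations (%s vs %s).",
                        pr[1], pr[2]))
        }
        if (length(unique(sub$eud_gy)) < 2L) {
          abort(sprintf(
            "Singular design for %s vs %s: only one dose (EUD) level present.",
            pr[1], pr[2]))
        }
        full <- lm(y ~ eud_gy + modality, data = sub)
        reduced <- lm(y ~ eud_gy, data = sub)
        an <- anova(reduced, full)
        inter <- lm(y ~ eud_gy * modality, data = sub)
        an_i <- anova(full, inter)
        tibble::tibble(
          group1 = pr[1], group2 = pr[2], n = nrow(sub),
          f_statistic = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
          p_value = an$`Pr(>F)`[2], p_slope = an_i$`Pr(>F)`[2]
        )
      })
    }) |>
    dplyr::ungroup()

  if (adjust == "holm") {
    pairs <- pairs |>
      dplyr::group_by(.data$cell_line) |>
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup()
  }

  structure(
    list(pairs = pairs,
         model = list(response = if (response == "log") "log(sf)" else "sf",
                      covariate = "eud_gy", slope = "common"),
         alpha_level = alpha_level, dose_range = dose_range, adjust = adjust),
    class = "mrt_ancova"
  )
}

#' @export
print.mrt_ancova <- function(x, ...) {
  cat(sprintf("<mrt_ancova> %s ~ %s + arm (common slope), alpha = %g%s\n",
              x$model$response, x$model$covariate, x$alpha_level,
              if (!is.null(x$dose_range))
                sprintf(", EUD in [%g, %g] Gy", x$dose_range[1], x$dose_range[2])
              else ""))
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.mrt_ancova <- function(x, ...) x$pairs

#' @export
glance.mrt_ancova <- function(x, ...) {
  tibble::tibble(
    response = x$model$response, covariate = x$model$covariate,
    slope = x$model$slope, alpha_level = x$alpha_level,
    n_pairs = nrow(x$pairs), adjust = x$adjust
  )
}

# star annotation: p <= 0.001 "**", p <= 0.05 "*"
p_stars <- function(p, alpha_level = 0.05) {
  dplyr::case_when(p <= 0.001 ~ " **", p <= alpha_level ~ " *", TRUE ~ "")
}

#' Significance matrix with star markers
#'
#' Formats the pairwise p-values as a symmetric modality-by-modality matrix,
#' one per cell line, with `*` marking p <= 0.05 and `**` marking p <= 0.001.
#'
#' @param result An `mrt_ancova` from [ancova_pairwise()].
#' @return A tibble in wide layout: columns `cell_line`, `modality`, then one
#'   column per modality holding strings like `"0.032 *"` (diagonal `"-"`).
#' @export
significance_table <- function(result) {
  stopifnot(inherits(result, "mrt_ancova"))
  fmt <- function(p) paste0(formatC(p, format = "g", digits = 3),
                            p_stars(p, result$alpha_level))
  long <- result$pairs |>
    dplyr::transmute(.data$cell_line, .data$group1, .data$group2,
                     cell = fmt(.data$p_value))
  both <- dplyr::bind_rows(
    dplyr::rename(long, modality = "group1", other = "group2"),
    dplyr::rename(long, modality = "group2", other = "group1")
  )
  diag <- both |>
    dplyr::distinct(.data$cell_line, .data$modality) |>
    dplyr::mutate(other = .data$modality, cell = "-")
  dplyr::bind_rows(both, diag) |>
    dplyr::arrange(.data$cell_line, .data$modality, .data$other) |>
    tidyr::pivot_wider(names_from = "other", values_from = "cell")
}
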