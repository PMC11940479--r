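#' @importFrom rlang abort warn %||%
#' @importFrom stats lm anova coef vcov sd rnorm rpois rnbinom runif sigma
#' @importFrom utils modifyList packageVersion
NULL

# scalar numeric check with a readable diagnostic
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside its valid range %s%g, %g%s.",
      name, x,
      if (allow_equal_lower) "[" else "(", lower, upper,
      if (allow_equal_upper) "]" else ")"
    ))
  }
  invisible(x)
}

check_nonneg_vector <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort(sprintf("`%s` must be a non-empty numeric vector.", name))
  }
  if (any(!is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  if (any(x < 0)) {
    abort(sprintf("`%s` contains negative values (doses must be >= 0 Gy).", name))
  }
  invisible(x)
}
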