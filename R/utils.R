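# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so seeded generators are pure
#' functions of (parameters, seed).
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simple ordinary least squares of y on x, returned as a plain list
#' @noRd
ols <- function(x, y) {
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact data ("essentially perfect fit"); exact data
  # are routine here (noiseless generators), so muffle that warning only
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  list(
    intercept = unname(stats::coef(fit)[1L]),
    slope = unname(stats::coef(fit)[2L]),
    se_intercept = unname(s$coefficients[1L, 2L]),
    se_slope = if (nrow(s$coefficients) > 1L) unname(s$coefficients[2L, 2L]) else NA_real_,
    r = stats::cor(x, y),
    r_squared = s$r.squared,
    residuals = unname(stats::resid(fit)),
    n = length(x)
  )
}

stop_quenchlab <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "quenchlab_error")))
}

warn_quenchlab <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "quenchlab_warning")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

fmt_num <- function(x) formatC(x, format = "g", digits = 6)
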