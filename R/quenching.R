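# Stern-Volmer and double-logarithmic binding fits, and classification of
# the quenching mechanism against the diffusion-limited rate.

#' Stern-Volmer fit of a quenching table
#'
#' Fits the Stern-Volmer relation F0/F = 1 + Ksv [Q] by ordinary least
#' squares of the fluorescence ratio on the quencher concentration. The
#' intercept is free by default (robust to baseline error; flagged when it
#' strays more than 0.05 from the theoretical 1); `fix_intercept = TRUE`
#' pins it at 1 and fits the slope only. The bimolecular quenching rate
#' constant is Kq = Ksv / tau0, with tau0 the unquenched fluorophore
#' lifetime (1e-8 s for most single-tryptophan proteins).
#'
#' @param t A [quench_table()].
#' @param tau0 Unquenched fluorescence lifetime, s.
#' @param fix_intercept Logical; force the intercept to 1.
#' @return A list of class `"sv_fit"`: `ksv` (L/mol), `kq` (L mol^-1 s^-1),
#'   `tau0`, `intercept`, `r`, `se_ksv`, `n_points`, `temperature`, `flags`.
#' @examples
#' q <- dilution_ladder()
#' tab <- quench_table(q, 1000 / (1 + 5e4 * q), temperature = 298)
#' stern_volmer_fit(tab)
#' @export
stern_volmer_fit <- function(t, tau0 = 1e-8, fix_intercept = FALSE) {
  stopifnot(inherits(t, "quench_table"), is_number(tau0), tau0 > 0)
  if (length(t$q) < 3L) {
    stop_quenchlab("Stern-Volmer fit needs at least 3 points", "quenchlab_fit_error")
  }
  y <- t$f0 / t$f
  q <- t$q
  flags <- character()
  if (fix_intercept) {
    slope <- sum(q * (y - 1)) / sum(q^2)
    res <- (y - 1) - slope * q
    se_slope <- sqrt(sum(res^2) / (length(q) - 1L) / sum(q^2))
    intercept <- 1
    r <- stats::cor(q, y)
  } else {
    fit <- ols(q, y)
    slope <- fit$slope
    intercept <- fit$intercept
    se_slope <- fit$se_slope
    r <- fit$r
    if (abs(intercept - 1) > 0.05) {
      flags <- c(flags, sprintf("intercept %s deviates from 1 by more than 0.05",
                                fmt_num(intercept)))
    }
  }
  if (slope < 0) {
    warn_quenchlab("negative Stern-Volmer slope: enhancement, not quenching",
                   "quenchlab_enhancement")
    flags <- c(flags, "enhancement, not quenching")
  }
  structure(
    list(ksv = slope, kq = slope / tau0, tau0 = tau0, intercept = intercept,
         r = r, se_ksv = se_slope, n_points = length(q),
         temperature = t$temperature, fixed_intercept = fix_intercept,
         flags = flags),
    class = "sv_fit"
  )
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("<sv_fit> T = %s K: Ksv = %s L/mol, Kq = %s L/mol/s (tau0 = %s s), r = %.4f\n",
              fmt_num(x$temperature), fmt_num(x$ksv), fmt_num(x$kq),
              fmt_num(x$tau0), x$r))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Fits lg[(F0 - F)/F] = lg Ka + n lg[Q] (decadic logarithms) by ordinary
#' least squares, yielding the apparent binding constant Ka and the binding
#' site number n. Points with q = 0 or F >= F0 carry no binding signal and
#' are dropped with a warning.
#'
#' @param t A [quench_table()].
#' @return A list of class `"dl_fit"`: `ka` (L/mol), `n`, `r`, `se_log_ka`,
#'   `se_n`, `n_points`, `temperature`, `dropped` (concentrations removed).
#' @export
double_log_fit <- function(t) {
  stopifnot(inherits(t, "quench_table"))
  keep <- t$q > 0 & t$f < t$f0
  dropped <- t$q[!keep & t$q > 0]
  if (length(dropped)) {
    warn_quenchlab(
      sprintf("dropping %d point(s) with no quenching signal (q = %s)",
              length(dropped), paste(fmt_num(dropped), collapse = ", ")),
      "quenchlab_points_dropped"
    )
  }
  if (sum(keep) < 3L) {
    stop_quenchlab(
      sprintf("fewer than 3 usable points after dropping q = {%s}",
              paste(fmt_num(dropped), collapse = ", ")),
      "quenchlab_fit_error"
    )
  }
  x <- log10(t$q[keep])
  y <- log10((t$f0 - t$f[keep]) / t$f[keep])
  fit <- ols(x, y)
  structure(
    list(ka = 10^fit$intercept, n = fit$slope, r = fit$r,
         se_log_ka = fit$se_intercept, se_n = fit$se_slope,
         n_points = fit$n, temperature = t$temperature,
         dropped = dropped),
    class = "dl_fit"
  )
}

#' @export
print.dl_fit <- function(x, ...) {
  cat(sprintf("<dl_fit> T = %s K: Ka = %s L/mol, n = %.4f, r = %.4f (%d points)\n",
              fmt_num(x$temperature), fmt_num(x$ka), x$n, x$r, x$n_points))
  invisible(x)
}

#' Classify the quenching mechanism
#'
#' Primary rule: if the smallest bimolecular quenching rate constant Kq
#' across temperatures exceeds the diffusion-limited maximum for dynamic
#' (collisional) quenching — 2.0e10 L mol^-1 s^-1 — the mechanism is
#' static (ground-state complex formation); otherwise dynamic. Secondary
#' evidence is the temperature trend of Ksv: decreasing corroborates
#' static, increasing corroborates dynamic. When the two disagree the
#' primary rule stands and a discordance note is appended. A call within
#' +/-5% of the threshold is `"ambiguous"`.
#'
#' @param fits List of [stern_volmer_fit()] results at distinct temperatures.
#' @param kq_threshold Diffusion-limited maximum dynamic quenching rate,
#'   L mol^-1 s^-1.
#' @return A list of class `"mechanism_call"`: `label`, `min_kq`,
#'   `kq_threshold`, `ksv_temperature_trend`, `evidence`.
#' @export
classify_mechanism <- function(fits, kq_threshold = 2.0e10) {
  if (inherits(fits, "sv_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "sv_fit")))
  temps <- vapply(fits, `[[`, numeric(1), "temperature")
  if (anyDuplicated(temps)) {
    stop_quenchlab("fits must be at distinct temperatures", "quenchlab_classification_error")
  }
  kq <- vapply(fits, `[[`, numeric(1), "kq")
  ksv <- vapply(fits, `[[`, numeric(1), "ksv")
  min_kq <- min(kq)
  evidence <- sprintf("min Kq = %s L/mol/s vs threshold %s L/mol/s",
                      fmt_num(min_kq), fmt_num(kq_threshold))
  if (length(temps) >= 2L) {
    slope <- ols(temps, ksv)$slope
    rel <- slope * (max(temps) - min(temps)) / mean(ksv)
    trend <- if (abs(rel) < 1e-3) "flat" else if (slope < 0) "decreasing" else "increasing"
  } else {
    trend <- "flat"
    evidence <- c(evidence, "single temperature: no Ksv trend available")
  }
  if (abs(min_kq - kq_threshold) <= 0.05 * kq_threshold) {
    label <- "ambiguous"
    evidence <- c(evidence, "min Kq within 5% of the diffusion-limited threshold")
  } else if (min_kq > kq_threshold) {
    label <- "static"
    evidence <- c(evidence, "Kq above the diffusion limit: ground-state complex formation")
  } else {
    label <- "dynamic"
    evidence <- c(evidence, "Kq below the diffusion limit: collisional quenching")
  }
  corroborates <- switch(trend, decreasing = "static", increasing = "dynamic", NA_character_)
  if (!is.na(corroborates) && label != "ambiguous") {
    if (corroborates == label) {
      evidence <- c(evidence, sprintf("Ksv %s with temperature corroborates %s quenching",
                                      trend, label))
    } else {
      evidence <- c(evidence, sprintf(
        "discordance: Ksv trend (%s) suggests %s but the Kq rule (%s) stands",
        trend, corroborates, label))
    }
  }
  structure(
    list(label = label, min_kq = min_kq, kq_threshold = kq_threshold,
         ksv_temperature_trend = trend, evidence = evidence),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s (min Kq = %s, Ksv trend %s)\n",
              x$label, fmt_num(x$min_kq), x$ksv_temperature_trend))
  for (e in x$evidence) cat("  -", e, "\n")
  invisible(x)
}
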