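# ABTS / DPPH / FRAP assay arithmetic and Trolox-equivalent calibration.

#' ABTS radical scavenging rate
#'
#' `(A0 - A1) / A0 * 100`, with A0 the radical-only control absorbance and
#' A1 the sample absorbance (both at 734 nm).
#'
#' @param a0 Control absorbance (> 0).
#' @param a1 Sample absorbance.
#' @return Scavenging rate, percent. Values outside \[0, 100\] are reported
#'   with a warning, never clipped.
#' @export
abts_rate <- function(a0, a1) {
  if (any(a0 <= 0)) {
    stop_quenchlab("ABTS control absorbance A0 must be positive", "quenchlab_domain_error")
  }
  rate <- (a0 - a1) / a0 * 100
  if (any(rate < 0 | rate > 100)) {
    warn_quenchlab("ABTS rate outside [0, 100]%: check assay absorbances",
                   "quenchlab_out_of_range")
  }
  rate
}

#' DPPH radical scavenging rate
#'
#' `(Ab - At - Ac) / Ab * 100`, with Ab the radical blank, At the sample
#' reaction, and Ac the sample-colour control without radical (517 nm).
#'
#' @param ab Blank absorbance (> 0).
#' @param at Sample absorbance.
#' @param ac No-radical control absorbance.
#' @return Scavenging rate, percent; may be negative (reported, warned).
#' @export
dpph_rate <- function(ab, at, ac) {
  if (any(ab <= 0)) {
    stop_quenchlab("DPPH blank absorbance Ab must be positive", "quenchlab_domain_error")
  }
  rate <- (ab - at - ac) / ab * 100
  if (any(rate < 0 | rate > 100)) {
    warn_quenchlab("DPPH rate outside [0, 100]%: check assay absorbances",
                   "quenchlab_out_of_range")
  }
  rate
}

#' Ferric-reducing antioxidant power
#'
#' `At - A1 - A0` (593 nm): sample reaction minus sample-only control minus
#' reagent blank.
#'
#' @param at Sample absorbance.
#' @param a1 Control (sample without reagent) absorbance.
#' @param a0 Blank (reagent without sample) absorbance.
#' @return Reducing power, absorbance units; negative values are warned.
#' @export
frap_power <- function(at, a1, a0) {
  power <- at - a1 - a0
  if (any(power < 0)) {
    warn_quenchlab("negative ferric-reducing power: check assay absorbances",
                   "quenchlab_out_of_range")
  }
  power
}

#' Calibrate a Trolox standard curve
#'
#' Ordinary least squares of assay response (percent scavenging rate, or
#' reducing-power absorbance) on Trolox concentration in mg/L, with a free
#' intercept. A curve with r-squared below 0.99 is flagged, as standard
#' curves at that quality are usually re-run.
#'
#' @param standards Two-column data frame `trolox_mg_per_L,response` (or a
#'   matrix with those columns).
#' @param response_kind `"percent_rate"` or `"reducing_power"`.
#' @return A list of class `"trolox_curve"`: `slope`, `intercept`,
#'   `r_squared`, `response_kind`, `n_standards`.
#' @export
calibrate_trolox <- function(standards, response_kind = c("percent_rate", "reducing_power")) {
  response_kind <- match.arg(response_kind)
  m <- as.data.frame(standards)
  stopifnot(ncol(m) >= 2L)
  conc <- as.numeric(m[[1L]])
  resp <- as.numeric(m[[2L]])
  if (length(conc) < 3L) {
    stop_quenchlab("calibration needs at least 3 standards", "quenchlab_calibration_error")
  }
  if (length(unique(conc)) < 2L) {
    stop_quenchlab("standards have no concentration spread", "quenchlab_calibration_error")
  }
  fit <- ols(conc, resp)
  if (fit$slope == 0) {
    stop_quenchlab("flat standard curve: zero slope", "quenchlab_calibration_error")
  }
  if (fit$r_squared < 0.99) {
    warn_quenchlab(sprintf("Trolox curve r-squared %.4f below 0.99", fit$r_squared),
                   "quenchlab_poor_calibration")
  }
  structure(
    list(slope = fit$slope, intercept = fit$intercept, r_squared = fit$r_squared,
         response_kind = response_kind, n_standards = length(conc)),
    class = "trolox_curve"
  )
}

#' @export
print.trolox_curve <- function(x, ...) {
  cat(sprintf("<trolox_curve> response = %s + %s * [Trolox mg/L] (%s), r^2 = %.4f, %d standards\n",
              fmt_num(x$intercept), fmt_num(x$slope), x$response_kind,
              x$r_squared, x$n_standards))
  invisible(x)
}

#' Convert an assay response to Trolox equivalents
#'
#' Inverts the standard curve: `teac = (response - intercept) / slope`.
#'
#' @param response Assay response (percent rate or reducing-power
#'   absorbance, matching the curve's `response_kind`). Vectorised.
#' @param curve A [calibrate_trolox()] curve.
#' @return A tibble of class `"teac_result"` with columns `raw_response`
#'   and `teac` (mg/L Trolox equivalents).
#' @export
to_teac <- function(response, curve) {
  stopifnot(inherits(curve, "trolox_curve"), is.numeric(response))
  out <- tibble::tibble(raw_response = response,
                        teac = (response - curve$intercept) / curve$slope)
  class(out) <- c("teac_result", class(out))
  out
}
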