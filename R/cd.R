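# Far-UV circular dichroism: secondary-structure estimation by
# non-negative least squares against a four-component reference basis.

#' Far-UV CD spectrum
#'
#' @param wavelengths Wavelengths in nm, within 185-265, at least 20 samples.
#' @param signal CD signal (millidegrees, or mean residue ellipticity when
#'   `mre = TRUE`).
#' @param meta Named list of annotations (protein mg/mL, ratio label, ...).
#' @param mre Logical flag: signal already converted to mean residue
#'   ellipticity. Accepted and recorded; no unit conversion is performed.
#' @return A [spectrum()] subclass of class `"cd_spectrum"`.
#' @export
cd_spectrum <- function(wavelengths, signal, meta = list(), mre = FALSE) {
  if (length(wavelengths) < 20L) {
    stop_quenchlab("a CD spectrum needs at least 20 samples", "quenchlab_invalid_spectrum")
  }
  if (any(wavelengths < 185) || any(wavelengths > 265)) {
    stop_quenchlab("CD wavelengths must lie within 185-265 nm", "quenchlab_invalid_spectrum")
  }
  s <- spectrum(wavelengths, signal, meta = meta)
  s$mre <- isTRUE(mre)
  class(s) <- c("cd_spectrum", class(s))
  s
}

# CD spectra are signed; the generic spectrum constructor allows that, but
# the intensity-positivity checks of the fluorescence stages never apply.

#' Synthetic reference basis for CD deconvolution
#'
#' Parametric component spectra for alpha-helix, beta-sheet, beta-turn and
#' random coil built from sums of Gaussian bands with the canonical far-UV
#' features: the helix's positive band near 192 nm and double negative
#' minima near 208 and 222 nm, the sheet's positive band near 196 nm and
#' single minimum near 218 nm, the turn's weak positive band near 202 nm,
#' and the coil's strong negative band near 198 nm. This basis is
#' synthetic — a documented stand-in for a measured reference set — and is
#' intended for recovery of known synthetic mixtures; for real spectra
#' supply a measured basis via [read_basis_csv()].
#'
#' @param grid Wavelength grid, nm.
#' @return A list of class `"cd_basis"`: `wavelengths` and a 4-column
#'   `components` matrix (`helix`, `sheet`, `turn`, `coil`).
#' @export
default_cd_basis <- function(grid = seq(190, 260, by = 1)) {
  g <- function(center, width) exp(-((grid - center) / width)^2)
  components <- cbind(
    helix = 65 * g(192, 5.5) - 33 * g(209, 6.5) - 32 * g(222, 6.0),
    sheet = 35 * g(196, 5.5) - 18 * g(218, 7.0),
    turn  =  8 * g(202, 6.0) -  4 * g(225, 8.0),
    coil  = -42 * g(198, 6.0) + 4 * g(220, 10.0)
  )
  cd_basis(grid, components, provenance = "synthetic parametric basis")
}

#' Construct a CD reference basis
#'
#' @param wavelengths Common strictly-increasing wavelength grid, nm.
#' @param components Numeric matrix with columns `helix`, `sheet`, `turn`,
#'   `coil`.
#' @param provenance Free-form label recording where the basis came from.
#' @return A list of class `"cd_basis"`.
#' @export
cd_basis <- function(wavelengths, components, provenance = "user") {
  wavelengths <- as.numeric(wavelengths)
  components <- as.matrix(components)
  need <- c("helix", "sheet", "turn", "coil")
  if (!identical(colnames(components), need)) {
    stop_quenchlab("basis components must be named helix, sheet, turn, coil (in order)",
                   "quenchlab_format_error")
  }
  if (nrow(components) != length(wavelengths) || any(diff(wavelengths) <= 0)) {
    stop_quenchlab("basis grid must be strictly increasing and match the component rows",
                   "quenchlab_format_error")
  }
  rownames(components) <- NULL
  structure(
    list(wavelengths = wavelengths, components = components, provenance = provenance),
    class = "cd_basis"
  )
}

#' Read a reference basis from CSV
#'
#' Expects columns `wavelength_nm,helix,sheet,turn,coil`.
#' @param path Path to the basis CSV.
#' @return A [cd_basis()].
#' @export
read_basis_csv <- function(path) {
  if (!file.exists(path)) {
    stop_quenchlab(sprintf("file not found: %s", path), "quenchlab_io_error")
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  need <- c("wavelength_nm", "helix", "sheet", "turn", "coil")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_quenchlab(sprintf("missing column(s) in %s: %s", path, paste(miss, collapse = ", ")),
                   "quenchlab_format_error")
  }
  ord <- order(df$wavelength_nm)
  cd_basis(df$wavelength_nm[ord],
           as.matrix(df[ord, c("helix", "sheet", "turn", "coil")]),
           provenance = path)
}

#' Estimate secondary-structure fractions from a CD spectrum
#'
#' Solves a non-negative least squares problem: the measured signal is
#' modelled as a nonnegative combination of the four reference component
#' spectra (interpolated onto the sample grid, so residuals live in
#' measurement space), and the coefficients are renormalised to sum to 1.
#' The residual norm is reported pre-normalisation, so scaling mismatch
#' between sample and basis shows up there rather than being hidden.
#'
#' @param cd A [cd_spectrum()] (any [spectrum()] within the basis range works).
#' @param basis A [cd_basis()]; default [default_cd_basis()] on the sample
#'   grid.
#' @return A list of class `"structure_fractions"`: `alpha_helix`,
#'   `beta_sheet`, `beta_turn`, `random_coil` (each in \[0, 1\], summing to
#'   1), `residual_norm`, and the raw `coefficients`.
#' @export
deconvolve_cd <- function(cd, basis = NULL) {
  stopifnot(inherits(cd, "spectrum"))
  if (is.null(basis)) basis <- default_cd_basis(cd$wavelengths)
  stopifnot(inherits(basis, "cd_basis"))
  if (min(basis$wavelengths) > min(cd$wavelengths) ||
      max(basis$wavelengths) < max(cd$wavelengths)) {
    stop_quenchlab("basis grid does not cover the spectrum's wavelength range",
                   "quenchlab_domain_error")
  }
  b <- cd$intensities
  if (all(b == 0)) {
    stop_quenchlab("all-zero CD signal: nothing to deconvolve", "quenchlab_degenerate_error")
  }
  A <- apply(basis$components, 2L, function(col) {
    stats::approx(basis$wavelengths, col, xout = cd$wavelengths, method = "linear")$y
  })
  if (qr(A)$rank < 4L) {
    stop_quenchlab("basis is rank-deficient on the working grid", "quenchlab_conditioning_error")
  }
  sol <- pracma::lsqnonneg(A, b)
  x <- sol$x
  if (sum(x) <= 0) {
    stop_quenchlab("degenerate NNLS solution: all coefficients zero",
                   "quenchlab_degenerate_error")
  }
  fr <- x / sum(x)
  structure(
    list(alpha_helix = fr[1L], beta_sheet = fr[2L], beta_turn = fr[3L],
         random_coil = fr[4L],
         residual_norm = sqrt(sum((A %*% x - b)^2)),
         coefficients = stats::setNames(x, colnames(basis$components))),
    class = "structure_fractions"
  )
}

#' Construct structure fractions directly
#'
#' @param alpha_helix,beta_sheet,beta_turn,random_coil Fractions in
#'   \[0, 1\] summing to 1 (within 1e-9).
#' @return A list of class `"structure_fractions"`.
#' @export
structure_fractions <- function(alpha_helix, beta_sheet, beta_turn, random_coil) {
  fr <- c(alpha_helix, beta_sheet, beta_turn, random_coil)
  if (any(fr < 0) || any(fr > 1)) {
    stop_quenchlab("fractions must lie in [0, 1]", "quenchlab_domain_error")
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop_quenchlab("fractions must sum to 1", "quenchlab_domain_error")
  }
  structure(
    list(alpha_helix = fr[1L], beta_sheet = fr[2L], beta_turn = fr[3L],
         random_coil = fr[4L], residual_norm = 0,
         coefficients = stats::setNames(fr, c("helix", "sheet", "turn", "coil"))),
    class = "structure_fractions"
  )
}

#' @export
print.structure_fractions <- function(x, ...) {
  cat(sprintf("<structure_fractions> helix %.1f%%, sheet %.1f%%, turn %.1f%%, coil %.1f%% (residual %.3g)\n",
              100 * x$alpha_helix, 100 * x$beta_sheet, 100 * x$beta_turn,
              100 * x$random_coil, x$residual_norm))
  invisible(x)
}

#' Composition change between two secondary-structure compositions
#'
#' Signed per-component change in percentage points (`after` minus
#' `before`). Inputs may be `"structure_fractions"` objects (fractions,
#' converted to percent) or bare length-4 numeric vectors already in
#' percent in helix/sheet/turn/coil order — the latter lets published
#' composition tables be compared as printed, even when instrument software
#' reports rows that do not sum exactly to 100. When both compositions sum
#' to the same total the four deltas sum to zero.
#'
#' @param before,after `"structure_fractions"` objects or length-4 percent
#'   vectors.
#' @return Named numeric vector of signed changes in percentage points.
#' @examples
#' composition_delta(c(18.8, 31.1, 19.2, 30.5), c(6.4, 52.9, 16.7, 28.8))
#' @export
composition_delta <- function(before, after) {
  as_pct <- function(x) {
    if (inherits(x, "structure_fractions")) {
      100 * c(x$alpha_helix, x$beta_sheet, x$beta_turn, x$random_coil)
    } else if (is.numeric(x) && length(x) == 4L) {
      as.numeric(x)
    } else {
      stop_quenchlab("expected structure_fractions or a length-4 percent vector",
                     "quenchlab_domain_error")
    }
  }
  d <- as_pct(after) - as_pct(before)
  stats::setNames(d, c("alpha_helix", "beta_sheet", "beta_turn", "random_coil"))
}
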