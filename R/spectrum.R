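# Spectral data model, CSV I/O and peak arithmetic shared by every
# downstream analysis stage.

#' Construct a spectrum
#'
#' A spectrum is the universal spectral record of the package: a series of
#' point samples (wavelength in nm, intensity in arbitrary units) with
#' free-form string metadata (sample id, temperature, delta-lambda, ligand
#' concentration and the like).
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length at least 3.
#' @param intensities Numeric vector of intensities (a.u.), same length as
#'   `wavelengths`, all finite.
#' @param meta Named list of annotations. Values are kept as supplied;
#'   numeric values are allowed and used by downstream assembly functions
#'   (e.g. `ligand_conc_M`, `temperature_K`).
#' @return An object of class `"spectrum"`.
#' @examples
#' s <- spectrum(300:500, dnorm(300:500, 345, 25), meta = list(sample = "blank"))
#' find_peak(s)
#' @export
spectrum <- function(wavelengths, intensities, meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) < 3L) {
    stop_quenchlab("a spectrum needs at least 3 samples", "quenchlab_invalid_spectrum")
  }
  if (length(intensities) != length(wavelengths)) {
    stop_quenchlab("wavelengths and intensities differ in length", "quenchlab_invalid_spectrum")
  }
  if (anyNA(wavelengths) || any(!is.finite(wavelengths))) {
    stop_quenchlab("wavelengths must be finite", "quenchlab_invalid_spectrum")
  }
  d <- diff(wavelengths)
  if (any(d <= 0)) {
    bad <- wavelengths[which(d <= 0)[1L] + 1L]
    stop_quenchlab(
      sprintf("wavelengths must be strictly increasing (violation at %s nm)", fmt_num(bad)),
      "quenchlab_invalid_spectrum"
    )
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop_quenchlab("intensities must be finite", "quenchlab_invalid_spectrum")
  }
  stopifnot(is.list(meta))
  structure(
    list(wavelengths = wavelengths, intensities = intensities, meta = meta),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum> %d samples, %s-%s nm\n",
    length(x$wavelengths), fmt_num(min(x$wavelengths)), fmt_num(max(x$wavelengths))
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavelengths)

#' Read a spectrum from CSV
#'
#' The default dialect expects columns `wavelength_nm,intensity`; metadata
#' may precede the header as `# key=value` comment lines. Rows are sorted by
#' wavelength; duplicate wavelengths are a data error.
#'
#' @param path Path to a CSV file.
#' @param cols Column mapping: named character vector with entries
#'   `wavelength` and `intensity` giving the CSV column names.
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path,
                              cols = c(wavelength = "wavelength_nm", intensity = "intensity")) {
  if (!file.exists(path)) {
    stop_quenchlab(sprintf("file not found: %s", path), "quenchlab_io_error")
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  miss <- setdiff(unname(cols), names(df))
  if (length(miss)) {
    stop_quenchlab(
      sprintf("missing column(s) in %s: %s", path, paste(miss, collapse = ", ")),
      "quenchlab_format_error"
    )
  }
  wl <- as.numeric(df[[cols[["wavelength"]]]])
  it <- as.numeric(df[[cols[["intensity"]]]])
  if (anyNA(wl) || anyNA(it)) {
    stop_quenchlab(sprintf("non-numeric values in %s", path), "quenchlab_format_error")
  }
  ord <- order(wl)
  wl <- wl[ord]; it <- it[ord]
  if (anyDuplicated(wl)) {
    dup <- wl[which(duplicated(wl))[1L]]
    stop_quenchlab(
      sprintf("duplicated wavelength %s nm in %s", fmt_num(dup), path),
      "quenchlab_data_error"
    )
  }
  spectrum(wl, it, meta = meta)
}

#' Write a spectrum to CSV
#'
#' Values are written with 17 significant digits so that
#' `read_spectrum_csv()` reproduces them bit-identically. Metadata is
#' written as `# key=value` comment lines above the header.
#'
#' @param s A [spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(s$meta)) {
    writeLines(sprintf("# %s=%s", key, format(s$meta[[key]], digits = 17)), con)
  }
  writeLines("wavelength_nm,intensity", con)
  writeLines(sprintf("%.17g,%.17g", s$wavelengths, s$intensities), con)
  invisible(path)
}

#' Read a long-format multi-spectrum CSV
#'
#' Expects columns `series_id,wavelength_nm,intensity` plus any extra
#' columns, which are attached (first value per series) as metadata.
#'
#' @param path Path to a long-format CSV file.
#' @return A named list of [spectrum()] objects, one per `series_id`.
#' @export
read_spectra_long <- function(path) {
  if (!file.exists(path)) {
    stop_quenchlab(sprintf("file not found: %s", path), "quenchlab_io_error")
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  need <- c("series_id", "wavelength_nm", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_quenchlab(
      sprintf("missing column(s) in %s: %s", path, paste(miss, collapse = ", ")),
      "quenchlab_format_error"
    )
  }
  extra <- setdiff(names(df), need)
  out <- lapply(split(df, df$series_id), function(g) {
    meta <- stats::setNames(lapply(extra, function(cl) g[[cl]][1L]), extra)
    ord <- order(g$wavelength_nm)
    spectrum(g$wavelength_nm[ord], g$intensity[ord], meta = meta)
  })
  out
}

#' Locate the emission maximum of a spectrum
#'
#' The peak is the sample-grid argmax; with `refine = TRUE` a three-point
#' parabolic interpolation around the argmax sharpens the call to
#' sub-grid precision (clamped to the grid at the boundaries). Ties are
#' broken toward the smaller wavelength; non-adjacent tied maxima (distinct
#' candidate bands) additionally raise a warning. Refinement is off by
#' default so whole-nm instrument grids report whole-nm maxima.
#'
#' @param s A [spectrum()].
#' @param refine Logical; apply parabolic refinement.
#' @return A list of class `"peak_call"` with `lambda_max` (nm),
#'   `intensity` (a.u.) and `method` (`"argmax"` or `"parabolic"`).
#' @export
find_peak <- function(s, refine = FALSE) {
  stopifnot(inherits(s, "spectrum"))
  it <- s$intensities
  wl <- s$wavelengths
  mx <- max(it)
  if (all(it == it[1L])) {
    warn_quenchlab("flat spectrum: degenerate peak at the smallest wavelength",
                   "quenchlab_degenerate_peak")
    return(structure(list(lambda_max = wl[1L], intensity = it[1L], method = "argmax"),
                     class = "peak_call"))
  }
  hits <- which(it == mx)
  if (length(hits) > 1L && any(diff(hits) > 1L)) {
    # non-adjacent equal maxima are genuinely ambiguous band candidates;
    # adjacent equal samples just mean the band peaks between grid points
    warn_quenchlab(
      sprintf("tied maxima at %s nm; reporting the smallest wavelength",
              paste(fmt_num(wl[hits]), collapse = ", ")),
      "quenchlab_peak_tie"
    )
  }
  i <- hits[1L]
  lambda <- wl[i]
  intensity <- it[i]
  method <- "argmax"
  if (isTRUE(refine) && i > 1L && i < length(it)) {
    y1 <- it[i - 1L]; y2 <- it[i]; y3 <- it[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {  # genuine local curvature
      # vertex of the parabola through the three samples (uniform-grid form
      # generalised to possibly nonuniform spacing via a quadratic fit)
      xs <- wl[(i - 1L):(i + 1L)] - wl[i]
      qf <- stats::lm(c(y1, y2, y3) ~ xs + I(xs^2))
      a2 <- stats::coef(qf)[[3L]]; a1 <- stats::coef(qf)[[2L]]
      if (a2 < 0) {
        xv <- -a1 / (2 * a2)
        xv <- min(max(xv, xs[1L]), xs[3L])  # clamp to the bracketing samples
        lambda <- wl[i] + xv
        intensity <- stats::coef(qf)[[1L]] + a1 * xv + a2 * xv^2
        method <- "parabolic"
      }
    }
  }
  structure(list(lambda_max = lambda, intensity = intensity, method = method),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("<peak_call> lambda_max = %s nm, intensity = %s a.u. (%s)\n",
              fmt_num(x$lambda_max), fmt_num(x$intensity), x$method))
  invisible(x)
}

#' Signed band shift between two peak calls
#'
#' Positive values are red shifts (toward longer wavelength, read as a more
#' hydrophilic fluorophore microenvironment), negative values blue shifts.
#'
#' @param reference,sample `"peak_call"` objects (or bare wavelengths in nm).
#' @return A list with `shift_nm` (sample minus reference) and `label`
#'   (`"red"`, `"blue"` or `"none"`).
#' @examples
#' peak_shift(274, 270)  # -4 nm blue shift
#' @export
peak_shift <- function(reference, sample) {
  lam <- function(p) if (inherits(p, "peak_call")) p$lambda_max else as.numeric(p)
  shift <- lam(sample) - lam(reference)
  label <- if (shift > 0) "red" else if (shift < 0) "blue" else "none"
  list(shift_nm = shift, label = label)
}

#' Percent decrease of a response relative to a reference
#'
#' `(reference - sample) / reference * 100`, returned unrounded; round only
#' at presentation.
#'
#' @param reference Reference intensity (a.u.), strictly positive.
#' @param sample Sample intensity (a.u.).
#' @return Percent change (positive = decline).
#' @examples
#' percent_change(3311, 1592)  # 51.92 % decline
#' @export
percent_change <- function(reference, sample) {
  if (any(reference <= 0)) {
    stop_quenchlab("percent_change needs a positive reference", "quenchlab_domain_error")
  }
  (reference - sample) / reference * 100
}

#' Interpolate a spectrum's intensity at given wavelengths
#'
#' Linear interpolation; wavelengths outside the sampled range are an error.
#' Used to compare spectra recorded on mismatched grids.
#'
#' @param s A [spectrum()].
#' @param at Wavelengths (nm) to evaluate at.
#' @return Numeric vector of intensities.
#' @export
spectrum_at <- function(s, at) {
  stopifnot(inherits(s, "spectrum"))
  if (any(at < min(s$wavelengths)) || any(at > max(s$wavelengths))) {
    stop_quenchlab("requested wavelength outside the sampled range", "quenchlab_domain_error")
  }
  stats::approx(s$wavelengths, s$intensities, xout = at, method = "linear")$y
}
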