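# Dilution arithmetic and assembly of per-temperature quenching tables.

#' Dilution specification
#'
#' Describes one titration point: a volume of ligand stock added to a base
#' volume of protein solution. Two volume conventions are supported:
#' `"nominal"` divides by the base volume only (the instrument-protocol
#' convention under which an 80 uL addition of 1e-3 M stock into 3.0 mL
#' reads 26.7 uM), `"additive"` divides by base plus added volume.
#'
#' @param stock_conc Stock concentration, mol/L.
#' @param added_volume Added volume, L.
#' @param base_volume Base volume, L.
#' @param volume_convention `"nominal"` (default) or `"additive"`.
#' @return A list of class `"dilution_spec"`.
#' @export
dilution_spec <- function(stock_conc, added_volume, base_volume,
                          volume_convention = c("nominal", "additive")) {
  volume_convention <- match.arg(volume_convention)
  stopifnot(is_number(stock_conc), is_number(added_volume), is_number(base_volume))
  if (stock_conc < 0 || added_volume < 0 || base_volume < 0) {
    stop_quenchlab("concentrations and volumes must be nonnegative", "quenchlab_domain_error")
  }
  structure(
    list(stock_conc = stock_conc, added_volume = added_volume,
         base_volume = base_volume, volume_convention = volume_convention),
    class = "dilution_spec"
  )
}

#' Ligand concentration from a dilution specification
#'
#' @param d A [dilution_spec()].
#' @return Ligand concentration, mol/L.
#' @examples
#' ligand_concentration(dilution_spec(1e-3, 80e-6, 3.0e-3))  # 2.67e-5 M
#' @export
ligand_concentration <- function(d) {
  stopifnot(inherits(d, "dilution_spec"))
  if (d$volume_convention == "nominal") {
    if (d$base_volume == 0) {
      stop_quenchlab("nominal convention needs a positive base volume", "quenchlab_domain_error")
    }
    d$stock_conc * d$added_volume / d$base_volume
  } else {
    total <- d$base_volume + d$added_volume
    if (total == 0) {
      stop_quenchlab("additive convention needs a positive total volume", "quenchlab_domain_error")
    }
    d$stock_conc * d$added_volume / total
  }
}

#' Concentration ladder for a titration series
#'
#' Convenience wrapper mapping a vector of added volumes onto ligand molar
#' concentrations under one dilution convention. The default arguments
#' reproduce the common protocol of adding 0-80 uL of a 1e-3 M stock to a
#' nominal 3.0 mL cuvette, i.e. 0 to 26.7 uM.
#'
#' @param volumes_uL Added volumes in microlitres (must include 0).
#' @param stock_conc Stock concentration, mol/L.
#' @param base_volume Base volume, L.
#' @param volume_convention Passed to [dilution_spec()].
#' @return Numeric vector of concentrations, mol/L.
#' @export
dilution_ladder <- function(volumes_uL = c(0, 20, 30, 40, 50, 60, 70, 80),
                            stock_conc = 1e-3, base_volume = 3.0e-3,
                            volume_convention = "nominal") {
  vapply(volumes_uL, function(v) {
    ligand_concentration(dilution_spec(stock_conc, v * 1e-6, base_volume,
                                       volume_convention))
  }, numeric(1))
}

#' Quenching table constructor
#'
#' Holds the ligand concentration ladder and the aligned fluorescence
#' response at one temperature; the first entry must be the zero-ligand
#' reference.
#'
#' @param q Ligand molar concentrations (mol/L), strictly increasing,
#'   first entry 0.
#' @param f Fluorescence response (a.u.), same length, all positive.
#' @param temperature Temperature, K.
#' @param response_mode `"peak"` or `"fixed_wavelength"`.
#' @return A list of class `"quench_table"` with `f0 = f[1]`.
#' @export
quench_table <- function(q, f, temperature,
                         response_mode = c("peak", "fixed_wavelength")) {
  response_mode <- match.arg(response_mode)
  q <- as.numeric(q); f <- as.numeric(f)
  stopifnot(length(q) == length(f), is_number(temperature))
  if (length(q) < 2L) {
    stop_quenchlab("a quench table needs at least 2 points", "quenchlab_data_error")
  }
  if (q[1L] != 0) {
    stop_quenchlab("the first concentration must be the zero-ligand reference",
                   "quenchlab_data_error")
  }
  if (any(diff(q) <= 0)) {
    stop_quenchlab("concentrations must be strictly increasing", "quenchlab_data_error")
  }
  if (any(f <= 0)) {
    stop_quenchlab("all fluorescence responses must be positive", "quenchlab_data_error")
  }
  structure(
    list(temperature = temperature, q = q, f = f, f0 = f[1L],
         response_mode = response_mode),
    class = "quench_table"
  )
}

#' @export
print.quench_table <- function(x, ...) {
  cat(sprintf("<quench_table> T = %s K, %d points, response = %s\n",
              fmt_num(x$temperature), length(x$q), x$response_mode))
  print(tibble::tibble(q_M = x$q, f = x$f, f0_over_f = x$f0 / x$f))
  invisible(x)
}

#' Assemble a quenching table from titration spectra
#'
#' Each spectrum must carry `ligand_conc_M` metadata; the series must
#' include the zero-ligand reference. The response per spectrum is either
#' the per-spectrum maximum (`"peak"`, the default and the common literature
#' practice) or the intensity at the zero-ligand peak wavelength
#' (`"fixed_wavelength"`, interpolated; useful as a sensitivity analysis
#' when the band shifts).
#'
#' @param spectra List of [spectrum()] objects with `ligand_conc_M` meta.
#' @param temperature Temperature in K (defaults to the spectra's
#'   `temperature_K` meta when consistent).
#' @param response_mode `"peak"` or `"fixed_wavelength"`.
#' @return A [quench_table()], sorted by concentration.
#' @export
build_quench_table <- function(spectra, temperature = NULL,
                               response_mode = c("peak", "fixed_wavelength")) {
  response_mode <- match.arg(response_mode)
  stopifnot(is.list(spectra), length(spectra) >= 3L)
  q <- vapply(spectra, function(s) {
    v <- s$meta$ligand_conc_M
    if (is.null(v)) stop_quenchlab("spectrum lacks ligand_conc_M metadata",
                                   "quenchlab_assembly_error")
    as.numeric(v)
  }, numeric(1))
  if (anyDuplicated(q)) {
    stop_quenchlab("ligand concentrations must be distinct", "quenchlab_assembly_error")
  }
  if (!any(q == 0)) {
    stop_quenchlab("missing zero-ligand reference spectrum", "quenchlab_assembly_error")
  }
  if (is.null(temperature)) {
    temps <- unique(unlist(lapply(spectra, function(s) s$meta$temperature_K)))
    if (length(temps) != 1L) {
      stop_quenchlab("supply `temperature` explicitly: spectra carry none or several",
                     "quenchlab_assembly_error")
    }
    temperature <- as.numeric(temps)
  }
  ord <- order(q)
  spectra <- spectra[ord]; q <- q[ord]
  if (response_mode == "peak") {
    f <- vapply(spectra, function(s) find_peak(s)$intensity, numeric(1))
  } else {
    lam0 <- find_peak(spectra[[1L]])$lambda_max
    f <- vapply(spectra, function(s) spectrum_at(s, lam0), numeric(1))
  }
  if (any(f <= 0)) {
    stop_quenchlab("nonpositive response extracted from a spectrum", "quenchlab_data_error")
  }
  quench_table(q, f, temperature, response_mode)
}
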