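# Synchronous-fluorescence series analysis: Tyr (delta-lambda 15 nm) and
# Trp (delta-lambda 60 nm) microenvironment summaries.

#' Synchronous fluorescence series
#'
#' A series of synchronous spectra recorded at one excitation-emission
#' offset (delta-lambda), one spectrum per ligand concentration including
#' zero. By convention delta-lambda = 15 nm reports tyrosine residues and
#' 60 nm tryptophan; other offsets are accepted and labelled `"custom"`.
#'
#' @param spectra List of [spectrum()] objects, each with `ligand_conc_M`
#'   metadata; one concentration must be 0.
#' @param delta_lambda Excitation-emission offset, nm.
#' @return A list of class `"sync_series"`.
#' @export
sync_series <- function(spectra, delta_lambda) {
  stopifnot(is.list(spectra), length(spectra) >= 2L, is_number(delta_lambda))
  conc <- vapply(spectra, function(s) {
    v <- s$meta$ligand_conc_M
    if (is.null(v)) stop_quenchlab("spectrum lacks ligand_conc_M metadata",
                                   "quenchlab_assembly_error")
    as.numeric(v)
  }, numeric(1))
  if (anyDuplicated(conc)) {
    stop_quenchlab("ligand concentrations must be distinct", "quenchlab_assembly_error")
  }
  if (!any(conc == 0)) {
    stop_quenchlab("missing zero-ligand reference spectrum", "quenchlab_assembly_error")
  }
  ord <- order(conc)
  residue <- if (delta_lambda == 15) "Tyr" else if (delta_lambda == 60) "Trp" else "custom"
  structure(
    list(delta_lambda = delta_lambda, residue_label = residue,
         spectra = spectra[ord], concentrations = conc[ord]),
    class = "sync_series"
  )
}

#' Summarise a synchronous fluorescence series
#'
#' Per concentration: the band maximum (integer-nm argmax by default,
#' matching whole-nm instrument reporting) and the percent decline of its
#' intensity relative to the zero-ligand spectrum. The total shift is the
#' signed wavelength difference between the highest-concentration and
#' zero-ligand maxima (positive = red).
#'
#' @param series A [sync_series()].
#' @param refine Logical; parabolic sub-grid peak refinement.
#' @return A list of class `"sync_summary"`: `per_concentration` tibble
#'   (`conc_M`, `lambda_max`, `intensity`, `percent_decline`),
#'   `total_shift`, `shift_label`, `max_decline`, `delta_lambda`,
#'   `residue_label`.
#' @export
analyze_sync <- function(series, refine = FALSE) {
  stopifnot(inherits(series, "sync_series"))
  peaks <- lapply(series$spectra, find_peak, refine = refine)
  lam <- vapply(peaks, `[[`, numeric(1), "lambda_max")
  it <- vapply(peaks, `[[`, numeric(1), "intensity")
  i0 <- it[1L]
  decline <- percent_change(i0, it)
  shift <- peak_shift(peaks[[1L]], peaks[[length(peaks)]])
  structure(
    list(
      per_concentration = tibble::tibble(
        conc_M = series$concentrations, lambda_max = lam,
        intensity = it, percent_decline = decline
      ),
      total_shift = shift$shift_nm,
      shift_label = shift$label,
      max_decline = max(decline),
      delta_lambda = series$delta_lambda,
      residue_label = series$residue_label
    ),
    class = "sync_summary"
  )
}

#' @export
print.sync_summary <- function(x, ...) {
  cat(sprintf("<sync_summary> %s (delta-lambda %s nm): max decline %.2f%%, shift %+g nm (%s)\n",
              x$residue_label, fmt_num(x$delta_lambda), x$max_decline,
              x$total_shift, x$shift_label))
  print(x$per_concentration)
  invisible(x)
}

#' Compare tryptophan and tyrosine contributions
#'
#' Reports which residue class carries the larger zero-ligand intensity
#' (i.e. dominates the protein's intrinsic fluorescence) and which shows
#' the larger maximal decline on ligand binding (i.e. sits closer to the
#' binding site), with intensity and decline ratios.
#'
#' @param trp,tyr `"sync_summary"` objects from the same concentration
#'   ladder.
#' @return A list of class `"contribution_report"`.
#' @export
compare_contributions <- function(trp, tyr) {
  stopifnot(inherits(trp, "sync_summary"), inherits(tyr, "sync_summary"))
  if (!isTRUE(all.equal(trp$per_concentration$conc_M, tyr$per_concentration$conc_M))) {
    stop_quenchlab("summaries come from different concentration ladders",
                   "quenchlab_comparison_error")
  }
  i_trp <- trp$per_concentration$intensity[1L]
  i_tyr <- tyr$per_concentration$intensity[1L]
  dom <- function(a, b, la, lb) if (a > b) la else if (b > a) lb else "tie"
  structure(
    list(
      intensity_dominant = dom(i_trp, i_tyr, trp$residue_label, tyr$residue_label),
      intensity_ratio = i_trp / i_tyr,
      decline_dominant = dom(trp$max_decline, tyr$max_decline,
                             trp$residue_label, tyr$residue_label),
      decline_ratio = trp$max_decline / tyr$max_decline,
      trp_zero_intensity = i_trp,
      tyr_zero_intensity = i_tyr,
      trp_max_decline = trp$max_decline,
      tyr_max_decline = tyr$max_decline
    ),
    class = "contribution_report"
  )
}

#' @export
print.contribution_report <- function(x, ...) {
  cat(sprintf("<contribution_report> zero-ligand intensity: %s dominant (ratio %.2f); max decline: %s dominant (ratio %.2f)\n",
              x$intensity_dominant, x$intensity_ratio,
              x$decline_dominant, x$decline_ratio))
  invisible(x)
}
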