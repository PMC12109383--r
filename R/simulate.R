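# Seeded synthetic-data generators. Every generator is a pure function of
# (parameters, seed): the caller's RNG state is untouched and repeated
# calls are bitwise identical. Ground truth is always known, so every
# analysis stage can be benchmarked offline.

#' Emission band model for titration simulation
#'
#' A single Gaussian emission band quenched statically: at quencher
#' concentration q the peak amplitude is F0 / (1 + Ksv q) and the band
#' center moves by `shift_at_saturation * Ksv q / (1 + Ksv q)` nm (a small
#' saturating red shift when positive). The band width is held constant —
#' static complex formation removes fluorophores without reshaping the
#' emission of those remaining. Noise is multiplicative Gaussian on the
#' intensities (relative detector noise).
#'
#' @param f0 Zero-quencher peak amplitude, a.u.
#' @param lambda_center Band center, nm.
#' @param bandwidth Gaussian standard deviation of the band, nm.
#' @param ksv_true Quenching constant, L/mol.
#' @param shift_at_saturation Band shift at full saturation, nm
#'   (positive = red).
#' @param noise_sigma Relative noise standard deviation.
#' @return A list of class `"emission_model"`.
#' @export
emission_model <- function(f0 = 3300, lambda_center = 345, bandwidth = 25,
                           ksv_true = 5e4, shift_at_saturation = 2,
                           noise_sigma = 0) {
  stopifnot(f0 > 0, bandwidth > 0, noise_sigma >= 0, ksv_true >= 0)
  structure(
    list(f0 = f0, lambda_center = lambda_center, bandwidth = bandwidth,
         ksv_true = ksv_true, shift_at_saturation = shift_at_saturation,
         noise_sigma = noise_sigma),
    class = "emission_model"
  )
}

gaussian_band <- function(grid, center, amplitude, bandwidth) {
  amplitude * exp(-(grid - center)^2 / (2 * bandwidth^2))
}

#' Simulate a fluorescence quenching titration
#'
#' @param model An [emission_model()].
#' @param concentrations Quencher concentrations, mol/L, including 0.
#' @param grid Emission wavelength grid, nm.
#' @param temperature Temperature recorded in the metadata, K.
#' @param seed Integer seed (`NULL` = use the current RNG state).
#' @return List of [spectrum()] objects with `ligand_conc_M` and
#'   `temperature_K` metadata.
#' @examples
#' spectra <- simulate_titration(emission_model(), dilution_ladder())
#' stern_volmer_fit(build_quench_table(spectra))
#' @export
simulate_titration <- function(model, concentrations = dilution_ladder(),
                               grid = seq(300, 500, by = 1),
                               temperature = 298, seed = NULL) {
  stopifnot(inherits(model, "emission_model"))
  if (!any(concentrations == 0)) {
    stop_quenchlab("concentrations must include the zero-ligand reference",
                   "quenchlab_domain_error")
  }
  with_seed(seed, {
    lapply(concentrations, function(q) {
      sat <- model$ksv_true * q / (1 + model$ksv_true * q)
      center <- model$lambda_center + model$shift_at_saturation * sat
      it <- gaussian_band(grid, center, model$f0 / (1 + model$ksv_true * q),
                          model$bandwidth)
      if (model$noise_sigma > 0) {
        it <- it * (1 + model$noise_sigma * stats::rnorm(length(grid)))
      }
      spectrum(grid, it, meta = list(ligand_conc_M = q, temperature_K = temperature))
    })
  })
}

#' Quenching mechanism scenario
#'
#' Bundles the temperature dependence of the quenching constant with a
#' concentration ladder at a realistic signal-to-noise level for each
#' mechanism. The static scenario uses complex-formation constants of
#' order 1e4-1e5 L/mol decreasing with temperature over a micromolar
#' ladder; the dynamic scenario uses collisional constants of order 1e2
#' L/mol increasing with temperature over a millimolar ladder (the
#' concentration range a collisional quencher needs for comparable
#' fractional quenching).
#'
#' @param kind `"static"` or `"dynamic"`.
#' @param tau0 Unquenched lifetime, s.
#' @return A list of class `"mechanism_scenario"`: `kind`,
#'   `ksv_by_temperature` (named numeric, names are temperatures in K),
#'   `concentrations`, `tau0`.
#' @export
mechanism_scenario <- function(kind = c("static", "dynamic"), tau0 = 1e-8) {
  kind <- match.arg(kind)
  if (kind == "static") {
    ksv <- c("298" = 5.0e4, "304" = 4.9e4, "310" = 4.0e4)
    conc <- dilution_ladder()
  } else {
    ksv <- c("298" = 100, "304" = 120, "310" = 140)
    conc <- dilution_ladder() * 500  # 0 to 13.3 mM
  }
  kq <- ksv / tau0
  if (kind == "static") {
    stopifnot(all(diff(ksv) < 0), min(kq) > 2e10)
  } else {
    stopifnot(all(diff(ksv) > 0), max(kq) < 2e10)
  }
  structure(
    list(kind = kind, ksv_by_temperature = ksv, concentrations = conc, tau0 = tau0),
    class = "mechanism_scenario"
  )
}

#' Simulate per-temperature quenching tables for a mechanism scenario
#'
#' Runs [simulate_titration()] at each scenario temperature and assembles
#' [quench_table()]s through the full spectral pipeline.
#'
#' @param scenario A [mechanism_scenario()].
#' @param noise_sigma Relative noise on intensities.
#' @param seed Integer seed.
#' @param response_mode Passed to [build_quench_table()].
#' @return List of [quench_table()]s, one per temperature.
#' @export
simulate_quench_tables <- function(scenario, noise_sigma = 0, seed = NULL,
                                   response_mode = "peak") {
  stopifnot(inherits(scenario, "mechanism_scenario"))
  with_seed(seed, {
    lapply(names(scenario$ksv_by_temperature), function(tk) {
      model <- emission_model(ksv_true = scenario$ksv_by_temperature[[tk]],
                              noise_sigma = noise_sigma)
      spectra <- simulate_titration(model, scenario$concentrations,
                                    temperature = as.numeric(tk))
      build_quench_table(spectra, response_mode = response_mode)
    })
  })
}

#' Default synchronous-series generator targets
#'
#' Band positions and zero/top intensities per residue class. The Trp
#' (delta-lambda 60 nm) band runs 274 to 270 nm (a 4 nm blue shift) with
#' intensity 3311 to 1592 a.u.; the Tyr (delta-lambda 15 nm) band stays at
#' 303 nm with intensity 746 to 400 a.u.
#'
#' @return Nested list with `trp` and `tyr` entries, each holding
#'   `lambda0`, `lambda_top`, `intensity0`, `intensity_top`.
#' @export
sync_targets <- function() {
  list(
    trp = list(lambda0 = 274, lambda_top = 270, intensity0 = 3311, intensity_top = 1592),
    tyr = list(lambda0 = 303, lambda_top = 303, intensity0 = 746, intensity_top = 400)
  )
}

#' Simulate a pair of synchronous fluorescence series
#'
#' Gaussian bands whose centers and amplitudes interpolate linearly in
#' concentration between the zero-ligand and top-concentration targets;
#' multiplicative Gaussian noise.
#'
#' @param targets Target list as from [sync_targets()].
#' @param concentrations Ligand concentrations, mol/L, including 0.
#' @param noise_sigma Relative noise standard deviation.
#' @param seed Integer seed.
#' @param grid Wavelength grid, nm.
#' @param bandwidth Gaussian band standard deviation, nm.
#' @return List with `trp` (delta-lambda 60) and `tyr` (delta-lambda 15)
#'   [sync_series()] objects.
#' @export
simulate_sync_pair <- function(targets = sync_targets(),
                               concentrations = dilution_ladder(),
                               noise_sigma = 0, seed = NULL,
                               grid = seq(200, 350, by = 1), bandwidth = 12) {
  stopifnot(any(concentrations == 0))
  qmax <- max(concentrations)
  make_series <- function(tg, delta_lambda) {
    spectra <- lapply(concentrations, function(q) {
      u <- if (qmax > 0) q / qmax else 0
      center <- tg$lambda0 + (tg$lambda_top - tg$lambda0) * u
      amp <- tg$intensity0 + (tg$intensity_top - tg$intensity0) * u
      it <- gaussian_band(grid, center, amp, bandwidth)
      if (noise_sigma > 0) it <- it * (1 + noise_sigma * stats::rnorm(length(grid)))
      spectrum(grid, it, meta = list(ligand_conc_M = q, delta_lambda_nm = delta_lambda))
    })
    sync_series(spectra, delta_lambda)
  }
  with_seed(seed, {
    trp <- make_series(targets$trp, 60)
    tyr <- make_series(targets$tyr, 15)
    list(trp = trp, tyr = tyr)
  })
}

#' Simulate a CD spectrum from known structure fractions
#'
#' Linear mixture of the basis components weighted by the fractions, plus
#' additive Gaussian noise scaled to the mixture's peak amplitude.
#'
#' @param fractions A [structure_fractions()] object.
#' @param basis A [cd_basis()].
#' @param noise_sigma Noise standard deviation as a fraction of the peak
#'   absolute amplitude.
#' @param seed Integer seed.
#' @param meta Metadata list for the resulting spectrum.
#' @return A [cd_spectrum()].
#' @export
simulate_cd <- function(fractions, basis = default_cd_basis(),
                        noise_sigma = 0, seed = NULL, meta = list()) {
  stopifnot(inherits(fractions, "structure_fractions"), inherits(basis, "cd_basis"))
  fr <- c(fractions$alpha_helix, fractions$beta_sheet,
          fractions$beta_turn, fractions$random_coil)
  mix <- as.numeric(basis$components %*% fr)
  with_seed(seed, {
    if (noise_sigma > 0) {
      mix <- mix + noise_sigma * max(abs(mix)) * stats::rnorm(length(mix))
    }
    cd_spectrum(basis$wavelengths, mix, meta = meta)
  })
}

#' Nominal Trolox standard curve
#'
#' A curve specification for simulation, without calibration data: the
#' defaults (2 percent response per mg/L over an intercept of 5 percent)
#' keep Trolox-equivalent values of 0-45 mg/L inside the usable 0-100
#' percent assay window.
#'
#' @param slope Response units per mg/L Trolox.
#' @param intercept Response at zero Trolox.
#' @param response_kind `"percent_rate"` or `"reducing_power"`.
#' @return A `"trolox_curve"` object with `r_squared = 1` and zero
#'   standards (a specification, not a calibration).
#' @export
nominal_trolox_curve <- function(slope = 2, intercept = 5,
                                 response_kind = c("percent_rate", "reducing_power")) {
  response_kind <- match.arg(response_kind)
  stopifnot(slope != 0)
  structure(
    list(slope = slope, intercept = intercept, r_squared = 1,
         response_kind = response_kind, n_standards = 0L),
    class = "trolox_curve"
  )
}

#' Simulate assay reads and Trolox standards
#'
#' Maps true Trolox-equivalent values through the curve into assay
#' responses, then inverts the responses into the absorbance roles of each
#' assay's defining formula (fixed control absorbances: ABTS A0 = 0.80;
#' DPPH Ab = 0.90, Ac = 0.02; FRAP A1 = 0.05, A0 = 0.10). Standards are
#' generated from the same curve. Noise is multiplicative Gaussian on
#' every absorbance and standard response.
#'
#' @param true_teac Named numeric vector of true TEAC values, mg/L.
#' @param curve A `"trolox_curve"` (e.g. [nominal_trolox_curve()]); must be
#'   `"reducing_power"` for FRAP and `"percent_rate"` otherwise.
#' @param assay `"ABTS"`, `"DPPH"` or `"FRAP"`.
#' @param noise_sigma Relative noise standard deviation.
#' @param seed Integer seed.
#' @param standards_conc Trolox standard concentrations, mg/L.
#' @return List with `reads` (tibble `assay,sample_id,role,absorbance`),
#'   `standards` (tibble `trolox_mg_per_L,response`) and `truth`.
#' @export
simulate_assay <- function(true_teac, curve = nominal_trolox_curve(),
                           assay = c("ABTS", "DPPH", "FRAP"),
                           noise_sigma = 0, seed = NULL,
                           standards_conc = c(5, 10, 20, 40)) {
  assay <- match.arg(assay)
  stopifnot(inherits(curve, "trolox_curve"), is.numeric(true_teac))
  if (assay == "FRAP" && curve$response_kind != "reducing_power") {
    stop_quenchlab("FRAP simulation needs a reducing_power curve", "quenchlab_domain_error")
  }
  if (assay != "FRAP" && curve$response_kind != "percent_rate") {
    stop_quenchlab("ABTS/DPPH simulation needs a percent_rate curve", "quenchlab_domain_error")
  }
  ids <- names(true_teac)
  if (is.null(ids)) ids <- sprintf("sample%02d", seq_along(true_teac))
  resp <- curve$intercept + curve$slope * true_teac
  with_seed(seed, {
    noisy <- function(x) if (noise_sigma > 0) x * (1 + noise_sigma * stats::rnorm(length(x))) else x
    reads <- do.call(rbind, lapply(seq_along(resp), function(i) {
      r <- unname(resp[i])
      ab <- switch(assay,
        ABTS = c(A0 = 0.80, A1 = 0.80 * (1 - r / 100)),
        DPPH = c(Ab = 0.90, At = 0.90 * (1 - r / 100) - 0.02, Ac = 0.02),
        FRAP = c(At = r + 0.05 + 0.10, A1 = 0.05, A0 = 0.10)
      )
      ab <- noisy(ab)
      tibble::tibble(assay = assay, sample_id = ids[i],
                     role = names(ab), absorbance = unname(ab))
    }))
    standards <- tibble::tibble(
      trolox_mg_per_L = standards_conc,
      response = noisy(curve$intercept + curve$slope * standards_conc)
    )
    list(reads = reads, standards = standards,
         truth = stats::setNames(as.numeric(true_teac), ids))
  })
}

#' Simulate a complete interaction study
#'
#' One seeded call producing every input the analysis pipeline consumes:
#' per-temperature quenching titrations (static scenario: quenching
#' constants {5.0, 4.9, 4.0}e4 L/mol at 298/304/310 K, micromolar ladder),
#' a synchronous Trp/Tyr series pair, CD spectra across protein:ligand
#' mass ratios following a helix-to-sheet conversion trajectory, and
#' ABTS/DPPH/FRAP assay reads with Trolox standards. Ground truth for
#' every stage is returned under `truth`.
#'
#' @param seed Integer seed.
#' @param noise_sigma Relative noise standard deviation applied to every
#'   simulated signal.
#' @return Nested list with components `titration`, `sync`, `cd`, `assay`,
#'   `truth`, `seed`, `noise_sigma`, directly consumable by [run_study()].
#' @export
simulate_study <- function(seed = 42, noise_sigma = 0.01) {
  scenario <- mechanism_scenario("static")
  basis <- default_cd_basis()
  ratios <- c("1:0", "2:1", "1:1", "1:2", "1:4")
  # helix-to-sheet conversion trajectory (percent, renormalised to sum 1)
  comp <- rbind(
    c(18.8, 31.1, 19.2, 30.5),
    c(8.1, 52.7, 17.3, 28.0),
    c(7.0, 52.7, 17.0, 28.6),
    c(6.7, 52.9, 16.8, 28.6),
    c(6.4, 52.9, 16.7, 28.8)
  )
  teac <- list(
    ABTS = c(protein = 9.09, complex_low = 17.39, complex_high = 25.88),
    DPPH = c(protein = 1.37, complex_low = 2.90, complex_high = 4.65),
    FRAP = c(protein = 3.75, complex_low = 5.50, complex_high = 7.20)
  )
  with_seed(seed, {
    titration <- stats::setNames(
      lapply(names(scenario$ksv_by_temperature), function(tk) {
        model <- emission_model(ksv_true = scenario$ksv_by_temperature[[tk]],
                                noise_sigma = noise_sigma)
        simulate_titration(model, scenario$concentrations,
                           temperature = as.numeric(tk))
      }),
      names(scenario$ksv_by_temperature)
    )
    sync <- simulate_sync_pair(noise_sigma = noise_sigma)
    cd_fracs <- lapply(seq_len(nrow(comp)), function(i) {
      fr <- comp[i, ] / sum(comp[i, ])
      structure_fractions(fr[1], fr[2], fr[3], fr[4])
    })
    names(cd_fracs) <- ratios
    cd_spectra <- lapply(ratios, function(r) {
      simulate_cd(cd_fracs[[r]], basis, noise_sigma = 2 * noise_sigma,
                  meta = list(ratio = r))
    })
    names(cd_spectra) <- ratios
    assay <- list(
      ABTS = simulate_assay(teac$ABTS, nominal_trolox_curve(), "ABTS",
                            noise_sigma = noise_sigma),
      DPPH = simulate_assay(teac$DPPH, nominal_trolox_curve(), "DPPH",
                            noise_sigma = noise_sigma),
      FRAP = simulate_assay(teac$FRAP,
                            nominal_trolox_curve(slope = 0.02, intercept = 0.05,
                                                 response_kind = "reducing_power"),
                            "FRAP", noise_sigma = noise_sigma)
    )
    list(
      titration = titration,
      sync = sync,
      cd = list(spectra = cd_spectra, basis = basis),
      assay = assay,
      truth = list(
        ksv_by_temperature = scenario$ksv_by_temperature,
        tau0 = scenario$tau0,
        mechanism = "static",
        n_sites = 1,
        sync_targets = sync_targets(),
        cd_fractions = cd_fracs,
        teac = teac
      ),
      seed = seed,
      noise_sigma = noise_sigma
    )
  })
}
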