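# Weights of the native-protein composition (percent, renormalised to
# fractions) used as the canonical recovery mixture.
native_fractions <- function() {
  w <- c(18.8, 31.1, 19.2, 30.5) / sum(c(18.8, 31.1, 19.2, 30.5))
  structure_fractions(w[1], w[2], w[3], w[4])
}

test_that("noiseless mixtures are recovered to 1e-6", {
  fr <- native_fractions()
  cd <- simulate_cd(fr, default_cd_basis())
  est <- deconvolve_cd(cd, default_cd_basis())
  expect_equal(est$alpha_helix, fr$alpha_helix, tolerance = 1e-6)
  expect_equal(est$beta_sheet, fr$beta_sheet, tolerance = 1e-6)
  expect_equal(est$beta_turn, fr$beta_turn, tolerance = 1e-6)
  expect_equal(est$random_coil, fr$random_coil, tolerance = 1e-6)
  expect_lt(est$residual_norm, 1e-8)
})

test_that("a pure basis component deconvolves to the unit vertex", {
  basis <- default_cd_basis()
  cd <- cd_spectrum(basis$wavelengths, basis$components[, "helix"])
  est <- deconvolve_cd(cd, basis)
  expect_equal(est$alpha_helix, 1, tolerance = 1e-9)
  expect_equal(est$beta_sheet + est$beta_turn + est$random_coil, 0, tolerance = 1e-9)
})

test_that("fractions sum to one and survive noise", {
  fr <- native_fractions()
  basis <- default_cd_basis()
  errs <- vapply(1:100, function(i) {
    cd <- simulate_cd(fr, basis, noise_sigma = 0.02, seed = PROPERTY_SEED + i)
    est <- deconvolve_cd(cd, basis)
    expect_equal(est$alpha_helix + est$beta_sheet + est$beta_turn + est$random_coil,
                 1, tolerance = 1e-9)
    mean(abs(c(est$alpha_helix - fr$alpha_helix, est$beta_sheet - fr$beta_sheet,
               est$beta_turn - fr$beta_turn, est$random_coil - fr$random_coil)))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})

test_that("fractions are invariant to positive rescaling of the signal", {
  fr <- native_fractions()
  basis <- default_cd_basis()
  cd <- simulate_cd(fr, basis, noise_sigma = 0.02, seed = PROPERTY_SEED)
  base <- deconvolve_cd(cd, basis)
  set.seed(PROPERTY_SEED)
  for (scale in stats::runif(5, 0.01, 100)) {
    scaled <- cd_spectrum(cd$wavelengths, cd$intensities * scale)
    est <- deconvolve_cd(scaled, basis)
    expect_equal(est$alpha_helix, base$alpha_helix, tolerance = 1e-9)
    expect_equal(est$random_coil, base$random_coil, tolerance = 1e-9)
  }
})

test_that("NNLS agrees with an exhaustive simplex grid search on toy spectra", {
  basis <- default_cd_basis()
  # four-wavelength toy problems at informative band positions
  wl <- c(195, 208, 218, 222)
  A <- apply(basis$components, 2, function(col) {
    stats::approx(basis$wavelengths, col, xout = wl)$y
  })
  set.seed(PROPERTY_SEED)
  for (i in 1:5) {
    f_true <- as.numeric(stats::rgamma(4, 1))
    f_true <- f_true / sum(f_true)
    b <- as.numeric(A %*% f_true)
    toy <- spectrum(wl, b)
    est <- deconvolve_cd(toy, basis)
    oracle <- simplex_grid_oracle(A, b)
    est_vec <- c(est$alpha_helix, est$beta_sheet, est$beta_turn, est$random_coil)
    expect_true(all(abs(est_vec - oracle) < 0.002))
  }
})

test_that("degenerate and ill-conditioned inputs are rejected", {
  basis <- default_cd_basis()
  zero <- cd_spectrum(basis$wavelengths, rep(0, length(basis$wavelengths)))
  expect_error(deconvolve_cd(zero, basis), class = "quenchlab_degenerate_error")
  bad <- basis$components
  bad[, "sheet"] <- bad[, "helix"]
  rank_def <- cd_basis(basis$wavelengths, bad)
  cd <- simulate_cd(native_fractions(), basis)
  expect_error(deconvolve_cd(cd, rank_def), class = "quenchlab_conditioning_error")
  narrow <- cd_basis(seq(200, 250, 1), basis$components[11:61, ])
  expect_error(deconvolve_cd(cd, narrow), class = "quenchlab_domain_error")
})

test_that("composition deltas match the published before/after comparison", {
  d <- composition_delta(c(18.8, 31.1, 19.2, 30.5), c(6.4, 52.9, 16.7, 28.8))
  expect_equal(unname(d[["alpha_helix"]]), -12.4, tolerance = 1e-9)
  expect_equal(unname(d[["beta_sheet"]]), 21.8, tolerance = 1e-9)
  same <- composition_delta(native_fractions(), native_fractions())
  expect_equal(unname(same), rep(0, 4))
})

test_that("composition deltas between normalised fraction sets sum to zero", {
  set.seed(PROPERTY_SEED)
  for (i in 1:20) {
    a <- as.numeric(stats::rgamma(4, 1)); a <- a / sum(a)
    b <- as.numeric(stats::rgamma(4, 1)); b <- b / sum(b)
    d <- composition_delta(structure_fractions(a[1], a[2], a[3], a[4]),
                           structure_fractions(b[1], b[2], b[3], b[4]))
    expect_equal(sum(d), 0, tolerance = 1e-12)
  }
})

test_that("basis CSV round-trips through read_basis_csv", {
  basis <- default_cd_basis()
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(wavelength_nm = basis$wavelengths, basis$components)
  utils::write.csv(df, path, row.names = FALSE)
  b2 <- read_basis_csv(path)
  expect_equal(b2$components, basis$components, tolerance = 1e-12)
})
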