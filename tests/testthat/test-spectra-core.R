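test_that("spectrum CSV round-trip preserves values bit-identically", {
  s <- gaussian_spectrum(345, meta = list(sample = "blank", temperature_K = 298))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_identical(s2$wavelengths, s$wavelengths)
  expect_identical(s2$intensities, s$intensities)
  expect_equal(s2$meta$sample, "blank")
  expect_equal(s2$meta$temperature_K, 298)
  expect_equal(length(s2), 201L)
})

test_that("malformed spectrum CSVs raise informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,intensity", "300,1", "301,2", "301,3", "302,1"), path)
  expect_error(read_spectrum_csv(path), "301", class = "quenchlab_data_error")
  writeLines(c("wl,intensity", "300,1", "301,2"), path)
  expect_error(read_spectrum_csv(path), "wavelength_nm", class = "quenchlab_format_error")
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(300, 301), c(1, 2)), class = "quenchlab_invalid_spectrum")
  expect_error(spectrum(c(300, 302, 301), c(1, 2, 3)), class = "quenchlab_invalid_spectrum")
  expect_error(spectrum(300:302, c(1, NA, 3)), class = "quenchlab_invalid_spectrum")
  expect_error(spectrum(300:303, c(1, 2, Inf, 3)), class = "quenchlab_invalid_spectrum")
})

test_that("find_peak locates symmetric and off-grid band maxima", {
  s <- gaussian_spectrum(345)
  expect_equal(find_peak(s, refine = TRUE)$lambda_max, 345, tolerance = 1e-6)
  # off-grid center: dense-grid argmax oracle places the maximum at 345.4 nm
  s2 <- gaussian_spectrum(345.4)
  pk <- find_peak(s2, refine = TRUE)
  expect_lt(abs(pk$lambda_max - 345.4), 0.1)
  expect_identical(pk$method, "parabolic")
  # refinement never reports an intensity below the sampled maximum
  expect_gte(pk$intensity, max(s2$intensities) - 1e-6)
})

test_that("find_peak tie and degenerate rules are deterministic", {
  grid <- seq(300, 400, by = 1)
  it <- rep(1, length(grid))
  it[grid == 340] <- 5
  it[grid == 350] <- 5
  s <- spectrum(grid, it)
  expect_warning(pk <- find_peak(s), class = "quenchlab_peak_tie")
  expect_equal(pk$lambda_max, 340)
  flat <- spectrum(grid, rep(2, length(grid)))
  expect_warning(pf <- find_peak(flat), class = "quenchlab_degenerate_peak")
  expect_equal(pf$lambda_max, 300)
})

test_that("argmax mode matches brute force on random spectra", {
  set.seed(PROPERTY_SEED)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    wl <- sort(sample(seq(200, 500, by = 0.5), n))
    it <- stats::runif(n, 0.1, 100)
    s <- spectrum(wl, it)
    pk <- find_peak(s, refine = FALSE)
    expect_identical(pk$lambda_max, wl[which.max(it)])
    expect_identical(pk$intensity, max(it))
  }
})

test_that("peak_shift signs and labels follow the red/blue convention", {
  expect_equal(peak_shift(274, 270), list(shift_nm = -4, label = "blue"))
  expect_equal(peak_shift(345, 347), list(shift_nm = 2, label = "red"))
  expect_equal(peak_shift(345, 345), list(shift_nm = 0, label = "none"))
  pk1 <- find_peak(gaussian_spectrum(274, grid = seq(200, 350, 1)))
  pk2 <- find_peak(gaussian_spectrum(270, grid = seq(200, 350, 1)))
  expect_equal(peak_shift(pk1, pk2)$shift_nm, -4)
})

test_that("percent_change reproduces worked intensity declines", {
  expect_equal(round(percent_change(3311, 1592), 2), 51.92)
  expect_equal(round(percent_change(746, 400), 2), 46.38)
  expect_equal(percent_change(100, 100), 0)
  expect_error(percent_change(0, 10), class = "quenchlab_domain_error")
  expect_error(percent_change(-5, 10), class = "quenchlab_domain_error")
})

test_that("percent_change satisfies the complement identity", {
  set.seed(PROPERTY_SEED)
  a <- stats::runif(100, 0.1, 1e4)
  b <- stats::runif(100, 0.1, 1e4)
  expect_equal(percent_change(a, b), 100 - 100 * b / a, tolerance = 1e-12)
})

test_that("spectrum_at interpolates linearly and rejects extrapolation", {
  s <- spectrum(c(300, 310, 320), c(0, 10, 0))
  expect_equal(spectrum_at(s, 305), 5)
  expect_error(spectrum_at(s, 299), class = "quenchlab_domain_error")
})

test_that("long-format CSV reads one spectrum per series", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- rbind(
    data.frame(series_id = "a", wavelength_nm = 300:310, intensity = 1:11,
               ligand_conc_M = 0),
    data.frame(series_id = "b", wavelength_nm = 300:310, intensity = 11:1,
               ligand_conc_M = 1e-5)
  )
  utils::write.csv(df, path, row.names = FALSE)
  out <- read_spectra_long(path)
  expect_named(out, c("a", "b"))
  expect_equal(out$a$meta$ligand_conc_M, 0)
  expect_equal(out$b$intensities, as.numeric(11:1))
})
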