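test_that("Stern-Volmer fit is exact on exact linear data", {
  tab <- exact_sv_table(5e4)
  fit <- stern_volmer_fit(tab)
  expect_equal(fit$ksv, 5e4, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_equal(fit$kq * fit$tau0, fit$ksv)  # exact identity
  fixed <- stern_volmer_fit(tab, fix_intercept = TRUE)
  expect_equal(fixed$ksv, 5e4, tolerance = 1e-9)
  expect_identical(fixed$intercept, 1)
})

test_that("Kq from published quenching constants exceeds the diffusion limit", {
  fits <- lapply(names(TABLE1_KSV), function(tk) {
    stern_volmer_fit(exact_sv_table(TABLE1_KSV[[tk]], temperature = as.numeric(tk)))
  })
  kq <- vapply(fits, `[[`, numeric(1), "kq")
  # smallest Kq: 0.40e5 / 1e-8 = 4.0e12, within 1% of the printed 4.02e12
  # (the published value reflects an unrounded quenching constant)
  expect_lt(abs(min(kq) - 4.02e12) / 4.02e12, 0.01)
  for (f in fits) expect_equal(f$kq * f$tau0, f$ksv, tolerance = 1e-14)
})

test_that("Ksv is recovered within 2% from noisy titrations (median over seeds)", {
  ksv <- 5e4
  err <- vapply(1:100, function(i) {
    spectra <- simulate_titration(emission_model(ksv_true = ksv, noise_sigma = 0.01),
                                  seed = PROPERTY_SEED + i)
    abs(stern_volmer_fit(build_quench_table(spectra))$ksv - ksv) / ksv
  }, numeric(1))
  expect_lt(stats::median(err), 0.02)
})

test_that("negative slope and short tables are flagged", {
  tab <- quench_table(c(0, 1e-5, 2e-5), c(100, 110, 120), 298)
  expect_warning(fit <- stern_volmer_fit(tab), class = "quenchlab_enhancement")
  expect_lt(fit$ksv, 0)
  short <- quench_table(c(0, 1e-5), c(100, 90), 298)
  expect_error(stern_volmer_fit(short), class = "quenchlab_fit_error")
})

test_that("double-log fit inverts its own forward model", {
  ka <- 7.16e4
  q <- dilution_ladder()
  tab <- quench_table(q, 3300 / (1 + ka * q), 298)
  fit <- double_log_fit(tab)
  expect_lt(abs(fit$ka - ka) / ka, 0.001)
  expect_lt(abs(fit$n - 1), 0.001)
})

test_that("double-log OLS agrees with the exhaustive grid-search oracle", {
  ka <- 7.16e4
  q <- dilution_ladder()
  set.seed(PROPERTY_SEED)
  f <- 3300 / (1 + ka * q) * (1 + 0.01 * stats::rnorm(length(q)))
  tab <- quench_table(q, f, 298)
  fit <- double_log_fit(tab)
  oracle <- double_log_grid_oracle(tab, lgka_range = c(4.3, 5.3), n_range = c(0.7, 1.3))
  expect_equal(signif(log10(fit$ka), 3), signif(oracle[["lgka"]], 3), tolerance = 2e-3)
  expect_equal(signif(fit$n, 3), signif(oracle[["n"]], 3), tolerance = 2e-3)
})

test_that("points without quenching signal are dropped with a warning", {
  q <- dilution_ladder()
  f <- 3300 / (1 + 5e4 * q)
  f[3] <- 3300  # equals f0 at a positive concentration
  tab <- quench_table(q, f, 298)
  expect_warning(fit <- double_log_fit(tab), class = "quenchlab_points_dropped")
  expect_equal(fit$n_points, 6L)
  expect_equal(fit$dropped, q[3])
  few <- quench_table(c(0, 1e-5, 2e-5, 3e-5), c(100, 100, 100, 90), 298)
  expect_warning(expect_error(double_log_fit(few), class = "quenchlab_fit_error"))
})

test_that("binding-site number stays close to 1 on single-site data", {
  devs <- vapply(1:50, function(i) {
    spectra <- simulate_titration(emission_model(ksv_true = 7.16e4, noise_sigma = 0.01),
                                  seed = PROPERTY_SEED + i)
    abs(double_log_fit(build_quench_table(spectra))$n - 1)
  }, numeric(1))
  expect_lt(stats::median(devs), 0.05)
})

test_that("mechanism classification follows the Kq threshold rule", {
  static_fits <- lapply(names(TABLE1_KSV), function(tk) {
    stern_volmer_fit(exact_sv_table(TABLE1_KSV[[tk]], temperature = as.numeric(tk)))
  })
  call <- classify_mechanism(static_fits)
  expect_identical(call$label, "static")
  expect_identical(call$ksv_temperature_trend, "decreasing")

  dyn_fits <- lapply(1:3, function(i) {
    ksv <- c(10, 12, 14)[i]  # Kq = 1, 1.2, 1.4 e9
    q <- dilution_ladder() * 5000
    stern_volmer_fit(quench_table(q, 100 / (1 + ksv * q),
                                  temperature = c(298, 304, 310)[i]))
  })
  dyn <- classify_mechanism(dyn_fits)
  expect_identical(dyn$label, "dynamic")
  expect_identical(dyn$ksv_temperature_trend, "increasing")

  # exactly at the threshold: ambiguous
  at <- stern_volmer_fit(exact_sv_table(200, q = dilution_ladder() * 500))
  expect_equal(at$kq, 2e10, tolerance = 1e-9)
  expect_identical(classify_mechanism(list(at))$label, "ambiguous")
})

test_that("single-temperature classification carries a caveat", {
  fit <- stern_volmer_fit(exact_sv_table(5e4))
  call <- classify_mechanism(list(fit))
  expect_identical(call$label, "static")
  expect_identical(call$ksv_temperature_trend, "flat")
  expect_true(any(grepl("single temperature", call$evidence)))
})

test_that("fitted slope equals the closed-form covariance ratio", {
  set.seed(PROPERTY_SEED)
  for (i in 1:500) {
    n <- sample(4:12, 1)
    q <- c(0, sort(stats::runif(n - 1, 1e-6, 5e-5)))
    f <- stats::runif(n, 10, 5000)
    tab <- quench_table(q, f, 298)
    fit <- suppressWarnings(stern_volmer_fit(tab))
    oracle <- closed_form_ols(q, f[1] / f)
    expect_equal(fit$ksv, oracle[["slope"]], tolerance = 1e-10)
    expect_equal(fit$intercept, oracle[["intercept"]], tolerance = 1e-10)
  }
})

test_that("static-quenching generator output decreases monotonically", {
  spectra <- simulate_titration(emission_model(ksv_true = 5e4))
  tab <- build_quench_table(spectra)
  expect_true(all(diff(tab$f) < 0))
})

test_that("simulated mechanisms are classified correctly across seeds", {
  classify_seeded <- function(kind, seed) {
    tables <- simulate_quench_tables(mechanism_scenario(kind),
                                     noise_sigma = 0.01, seed = seed)
    classify_mechanism(lapply(tables, stern_volmer_fit))$label
  }
  static_labels <- vapply(1:50, function(i) classify_seeded("static", PROPERTY_SEED + i),
                          character(1))
  dynamic_labels <- vapply(1:50, function(i) classify_seeded("dynamic", PROPERTY_SEED + 1000 + i),
                           character(1))
  expect_gte(sum(static_labels == "static"), 49)
  expect_gte(sum(dynamic_labels == "dynamic"), 49)
})
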