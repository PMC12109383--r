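test_that("Van't Hoff fit exactly inverts its own linear model", {
  dh <- 25400; ds <- 173.46; R <- 8.314
  temps <- c(298, 304, 310)
  ka <- exp(-dh / (R * temps) + ds / R)
  fit <- vant_hoff(data.frame(temps, ka))
  expect_equal(fit$dh, dh, tolerance = 1e-9)
  expect_equal(fit$ds, ds, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("published binding constants yield an exothermic fit", {
  # frozen three-point OLS oracle (closed-form covariance/variance on
  # ln Ka vs 1/T): dh = -17562.117 J/mol, ds = +33.69865 J/(mol K)
  fit <- vant_hoff(data.frame(as.numeric(names(TABLE1_KA)), unname(TABLE1_KA)))
  expect_equal(fit$dh, -17562.117, tolerance = 1e-6)
  expect_equal(fit$ds, 33.69865, tolerance = 1e-6)
  oracle <- closed_form_ols(1 / as.numeric(names(TABLE1_KA)), log(unname(TABLE1_KA)))
  expect_equal(fit$dh, -8.314 * oracle[["slope"]], tolerance = 1e-12)
  expect_equal(fit$ds, 8.314 * oracle[["intercept"]], tolerance = 1e-12)
})

test_that("two temperatures determine the line with undefined SEs", {
  fit <- vant_hoff(data.frame(c(298, 310), c(7.16e4, 5.45e4)))
  expect_equal(fit$r_squared, 1)
  expect_true(is.na(fit$se_dh) && is.na(fit$se_ds))
  expect_error(vant_hoff(data.frame(c(298, 298), c(1e4, 2e4))),
               class = "quenchlab_fit_error")
  expect_error(vant_hoff(data.frame(c(298, 310), c(-1, 2e4))),
               class = "quenchlab_domain_error")
})

test_that("Gibbs energy reproduces the worked thermodynamic identities", {
  g <- gibbs(25400, 173.46, c(298, 304, 310))
  expect_equal(round(g$dg / 1000, 2), c(-26.29, -27.33, -28.37))
  expect_true(all(g$spontaneous))
  g0 <- gibbs(0, 0, 298)
  expect_equal(g0$dg, 0)
  expect_false(g0$spontaneous)
  expect_error(gibbs(1, 1, -5), class = "quenchlab_domain_error")
})

test_that("Gibbs energy is linear in temperature", {
  set.seed(PROPERTY_SEED)
  for (i in 1:50) {
    dh <- stats::runif(1, -5e4, 5e4)
    ds <- stats::runif(1, -300, 300)
    t1 <- stats::runif(1, 250, 350)
    t2 <- stats::runif(1, 250, 350)
    d1 <- gibbs(dh, ds, t1)$dg
    d2 <- gibbs(dh, ds, t2)$dg
    expect_equal(d2 - d1, -ds * (t2 - t1), tolerance = 1e-9)
  }
})

test_that("the fitted model, Gibbs energy and predicted ln Ka are consistent", {
  fit <- vant_hoff(data.frame(as.numeric(names(TABLE1_KA)), unname(TABLE1_KA)))
  for (temp in fit$temperatures) {
    ln_ka_pred <- -fit$dh / (fit$gas_constant * temp) + fit$ds / fit$gas_constant
    dg <- gibbs(fit$dh, fit$ds, temp)$dg
    expect_equal(dg, -fit$gas_constant * temp * ln_ka_pred, tolerance = 1e-9)
  }
})

test_that("force classification covers every sign quadrant", {
  expect_identical(classify_forces(25400, 173.46)$label, "hydrophobic")
  expect_identical(classify_forces(-10000, 50)$label, "electrostatic")
  expect_identical(classify_forces(10000, -50)$label, "electrostatic+hydrophobic")
  expect_identical(classify_forces(-10000, -50)$label, "vdw+hbond")
  # zero bands
  expect_identical(classify_forces(50, 0.5)$label, "indeterminate")
  expect_identical(classify_forces(50, 100)$label, "indeterminate")
  expect_identical(classify_forces(1e4, 0.5)$label, "indeterminate")
  expect_identical(classify_forces(-50, -0.5)$label, "indeterminate")
  expect_identical(classify_forces(0, 0)$label, "indeterminate")
  # mapping is total: every combination yields one of the five labels
  labels <- c("hydrophobic", "electrostatic", "electrostatic+hydrophobic",
              "vdw+hbond", "indeterminate")
  for (dh in c(-1e4, 0, 1e4)) {
    for (ds in c(-50, 0, 50)) {
      expect_true(classify_forces(dh, ds)$label %in% labels)
    }
  }
})

test_that("enthalpy and entropy are recovered from noisy ln Ka data", {
  dh <- 25400; ds <- 173.46; R <- 8.314
  temps <- c(298, 304, 310)
  ln_ka_true <- -dh / (R * temps) + ds / R
  set.seed(PROPERTY_SEED)
  errs <- t(vapply(1:100, function(i) {
    ka <- exp(ln_ka_true + 0.02 * stats::rnorm(3))
    fit <- vant_hoff(data.frame(temps, ka))
    c(abs(fit$dh - dh) / abs(dh), abs(fit$ds - ds) / abs(ds))
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.05)
  expect_lt(stats::median(errs[, 2]), 0.05)
})
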