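test_that("single-exponential fitting is exact on model data and flags flat traces", {
  times <- seq(0, 0.1, length.out = 200)
  tr <- fluorescence_trace(times, 2 + 1.5 * exp(-50 * times),
                           partner_conc = 2, labeled_conc = 0.1)
  fit <- fit_single_exponential(tr)
  expect_lt(abs(fit$kobs - 50) / 50, 1e-6)
  expect_true(fit$ok)

  flat <- fluorescence_trace(times, rep(2, 200))
  expect_warning(ffit <- fit_single_exponential(flat))
  expect_false(ffit$ok)
  expect_true(is.na(ffit$kobs))

  # pseudo-first-order violation warns
  bad <- fluorescence_trace(times, 2 + exp(-50 * times),
                            partner_conc = 0.5, labeled_conc = 0.1)
  expect_warning(fit_single_exponential(bad), "pseudo-first-order")
})

test_that("noisy trace fit agrees with the brute-force grid oracle", {
  truth <- kinetic_ground_truth(240, 0.18, noise_sd = 0.01, seed = 5)
  tr <- gen_trace(truth, 1, seq(0, 5 / 240.18, length.out = 400))
  fit <- fit_single_exponential(tr)
  k_oracle <- oracle_grid_kobs(tr$times, tr$signal, 150, 350)
  expect_lt(abs(fit$kobs - 240.18) / 240.18, 0.02)
  expect_lt(abs(fit$kobs - k_oracle) / 240.18, 0.005)
})

test_that("association fits reproduce exact lines and the closed-form OLS", {
  s <- pfo_series(1:6, 240 * (1:6) + 0.18)
  fit <- fit_association(s)
  expect_equal(fit$kon, 240, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.18, tolerance = 1e-10)

  two <- fit_association(pfo_series(c(1, 2), c(240.18, 480.18)))
  expect_equal(two$kon, 240, tolerance = 1e-12)
  expect_true(is.na(two$kon_se))

  expect_error(pfo_series(c(2, 2, 2), c(1, 2, 3)), "distinct")
})

test_that("displacement fits recover the asymptote", {
  d <- seq(5, 60, by = 5)
  const <- fit_displacement(displacement_series(d, rep(0.18, 12)))
  expect_equal(const$koff, 0.18)
  expect_equal(const$amplitude, 0)

  exact <- fit_displacement(displacement_series(d, 0.18 + 2 * exp(-d / 10)))
  expect_equal(exact$koff, 0.18, tolerance = 1e-6)
  expect_equal(exact$decay_scale, 10, tolerance = 1e-4)

  noisy <- gen_displacement_series(kinetic_ground_truth(240, 0.18, seed = 9),
                                   10, 2.18, d, kobs_noise_sd = 0.01)
  fit <- fit_displacement(noisy)
  oracle <- oracle_displacement_koff(d, noisy$kobs_values)
  expect_lt(abs(fit$koff - 0.18) / 0.18, 0.05)
  expect_lt(abs(fit$koff - oracle) / 0.18, 0.05)

  expect_warning(fit_displacement(displacement_series(d, 0.18 + d * 0.01)),
                 "not overall decreasing")
})

test_that("Kd derivation reproduces the published variant rows", {
  r266g <- compute_kd(230, 0.70, 15, 0.01)
  expect_equal(signif(r266g$kd_nM, 2), 3.0)
  expect_equal(signif(r266g$kd_se, 1), 0.2)
  expect_equal(signif(compute_kd(222, 0.07)$kd_nM, 2), 0.32)
  expect_equal(signif(compute_kd(235, 0.030)$kd_nM, 2), 0.13)
  expect_warning(zero <- compute_kd(230, 0))
  expect_equal(zero$kd_nM, 0)
  expect_true(zero$flagged)
})

test_that("binding_kinetics keeps the Kd identity exactly", {
  for (i in 1:20) {
    kon <- withr::with_seed(i, runif(1, 1, 500))
    koff <- withr::with_seed(i + 100, runif(1, 0.001, 5))
    b <- binding_kinetics("v", kon, 1, koff, 0.01)
    expect_identical(b$kd_nM, koff / kon * 1e3)
  }
})

test_that("fold changes match the salt-series ratios and invert", {
  expect_equal(signif(fold_change(1.78, 0.18), 2), 9.9)
  expect_equal(fold_change(3, 3), 1)
  expect_equal(signif(fold_change(413, 10.6), 2), 39)
  expect_equal(fold_change(2, 5) * fold_change(5, 2), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("basal-rate extrapolation recovers exact synthetic data and the published rates", {
  flat <- fit_salt_dependence(salt_series(c(100, 200, 500, 800), rep(7, 4), "association"))
  expect_equal(flat$basal_rate, 7, tolerance = 1e-12)
  expect_equal(flat$slope_beta, 0, tolerance = 1e-12)

  I <- c(0.1, 0.2, 0.5, 0.8)
  exact <- fit_salt_dependence(salt_series(I * 1000, exp(log(5) + 1.0 / sqrt(I)),
                                           "association"))
  expect_equal(exact$basal_rate, 5, tolerance = 1e-10)
  expect_equal(exact$slope_beta, 1.0, tolerance = 1e-10)

  ref <- reference_tables()$salt_series
  d267l <- ref[ref$variant_id == "D267L" & ref$rate_kind == "association", ]
  bf <- fit_salt_dependence(salt_series(d267l$nacl_mM, d267l$rate, "association"))
  cf <- oracle_ols(1 / sqrt(d267l$nacl_mM / 1000), log(d267l$rate))
  expect_equal(bf$basal_rate, exp(unname(cf["intercept"])), tolerance = 1e-12)
  expect_equal(bf$basal_rate, 10.367, tolerance = 1e-3)

  expect_error(fit_salt_dependence(salt_series(I * 1000, c(1, 2, -1, 3), "association")),
               "positive")
})

test_that("LFER slopes obey the algebraic identity and the OLS oracle", {
  # identical kon, varying koff -> slopes exactly (0, 1)
  ks <- lapply(c(0.1, 0.3, 1, 3), function(koff) binding_kinetics("v", 240, 1, koff, 0.01))
  l <- lfer_regression(ks)
  expect_equal(l$slope_kon_vs_kd, 0, tolerance = 1e-12)
  expect_equal(l$slope_koff_vs_kd, 1, tolerance = 1e-12)

  # identity holds for arbitrary panels built from kon/koff
  for (i in 1:10) {
    kin <- lapply(1:5, function(j) {
      binding_kinetics("v", withr::with_seed(i * 100 + j, runif(1, 10, 500)), 1,
                       withr::with_seed(i * 100 + j + 50, runif(1, 0.01, 5)), 0.01)
    })
    li <- lfer_regression(kin)
    expect_equal(li$slope_koff_vs_kd - li$slope_kon_vs_kd, 1, tolerance = 1e-9)
  }

  # published five-variant panel, against closed-form OLS
  ref <- reference_tables()$kinetics
  panel <- lfer_regression(data.frame(kon = ref$kon_uM_s, koff = ref$koff_s,
                                      kd_nM = ref$koff_s / ref$kon_uM_s * 1e3))
  x <- log10(ref$koff_s / ref$kon_uM_s * 1e3)
  expect_equal(panel$slope_koff_vs_kd,
               unname(oracle_ols(x, log10(ref$koff_s))["slope"]), tolerance = 1e-12)
  expect_equal(panel$slope_koff_vs_kd, 1.008123, tolerance = 1e-5)
  expect_equal(panel$slope_kon_vs_kd, 0.008123, tolerance = 1e-3)

  expect_error(lfer_regression(ks[1:2]), "3 variants")
})

test_that("pearson_r2 handles exact, orthogonal and published data", {
  expect_equal(pearson_r2(1:5, 2 * (1:5) + 3), 1)
  expect_equal(pearson_r2(c(-1, 0, 1), c(1, -2, 1)), 0)
  # calibrated helicities against log10 koff across the variant panel
  h <- c(2, 3, 5, 11, 14)
  koff <- c(0.70, 0.383, 0.18, 0.07, 0.030)
  expect_equal(pearson_r2(h, log10(koff)), 0.9640, tolerance = 1e-4)
  expect_error(pearson_r2(c(1, 1, 1), 1:3), "constant")
})

test_that("full kinetic chain recovers ground-truth Kd within 5% at 1% noise", {
  truth <- kinetic_ground_truth(240, 0.18, noise_sd = 0.01, seed = 21)
  kobs <- vapply(1:6, function(conc) {
    tr_truth <- truth; tr_truth$seed <- truth$seed + conc
    k <- 240 * conc + 0.18
    fit_single_exponential(gen_trace(tr_truth, conc,
                                     seq(0, 5 / k, length.out = 300)))$kobs
  }, numeric(1))
  kon <- fit_association(pfo_series(1:6, kobs))$kon
  disp <- gen_displacement_series(truth, 10, 2.18, seq(5, 60, by = 5),
                                  kobs_noise_sd = 0.01 * 0.18)
  koff <- fit_displacement(disp)$koff
  kd <- compute_kd(kon, koff)$kd_nM
  expect_lt(abs(kd - 0.75) / 0.75, 0.05)
})
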