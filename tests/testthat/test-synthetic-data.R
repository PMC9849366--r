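test_that("gen_trace obeys the noiseless closed form and rejects bad time grids", {
  truth <- kinetic_ground_truth(240, 0.18, fluorescence_amplitude = 2, baseline = 1)
  times <- seq(0, 0.02, length.out = 100)
  tr <- gen_trace(truth, 1, times)
  # log-residual slope equals -(kon*conc + koff)
  slope <- oracle_ols(times, log((tr$signal - 1) / 2))[["slope"]]
  expect_equal(slope, -240.18, tolerance = 1e-10)
  expect_equal(tr$true_kobs, 240.18)

  flat <- kinetic_ground_truth(240, 0.18, fluorescence_amplitude = 0, baseline = 3)
  expect_equal(gen_trace(flat, 1, times)$signal, rep(3, 100))

  expect_error(gen_trace(truth, 1, c(0, 0.1, 0.1, 0.2)), "strictly increasing")
})

test_that("traces are seed-deterministic and refittable within 2% at 1% noise", {
  truth <- kinetic_ground_truth(240, 0.18, noise_sd = 0.01, seed = 1)
  times <- seq(0, 5 / 480.18, length.out = 300)
  tr1 <- gen_trace(truth, 2, times)
  tr2 <- gen_trace(truth, 2, times)
  expect_identical(tr1$signal, tr2$signal)
  tr3 <- gen_trace(kinetic_ground_truth(240, 0.18, noise_sd = 0.01, seed = 2), 2, times)
  expect_false(identical(tr1$signal, tr3$signal))

  k_oracle <- oracle_grid_kobs(tr1$times, tr1$signal, 300, 700)
  expect_lt(abs(k_oracle - 480.18) / 480.18, 0.02)
  fit <- fit_single_exponential(tr1)
  expect_lt(abs(fit$kobs - 480.18) / 480.18, 0.02)
  expect_lt(abs(fit$kobs - k_oracle) / 480.18, 0.005)
})

test_that("gen_association_series follows the linear law and OLS recovers the slope", {
  truth <- kinetic_ground_truth(240, 0.18)
  s <- gen_association_series(truth, 1:6)
  expect_equal(s$kobs_values, 240 * (1:6) + 0.18)
  expect_error(gen_association_series(truth, c(2, 2)), "2 distinct")

  noisy <- gen_association_series(kinetic_ground_truth(240, 0.18, seed = 7),
                                  1:6, kobs_noise_sd = 5)
  cf <- oracle_ols(noisy$concs, noisy$kobs_values)
  fitted <- fit_association(noisy)
  expect_equal(fitted$kon, unname(cf["slope"]), tolerance = 1e-12)
  expect_lt(abs(fitted$kon - 240), 3 * fitted$kon_se)
})

test_that("gen_displacement_series decays to koff and rejects bad scales", {
  truth <- kinetic_ground_truth(240, 0.18, seed = 3)
  s <- gen_displacement_series(truth, decay_scale = 10, initial_kobs = 2.18,
                               displacer_concs = seq(5, 60, by = 5))
  expect_equal(s$kobs_values[12], 0.18 + 2 * exp(-6), tolerance = 1e-12)
  flat <- gen_displacement_series(truth, 10, initial_kobs = 0.18,
                                  displacer_concs = seq(5, 60, by = 5))
  expect_equal(flat$kobs_values, rep(0.18, 12))
  expect_error(gen_displacement_series(truth, -1, 2.18, seq(5, 60, 5)), "positive")

  noisy <- gen_displacement_series(truth, 10, 2.18, seq(5, 60, by = 5),
                                   kobs_noise_sd = 0.005)
  fit <- fit_displacement(noisy)
  expect_lt(abs(fit$koff - 0.18) / 0.18, 0.05)
  expect_lt(abs(oracle_displacement_koff(noisy$displacer_concs, noisy$kobs_values) -
                  0.18) / 0.18, 0.05)
})

test_that("gen_itc_isotherm spans zero-enthalpy and stoichiometric limits", {
  zero <- gen_itc_isotherm(itc_ground_truth(84, 0, 0.84))
  expect_equal(zero$heats, rep(0, 18))

  tight <- gen_itc_isotherm(itc_ground_truth(1e-6, -68, 1))
  ratio <- cumsum(tight$injection_volumes) * 96 / (10 * 200)  # approx molar ratio
  pre <- which(ratio < 0.9)[-1]   # skip the small first injection
  post <- which(ratio > 1.15)
  expect_lt(max(abs(tight$heats[pre] - tight$heats[pre][1])) / abs(tight$heats[pre][1]), 0.05)
  expect_lt(max(abs(tight$heats[post])) / abs(tight$heats[pre][1]), 0.02)

  # round trip: the fitter recovers the generator truth to solver tolerance
  ex <- gen_itc_isotherm(itc_ground_truth(84, -68, 0.84))
  tp <- fit_one_site(ex)
  expect_equal(tp$kd, 84, tolerance = 1e-3)
  expect_equal(tp$dh, -68, tolerance = 1e-3)
  expect_equal(tp$n, 0.84, tolerance = 1e-3)
})

test_that("gen_cd_spectrum is pinned to the 222 nm anchors and inverts", {
  at222 <- function(sp) sp$mre[which.min(abs(sp$wavelengths - 222))]
  expect_equal(at222(gen_cd_spectrum(0)), -3000)
  expect_equal(at222(gen_cd_spectrum(1)), -42000)
  sp13 <- gen_cd_spectrum(0.13)
  expect_equal(at222(sp13), -8070)
  expect_equal(helicity_from_mre(sp13), 13)
  expect_error(gen_cd_spectrum(1.2), "\\[0, 1\\]")
  # determinism with noise
  a <- gen_cd_spectrum(0.5, noise_sd = 100, seed = 11)
  b <- gen_cd_spectrum(0.5, noise_sd = 100, seed = 11)
  expect_identical(a$mre, b$mre)
})

test_that("gen_shift_table encodes fractions as secondary shifts", {
  coil <- gen_shift_table(flat_profile(0))
  rc <- random_coil_for_sequence(synthetic_dreb2a_sequence("WT")$sequence, 244)
  expect_equal(compute_scs(coil, rc)$scs_ca_ppm, rep(0, 29))

  helix <- gen_shift_table(flat_profile(1))
  expect_equal(compute_scs(helix, rc)$scs_ca_ppm, rep(3.1, 29))

  short_rc <- random_coil_table(244:260, rep(55, 17))
  expect_error(gen_shift_table(flat_profile(0.5), short_rc), "261")

  # region mean 0.5 ppm -> about 16% downstream helicity
  prof <- flat_profile(0.5 / 3.1)
  rh <- region_helicity(compute_scs(gen_shift_table(prof), rc), c(262, 266))
  expect_equal(rh$percent_helix, 100 * 0.5 / 3.1, tolerance = 1e-12)
})

test_that("noisy generators are centred on truth across seeds", {
  # association slope over 100 seeds: |mean bias| under 1 SE of the mean
  slopes <- vapply(1:100, function(s) {
    ser <- gen_association_series(kinetic_ground_truth(240, 0.18, seed = s),
                                  1:6, kobs_noise_sd = 5)
    fit_association(ser)$kon
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 240), sd(slopes) / sqrt(100))
})
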