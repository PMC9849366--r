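make_shifts <- function(scs, rc) {
  chemical_shift_table(rc$residue_number,
                       strsplit(synthetic_dreb2a_sequence("WT")$sequence, "")[[1]],
                       rc$rc_ca_ppm + scs, cb_ppm = rc$rc_cb_ppm)
}

test_that("secondary shifts are observed minus random coil", {
  rc <- random_coil_for_sequence(synthetic_dreb2a_sequence("WT")$sequence, 244)
  expect_equal(compute_scs(make_shifts(0, rc), rc)$scs_ca_ppm, rep(0, 29))
  expect_equal(compute_scs(make_shifts(3.1, rc), rc)$scs_ca_ppm, rep(3.1, 29))

  # generator round trip: scs_ca = 3.1 * fraction per residue
  f <- withr::with_seed(2, runif(29))
  sq <- synthetic_dreb2a_sequence("WT")
  prof <- helix_profile(sq$sequence, f, first_residue = 244)
  scs <- compute_scs(gen_shift_table(prof), rc)
  expect_equal(scs$scs_ca_ppm, 3.1 * f, tolerance = 1e-12)

  # Cb present on both sides: Ca-minus-Cb metric defined and equals Ca SCS
  # when Cb sits at random coil
  expect_equal(scs$scs_ca_minus_cb_ppm[!is.na(scs$scs_ca_minus_cb_ppm)],
               scs$scs_ca_ppm[!is.na(scs$scs_ca_minus_cb_ppm)], tolerance = 1e-12)

  expect_error(compute_scs(make_shifts(0, rc), random_coil_table(244:260, rep(55, 17))),
               "261")
})

test_that("region helicity reproduces the published free- and bound-state values", {
  rc <- random_coil_for_sequence(synthetic_dreb2a_sequence("WT")$sequence, 244)
  prof02 <- compute_scs(make_shifts(0.2, rc), rc)
  rh <- region_helicity(prof02, c(262, 266))
  expect_equal(rh$percent_helix, 100 * 0.2 / 3.1)
  expect_equal(round_half_away(rh$percent_helix), 6)   # printed 6%

  full <- region_helicity(compute_scs(make_shifts(3.1, rc), rc), c(261, 267))
  expect_equal(full$percent_helix, 100)

  zero <- region_helicity(compute_scs(make_shifts(0, rc), rc), c(262, 266))
  expect_equal(zero$percent_helix, 0)

  # unassigned residues are excluded, not imputed
  sh <- make_shifts(0.5, rc)
  sh$ca_ppm[sh$residue_number %in% 263:265] <- NA
  sh$assigned[sh$residue_number %in% 263:265] <- FALSE
  rh2 <- region_helicity(compute_scs(sh, rc), c(262, 266))
  expect_equal(rh2$n_residues, 2)
  expect_error(region_helicity(compute_scs(sh, rc), c(263, 265)), "no assigned")

  # linear in the profile before clipping
  a <- region_helicity(compute_scs(make_shifts(1.3, rc), rc), c(262, 266))
  b <- region_helicity(compute_scs(make_shifts(2.6, rc), rc), c(262, 266))
  expect_equal(b$percent_helix, 2 * a$percent_helix, tolerance = 1e-12)
})

test_that("mean residue ellipticity follows the normalisation formula", {
  expect_equal(compute_mre(0, 110, 0.1, 1e-3), 0)
  expect_equal(compute_mre(-0.01, 110, 0.1, 1e-3), -1100)
  expect_equal(compute_mre(-0.01, 110, 0.1, 2e-3), -550)  # doubling c halves MRE
  expect_error(compute_mre(-0.01, 110, 0, 1e-3), "positive")
})

test_that("helicity from the 222 nm ellipticity uses the two-point anchors", {
  wl <- seq(200, 250, by = 0.5)
  expect_equal(helicity_from_mre(mre_spectrum(wl, rep(-3000, length(wl)))), 0)
  expect_equal(helicity_from_mre(mre_spectrum(wl, rep(-42000, length(wl)))), 100)
  expect_equal(helicity_from_mre(-8070), 13)
  expect_equal(helicity_from_mre(-100), 0)       # clipped at 0
  expect_error(helicity_from_mre(mre_spectrum(c(250, 260), c(0, 0))), "222")

  # Eq.-2 round trip with the generator is the identity on [0, 100]%
  for (f in seq(0, 1, by = 0.1))
    expect_equal(helicity_from_mre(gen_cd_spectrum(f)), 100 * f, tolerance = 1e-9)
})

test_that("TFE titration summaries keep order and reject duplicates", {
  same <- lapply(c(0, 30, 70), function(tfe)
    gen_cd_spectrum(0.2, tfe_percent = tfe))
  tt <- tfe_titration_summary(same)
  expect_equal(tt$percent_helix, rep(20, 3), tolerance = 1e-9)

  rising <- lapply(c(0, 10, 30, 50, 70), function(tfe)
    gen_cd_spectrum(0.1 + 0.008 * tfe, tfe_percent = tfe))
  expect_true(all(diff(tfe_titration_summary(rising)$percent_helix) > 0))

  # five-peptide panel keeps rank order at every TFE level
  f0 <- c(0.11, 0.12, 0.13, 0.17, 0.19)
  per_tfe <- lapply(c(0, 20, 40), function(tfe) {
    vapply(f0, function(f) helicity_from_mre(
      gen_cd_spectrum(f + (0.9 - f) * tfe / 100, tfe_percent = tfe)), numeric(1))
  })
  for (h in per_tfe) expect_equal(order(h), 1:5)

  expect_error(tfe_titration_summary(list(gen_cd_spectrum(0.1, tfe_percent = 10),
                                          gen_cd_spectrum(0.2, tfe_percent = 10))),
               "duplicate")
})

test_that("calibration fitting matches closed-form OLS and exact lines", {
  ident <- fit_calibration(c(2, 11, 14), c(2, 11, 14))
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_equal(ident$r_squared, 1)

  x <- c(11, 13, 17, 19)
  exact <- fit_calibration(1.538 * x - 14.93, x)
  expect_equal(exact$slope, 1.538, tolerance = 1e-12)
  expect_equal(exact$intercept, -14.93, tolerance = 1e-10)

  gx <- c(3, 9, 20); gy <- c(1, 14, 17)
  gen <- fit_calibration(gy, gx)
  cf <- oracle_ols(gx, gy)
  expect_equal(gen$slope, unname(cf["slope"]), tolerance = 1e-12)
  expect_equal(gen$intercept, unname(cf["intercept"]), tolerance = 1e-12)

  expect_error(fit_calibration(c(1, 2), c(1, 2)), "3 points")
})

test_that("applying the published calibration transfers CD onto the NMR scale", {
  line <- calibration_line(1.538, -14.93)
  expect_equal(round_half_away(apply_calibration(line, 13)), 5)
  expect_equal(round_half_away(apply_calibration(line, 19)), 14)
  expect_equal(apply_calibration(line, 14.93 / 1.538), 0, tolerance = 1e-12)
  floored <- apply_calibration(line, 2)
  expect_equal(as.numeric(floored), 0)
  expect_true(attr(floored, "floored"))

  # fitted line reproduces training responses up to OLS residuals
  gx <- c(3, 9, 20, 25); gy <- c(1, 14, 17, 30)
  gen <- fit_calibration(gy, gx)
  m <- lm(gy ~ gx)
  expect_equal(apply_calibration(gen, gx), unname(fitted(m)), tolerance = 1e-10)
})
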