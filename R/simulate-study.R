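#' Materialise a complete synthetic five-variant study
#'
#' Writes every input file of a WT/R266G/R266A/D267A/D267L-style coupled
#' folding-and-binding study into a directory, plus a `study.yaml` manifest
#' consumable by [run_study()]. Ground truths are the published per-variant
#' values: kinetic rate constants from the kinetics reference table
#' (traces at 1-6 uM partner with 1% amplitude noise; displacement series
#' at 5-60 uM competitor), region helix fractions from the published
#' region-averaged secondary shifts (free D262-R266, bound V261-D267),
#' CD helix fractions from the 0% TFE helicities with a TFE titration on
#' top, ITC parameters from the thermodynamics reference table, and a WT
#' ionic-strength series generated from the basal-rate model. All noise is
#' seeded; identical `seed` gives a byte-identical study.
#'
#' @param dir output directory (created if needed).
#' @param seed master integer seed; per-file seeds are derived from it.
#' @param trace_noise Gaussian trace noise as a fraction of the
#'   fluorescence amplitude (default 0.01).
#' @param n_trace_points points per trace (default 250).
#' @return the study config (invisibly), as read back by
#'   [read_study_config()].
#' @export
simulate_study <- function(dir, seed = 1L, trace_noise = 0.01,
                           n_trace_points = 250L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    (seed * 1009L + counter * 101L) %% 2147483647L
  }
  ref <- reference_tables()
  kin <- ref$kinetics; hel <- ref$helicity; itc <- ref$thermo
  variants <- kin$variant_id
  cfg <- list(seed = seed, temperature_K = 298.15, reference_scs = 3.1,
              regions = list(free = c(262L, 266L), bound = c(261L, 267L)),
              variants = list())

  for (vid in variants) {
    krow <- kin[kin$variant_id == vid, ]
    hrow <- hel[hel$variant_id == vid, ]
    vcfg <- list()

    # stopped-flow traces, 1-6 uM partner
    truth0 <- kinetic_ground_truth(krow$kon_uM_s, krow$koff_s,
                                   fluorescence_amplitude = 1, baseline = 5,
                                   noise_sd = trace_noise, seed = seed)
    vcfg$traces <- lapply(1:6, function(conc) {
      tr_truth <- truth0; tr_truth$seed <- next_seed()
      kobs <- tr_truth$kon * conc + tr_truth$koff
      times <- seq(0, 5 / kobs, length.out = n_trace_points)
      f <- sprintf("trace_%s_%duM.csv", vid, conc)
      write_trace(gen_trace(tr_truth, conc, times), file.path(dir, f))
      list(file = f, conc_uM = conc)
    })

    # displacement series, 5-60 uM competitor
    d_truth <- truth0; d_truth$seed <- next_seed()
    disp <- gen_displacement_series(d_truth, decay_scale = 10,
                                    initial_kobs = krow$koff_s + 2,
                                    displacer_concs = seq(5, 60, by = 5),
                                    kobs_noise_sd = 0.01 * krow$koff_s)
    vcfg$displacement <- sprintf("displacement_%s.csv", vid)
    write_kobs_series(disp, file.path(dir, vcfg$displacement))

    # NMR shift tables for the variants with published region shifts
    if (!is.na(hrow$free_scs_ppm)) {
      sq <- synthetic_dreb2a_sequence(vid)
      nres <- nchar(sq$sequence)
      resno <- seq_len(nres) + sq$first_residue - 1L
      make_prof <- function(region, scs) {
        f <- rep(0.02, nres)
        f[resno >= region[1] & resno <= region[2]] <- scs / 3.1
        helix_profile(sq$sequence, pmin(f, 1), first_residue = sq$first_residue)
      }
      rc <- random_coil_for_sequence(sq$sequence, sq$first_residue)
      vcfg$random_coil <- sprintf("random_coil_%s.csv", vid)
      write_random_coil(rc, file.path(dir, vcfg$random_coil))
      vcfg$shifts_free <- sprintf("shifts_free_%s.csv", vid)
      write_shift_table(gen_shift_table(make_prof(c(262, 266), hrow$free_scs_ppm), rc),
                        file.path(dir, vcfg$shifts_free))
      vcfg$shifts_bound <- sprintf("shifts_bound_%s.csv", vid)
      write_shift_table(gen_shift_table(make_prof(c(261, 267), hrow$bound_scs_ppm), rc),
                        file.path(dir, vcfg$shifts_bound))
    }

    # CD / TFE titration
    f0 <- hrow$cd_percent / 100
    vcfg$cd <- lapply(seq(0, 70, by = 10), function(tfe) {
      fname <- sprintf("cd_%s_tfe%02d.csv", vid, tfe)
      sp <- gen_cd_spectrum(f0 + (0.9 - f0) * tfe / 100, noise_sd = 100,
                            seed = next_seed(), tfe_percent = tfe, peptide_id = vid)
      write_spectrum(sp, file.path(dir, fname))
      list(file = fname, tfe_percent = tfe)
    })

    # ITC for the variants measured calorimetrically
    irow <- itc[itc$variant_id == vid, ]
    if (nrow(irow) == 1) {
      tr <- itc_ground_truth(irow$kd_nM, irow$dh_kJmol, irow$n,
                             heat_noise_sd = 0.05, seed = next_seed())
      ex <- gen_itc_isotherm(tr)
      vcfg$itc <- list(file = sprintf("itc_%s.csv", vid),
                       cell_conc_uM = tr$cell_conc, syringe_conc_uM = tr$syringe_conc,
                       cell_volume_uL = tr$cell_volume, temperature_C = 25)
      write_isotherm(ex, file.path(dir, vcfg$itc$file))
    }

    cfg$variants[[vid]] <- vcfg
  }

  # WT ionic-strength series from the basal-rate model:
  # ln k = ln(basal) + beta * I^(-1/2), anchored at the 100 mM rate
  nacl <- c(100, 150, 200, 300, 500, 800)
  basal_assoc <- 5; basal_dissoc <- 5
  wt <- kin[kin$variant_id == "WT", ]
  beta_on <- (log(wt$kon_uM_s) - log(basal_assoc)) * sqrt(0.1)
  beta_off <- (log(wt$koff_s) - log(basal_dissoc)) * sqrt(0.1)
  salt_files <- list(
    list(variant_id = "WT", rate_kind = "association",
         file = "salt_WT_association.csv",
         rate = exp(log(basal_assoc) + beta_on / sqrt(nacl / 1000))),
    list(variant_id = "WT", rate_kind = "dissociation",
         file = "salt_WT_dissociation.csv",
         rate = exp(log(basal_dissoc) + beta_off / sqrt(nacl / 1000))))
  cfg$salt <- lapply(salt_files, function(s) {
    write.csv(data.frame(nacl_mM = nacl, rate = s$rate),
              file.path(dir, s$file), row.names = FALSE, quote = FALSE)
    s[c("variant_id", "rate_kind", "file")]
  })

  yaml::write_yaml(cfg, file.path(dir, "study.yaml"))
  invisible(read_study_config(file.path(dir, "study.yaml")))
}
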