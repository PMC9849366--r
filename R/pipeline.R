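#' Per-variant study record
#'
#' One row of the cross-technique join: kinetics, free/bound NMR helicity,
#' CD helicity, thermodynamics. Missing stages are NA.
#'
#' @param variant_id unique label.
#' @param kinetics optional [binding_kinetics()].
#' @param free_helicity_percent,bound_helicity_percent NMR-derived percent
#'   helix of the free / bound state.
#' @param cd_helicity_percent CD-derived percent helix (0% TFE).
#' @param thermo optional [thermo_params()].
#' @return one-row data frame of class `variant_record`.
#' @export
variant_record <- function(variant_id, kinetics = NULL,
                           free_helicity_percent = NA_real_,
                           bound_helicity_percent = NA_real_,
                           cd_helicity_percent = NA_real_, thermo = NULL) {
  df <- data.frame(variant_id = variant_id,
                   kon = kinetics$kon %||% NA_real_,
                   kon_se = kinetics$kon_se %||% NA_real_,
                   koff = kinetics$koff %||% NA_real_,
                   koff_se = kinetics$koff_se %||% NA_real_,
                   kd_nM = kinetics$kd_nM %||% NA_real_,
                   kd_se = kinetics$kd_se %||% NA_real_,
                   free_helicity_percent = free_helicity_percent,
                   bound_helicity_percent = bound_helicity_percent,
                   cd_helicity_percent = cd_helicity_percent,
                   itc_kd_nM = thermo$kd %||% NA_real_,
                   itc_n = thermo$n %||% NA_real_,
                   itc_dh = thermo$dh %||% NA_real_,
                   itc_dg = thermo$dg %||% NA_real_,
                   itc_minus_tds = thermo$minus_tds %||% NA_real_,
                   stringsAsFactors = FALSE)
  class(df) <- c("variant_record", class(df))
  df
}

#' Read a study configuration
#'
#' YAML manifest listing per-variant data files (traces, displacement
#' series, shift tables, CD spectra, ITC isotherms), region definitions,
#' the full-helix reference SCS, temperatures and the seed. Relative file
#' paths resolve against the config file's directory.
#'
#' @param path path to a YAML study config.
#' @return object of class `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$base_dir <- dirname(normalizePath(path))
  structure(cfg, class = "study_config")
}

cfg_path <- function(config, f) {
  if (is.null(f)) return(NULL)
  if (file.exists(f)) f else file.path(config$base_dir %||% ".", f)
}

#' Run the full per-variant study
#'
#' Orchestrates kinetics (trace fitting, association slope, displacement
#' asymptote, Kd), structure (SCS region helicity, CD/TFE helicity, NMR-CD
#' calibration) and thermodynamics (one-site ITC) for every variant in the
#' config, then the cross-variant analyses: the LFER, the helicity-koff
#' correlation (both axis conventions), the free-vs-bound helicity
#' correlation and, when salt series are listed, basal-rate extrapolations.
#' Stages with missing data are skipped with a logged warning, never
#' silently. The run is deterministic: re-running an identical config
#' produces identical report tables (timestamps are confined to the log).
#'
#' @param config a `study_config` (from [read_study_config()]) or an
#'   equivalent list.
#' @param output_dir optional directory; when given, report CSVs and the run
#'   log are written there.
#' @return object of class `study_report`: list with `records` (joined
#'   variant table), `kinetics_table`, `structure_table`, `thermo_table`,
#'   `salt_table`, `calibration`, `lfer`, `correlations`, `log`.
#' @export
run_study <- function(config, output_dir = NULL) {
  stopifnot(is.list(config))
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), line))
    invisible(NULL)
  }
  note("helixbind %s study run; seed %s",
       as.character(utils::packageVersion("helixbind")), config$seed %||% "none")
  ref_scs <- config$reference_scs %||% 3.1
  region_free <- unlist(config$regions$free %||% c(262, 266))
  region_bound <- unlist(config$regions$bound %||% c(261, 267))
  temperature_K <- config$temperature_K %||% 298.15

  records <- list()
  for (vid in names(config$variants)) {
    v <- config$variants[[vid]]
    kin <- NULL; free_pct <- NA_real_; bound_pct <- NA_real_
    cd_pct <- NA_real_; thermo <- NULL

    # --- kinetics ---------------------------------------------------------
    if (!is.null(v$traces) && !is.null(v$displacement)) {
      concs <- vapply(v$traces, function(tr) tr$conc_uM, numeric(1))
      kobs <- vapply(v$traces, function(tr) {
        trace <- read_trace(cfg_path(config, tr$file), partner_conc = tr$conc_uM,
                            labeled_conc = tr$labeled_conc_uM %||% (tr$conc_uM / 10))
        fit <- fit_single_exponential(trace)
        note("%s: trace %s (conc %g uM) kobs = %.6g +/- %.2g s^-1",
             vid, tr$file, tr$conc_uM, fit$kobs, fit$kobs_se)
        fit$kobs
      }, numeric(1))
      assoc <- fit_association(pfo_series(concs, kobs, variant_id = vid))
      note("%s: association slope kon = %.6g +/- %.2g uM^-1 s^-1 (intercept %.4g)",
           vid, assoc$kon, assoc$kon_se, assoc$intercept)
      disp_df <- read_kobs_series(cfg_path(config, v$displacement))
      disp <- fit_displacement(displacement_series(disp_df$conc_uM, disp_df$kobs_s,
                                                   variant_id = vid))
      note("%s: displacement asymptote koff = %.6g +/- %.2g s^-1",
           vid, disp$koff, disp$koff_se)
      kin <- binding_kinetics(vid, assoc$kon, assoc$kon_se, disp$koff, disp$koff_se)
      note("%s: Kd = %.6g +/- %.2g nM", vid, kin$kd_nM, kin$kd_se)
    } else {
      note("%s: kinetics data missing; stage skipped", vid)
    }

    # --- structure: NMR ---------------------------------------------------
    if (!is.null(v$shifts_free) && !is.null(v$random_coil)) {
      rc <- read_random_coil(cfg_path(config, v$random_coil))
      prof <- compute_scs(read_shift_table(cfg_path(config, v$shifts_free)), rc)
      rh <- region_helicity(prof, region_free, reference = ref_scs)
      free_pct <- rh$percent_helix
      note("%s: free-state mean SCS %.4g ppm over %d-%d -> %.4g%% helix",
           vid, rh$mean_scs_ppm, region_free[1], region_free[2], free_pct)
      if (!is.null(v$shifts_bound)) {
        prof_b <- compute_scs(read_shift_table(cfg_path(config, v$shifts_bound)), rc)
        rhb <- region_helicity(prof_b, region_bound, reference = ref_scs)
        bound_pct <- rhb$percent_helix
        note("%s: bound-state mean SCS %.4g ppm over %d-%d -> %.4g%% helix",
             vid, rhb$mean_scs_ppm, region_bound[1], region_bound[2], bound_pct)
      }
    } else {
      note("%s: NMR shift data missing; stage skipped", vid)
    }

    # --- structure: CD ----------------------------------------------------
    if (!is.null(v$cd)) {
      spectra <- lapply(v$cd, function(s)
        read_spectrum(cfg_path(config, s$file), tfe_percent = s$tfe_percent %||% 0,
                      peptide_id = vid))
      if (length(spectra) >= 2) {
        tt <- tfe_titration_summary(spectra)
        cd_pct <- tt$percent_helix[tt$tfe_percent == min(tt$tfe_percent)]
        note("%s: CD/TFE titration over %d points; %.4g%% helix at %g%% TFE",
             vid, nrow(tt), cd_pct, min(tt$tfe_percent))
      } else {
        cd_pct <- helicity_from_mre(spectra[[1]])
        note("%s: CD helicity %.4g%% (single spectrum)", vid, cd_pct)
      }
    } else {
      note("%s: CD data missing; stage skipped", vid)
    }

    # --- thermodynamics ---------------------------------------------------
    if (!is.null(v$itc)) {
      ex <- read_isotherm(cfg_path(config, v$itc$file),
                          cell_conc = v$itc$cell_conc_uM,
                          syringe_conc = v$itc$syringe_conc_uM,
                          cell_volume = v$itc$cell_volume_uL,
                          temperature = v$itc$temperature_C %||% 25)
      thermo <- fit_one_site(ex)
      thermo$variant_id <- vid
      note("%s: ITC Kd %.5g +/- %.2g nM, N %.3g, dH %.4g kJ/mol, dG %.4g, -TdS %.4g",
           vid, thermo$kd, thermo$kd_se, thermo$n, thermo$dh, thermo$dg,
           thermo$minus_tds)
    } else {
      note("%s: ITC data missing; stage skipped", vid)
    }

    records[[vid]] <- variant_record(vid, kinetics = kin,
                                     free_helicity_percent = free_pct,
                                     bound_helicity_percent = bound_pct,
                                     cd_helicity_percent = cd_pct,
                                     thermo = thermo)
  }
  records <- do.call(rbind, c(records, make.row.names = FALSE))

  # --- NMR-CD calibration -------------------------------------------------
  calibration <- NULL
  both <- !is.na(records$free_helicity_percent) & !is.na(records$cd_helicity_percent)
  if (sum(both) >= 3) {
    calibration <- fit_calibration(records$free_helicity_percent[both],
                                   records$cd_helicity_percent[both])
    records$nmr_scale_percent <- ifelse(
      is.na(records$cd_helicity_percent), NA_real_,
      apply_calibration(calibration, records$cd_helicity_percent))
    note("calibration: Y = %.4gx %+.4g (R^2 %.4f) on %d variants",
         calibration$slope, calibration$intercept, calibration$r_squared, sum(both))
  } else {
    records$nmr_scale_percent <- NA_real_
    note("calibration skipped: fewer than 3 variants with both NMR and CD helicity")
  }

  # --- salt series --------------------------------------------------------
  salt_table <- NULL
  if (!is.null(config$salt)) {
    salt_table <- do.call(rbind, lapply(config$salt, function(s) {
      df <- read.csv(cfg_path(config, s$file))
      bf <- fit_salt_dependence(salt_series(df$nacl_mM, df$rate, s$rate_kind,
                                            variant_id = s$variant_id))
      note("%s %s: basal rate %.4g +/- %.2g (slope %.3g, R^2 %.3f)",
           s$variant_id, s$rate_kind, bf$basal_rate, bf$basal_se,
           bf$slope_beta, bf$r_squared)
      data.frame(variant_id = s$variant_id, rate_kind = s$rate_kind,
                 basal_rate = bf$basal_rate, basal_se = bf$basal_se,
                 slope_beta = bf$slope_beta, r_squared = bf$r_squared)
    }))
  }

  # --- cross-variant analyses --------------------------------------------
  kin_ok <- complete.cases(records[, c("kon", "koff")])
  lfer <- if (sum(kin_ok) >= 3) {
    l <- lfer_regression(records[kin_ok, c("kon", "koff", "kd_nM")])
    note("LFER: slope(log kon) %.4f +/- %.4f, slope(log koff) %.4f +/- %.4f",
         l$slope_kon_vs_kd, l$slope_kon_se, l$slope_koff_vs_kd, l$slope_koff_se)
    l
  } else NULL
  correlations <- list()
  hk <- tryCatch(correlate_helicity_koff(records), error = function(e) NULL)
  if (!is.null(hk)) {
    correlations$helicity_koff <- hk
    note("helicity-koff: R^2 %.4f (log), %.4f (linear)",
         hk$r_squared_log, hk$r_squared_linear)
  }
  fb <- tryCatch(correlate_free_bound(records), error = function(e) NULL)
  if (!is.null(fb)) {
    correlations$free_bound <- fb
    note("free-bound helicity: R^2 %.4f (slope %.4g)", fb$r_squared, fb$slope)
  }

  report <- structure(
    list(records = records,
         kinetics_table = records[kin_ok, c("variant_id", "kon", "kon_se",
                                            "koff", "koff_se", "kd_nM", "kd_se")],
         structure_table = records[, c("variant_id", "free_helicity_percent",
                                       "bound_helicity_percent",
                                       "cd_helicity_percent", "nmr_scale_percent")],
         thermo_table = records[!is.na(records$itc_kd_nM),
                                c("variant_id", "itc_kd_nM", "itc_n", "itc_dh",
                                  "itc_minus_tds", "itc_dg")],
         salt_table = salt_table, calibration = calibration, lfer = lfer,
         correlations = correlations, log = log_lines),
    class = "study_report")

  if (!is.null(output_dir)) write_study_report(report, output_dir)
  report
}

write_study_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) if (!is.null(df) && nrow(df))
    write.csv(df, file.path(output_dir, f), row.names = FALSE, quote = FALSE)
  w(report$kinetics_table, "kinetics_report.csv")
  w(report$structure_table, "structure_report.csv")
  w(report$thermo_table, "thermo_report.csv")
  w(report$salt_table, "salt_report.csv")
  writeLines(report$log, file.path(output_dir, "run.log"))
  invisible(output_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", nrow(x$records), "variants\n")
  cat("kinetics:\n"); print(format_kinetics_table(x$kinetics_table))
  if (!is.null(x$lfer)) print(x$lfer)
  invisible(x)
}

# Table-1-style rendering: 2 significant figures for rates and Kd
format_kinetics_table <- function(tab) {
  data.frame(variant_id = tab$variant_id,
             kon = signif(tab$kon, 2), koff = signif(tab$koff, 2),
             kd_nM = signif(tab$kd_nM, 2))
}

#' Correlation between residual helicity and dissociation rate
#'
#' OLS of koff on free-state percent helix across variants, reported on
#' both axis conventions (koff linear and log10); the log scale linearises
#' the expected exponential dependence of complex lifetime on residual
#' structure.
#'
#' @param records data frame with columns `koff` and a helicity column
#'   (`nmr_scale_percent` preferred, else `free_helicity_percent`), e.g.
#'   the `records` table of a [run_study()] report.
#' @param helicity optional explicit helicity column name.
#' @return list with `r_squared_log`, `slope_log`, `intercept_log`,
#'   `r_squared_linear`, `slope_linear`, `intercept_linear`, `n`.
#' @export
correlate_helicity_koff <- function(records, helicity = NULL) {
  hcol <- helicity %||%
    (if (!is.null(records$nmr_scale_percent) &&
         sum(complete.cases(records[, c("koff", "nmr_scale_percent")])) >= 3)
       "nmr_scale_percent" else "free_helicity_percent")
  ok <- complete.cases(records[, c("koff", hcol)])
  stop_if(sum(ok) < 3, "need at least 3 records with both koff and helicity")
  h <- records[[hcol]][ok]; k <- records$koff[ok]
  mlin <- lm(y ~ x, data = data.frame(x = h, y = k))
  mlog <- lm(y ~ x, data = data.frame(x = h, y = log10(k)))
  list(helicity_column = hcol, n = sum(ok),
       r_squared_log = summary(mlog)$r.squared,
       slope_log = unname(coef(mlog)[2]), intercept_log = unname(coef(mlog)[1]),
       r_squared_linear = summary(mlin)$r.squared,
       slope_linear = unname(coef(mlin)[2]), intercept_linear = unname(coef(mlin)[1]))
}

#' Correlation between free- and bound-state helicity
#'
#' OLS of bound-state percent helix on free-state percent helix.
#'
#' @param records data frame with `free_helicity_percent` and
#'   `bound_helicity_percent` columns (>= 3 complete rows).
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
correlate_free_bound <- function(records) {
  ok <- complete.cases(records[, c("free_helicity_percent", "bound_helicity_percent")])
  stop_if(sum(ok) < 3, "need at least 3 records with both free and bound helicity")
  f <- records$free_helicity_percent[ok]; b <- records$bound_helicity_percent[ok]
  stop_if(sd(b) == 0, "bound helicity is constant: correlation undefined")
  m <- lm(y ~ x, data = data.frame(x = f, y = b))
  list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
       r_squared = summary(m)$r.squared, n = sum(ok))
}
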