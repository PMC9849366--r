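#' Construct a chemical-shift table
#'
#' Per-residue observed backbone shifts in full-protein numbering. Residues
#' that could not be assigned carry `assigned = FALSE` and are excluded from
#' region averages rather than imputed.
#'
#' @param residue_number integer residue numbers, unique and increasing.
#' @param residue_type one-letter amino-acid codes.
#' @param ca_ppm observed C-alpha shifts (ppm); NA where unassigned.
#' @param cb_ppm optional observed C-beta shifts (ppm).
#' @param assigned logical flag per residue; defaults to `!is.na(ca_ppm)`.
#' @return data frame of class `chemical_shift_table`.
#' @export
chemical_shift_table <- function(residue_number, residue_type, ca_ppm,
                                 cb_ppm = NULL, assigned = NULL) {
  residue_number <- as.integer(residue_number)
  stop_if(anyDuplicated(residue_number) > 0, "residue numbers must be unique")
  stop_if(is.unsorted(residue_number, strictly = TRUE), "residue numbers must be increasing")
  assigned <- assigned %||% !is.na(ca_ppm)
  stop_if(any(assigned & !is.finite(ca_ppm)), "assigned residues need finite ca_ppm")
  df <- data.frame(residue_number = residue_number,
                   residue_type = as.character(residue_type),
                   ca_ppm = as.numeric(ca_ppm),
                   cb_ppm = if (is.null(cb_ppm)) NA_real_ else as.numeric(cb_ppm),
                   assigned = assigned, stringsAsFactors = FALSE)
  class(df) <- c("chemical_shift_table", class(df))
  df
}

#' Construct a random-coil reference table
#'
#' @param residue_number integer residue numbers.
#' @param rc_ca_ppm random-coil C-alpha shifts (ppm).
#' @param rc_cb_ppm optional random-coil C-beta shifts (ppm).
#' @return data frame of class `random_coil_table`.
#' @export
random_coil_table <- function(residue_number, rc_ca_ppm, rc_cb_ppm = NULL) {
  df <- data.frame(residue_number = as.integer(residue_number),
                   rc_ca_ppm = as.numeric(rc_ca_ppm),
                   rc_cb_ppm = if (is.null(rc_cb_ppm)) NA_real_ else as.numeric(rc_cb_ppm))
  class(df) <- c("random_coil_table", class(df))
  df
}

#' Random-coil table for a specific sequence from the generic reference
#'
#' Expands the per-residue-type reference of [random_coil_reference()] into
#' a per-residue [random_coil_table()] for a given sequence.
#'
#' @param sequence one-letter amino-acid string.
#' @param first_residue residue number of the first position.
#' @param reference data frame with `residue_type`, `rc_ca_ppm`, `rc_cb_ppm`.
#' @return a [random_coil_table()].
#' @export
random_coil_for_sequence <- function(sequence, first_residue = 1L,
                                     reference = random_coil_reference()) {
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, reference$residue_type)
  stop_if(anyNA(idx), "residue type(s) not in random-coil reference: %s",
          paste(unique(aa[is.na(idx)]), collapse = ", "))
  random_coil_table(seq_along(aa) + first_residue - 1L,
                    reference$rc_ca_ppm[idx], reference$rc_cb_ppm[idx])
}

#' Secondary chemical shifts
#'
#' Subtracts random-coil reference shifts from observed shifts:
#' `SCS(Ca) = d(Ca,obs) - d(Ca,rc)`. Consecutive positive C-alpha SCSs
#' indicate helix. When C-beta shifts are present on both sides the
#' `(dCa - dCa,rc) - (dCb - dCb,rc)` comparison metric is added.
#'
#' @param shifts a [chemical_shift_table()].
#' @param rc a [random_coil_table()] covering every assigned residue.
#' @return data frame of class `scs_profile` with columns `residue_number`,
#'   `scs_ca_ppm`, optional `scs_ca_minus_cb_ppm`, `assigned`.
#' @export
compute_scs <- function(shifts, rc) {
  stopifnot(inherits(shifts, "chemical_shift_table"))
  idx <- match(shifts$residue_number, rc$residue_number)
  missing <- shifts$assigned & is.na(idx)
  stop_if(any(missing), "no random-coil entry for residue(s): %s",
          paste(shifts$residue_number[missing], collapse = ", "))
  scs_ca <- shifts$ca_ppm - rc$rc_ca_ppm[idx]
  scs_cab <- rep(NA_real_, nrow(shifts))
  have_cb <- !is.na(shifts$cb_ppm) & !is.na(rc$rc_cb_ppm[idx])
  scs_cab[have_cb] <- scs_ca[have_cb] -
    (shifts$cb_ppm[have_cb] - rc$rc_cb_ppm[idx][have_cb])
  df <- data.frame(residue_number = shifts$residue_number,
                   scs_ca_ppm = ifelse(shifts$assigned, scs_ca, NA_real_),
                   scs_ca_minus_cb_ppm = ifelse(shifts$assigned, scs_cab, NA_real_),
                   assigned = shifts$assigned)
  class(df) <- c("scs_profile", class(df))
  df
}

#' Region-averaged percent helix from secondary shifts
#'
#' Averages the C-alpha SCS over the assigned residues of an inclusive
#' residue interval and converts to percent helix against a full-helix
#' reference SCS (default 3.1 ppm for 100% helix):
#' `percent = 100 * mean(SCS) / reference`. The stored value is unrounded
#' and unclipped; printing clips to \[0, 110\] (region means slightly above
#' the reference occur in highly helical complexes) and rounds to integer.
#'
#' @param profile an `scs_profile` from [compute_scs()].
#' @param region length-2 inclusive residue interval, e.g. `c(262, 266)`.
#' @param reference full-helix reference SCS (ppm).
#' @return object of class `region_helicity` with `region`, `mean_scs_ppm`,
#'   `percent_helix`, `n_residues`, `reference_scs_ppm`.
#' @export
region_helicity <- function(profile, region, reference = 3.1) {
  stopifnot(inherits(profile, "scs_profile"), length(region) == 2L)
  stop_if(!is_number(reference) || reference <= 0, "reference must be positive")
  sel <- profile$residue_number >= region[1] & profile$residue_number <= region[2] &
    profile$assigned & !is.na(profile$scs_ca_ppm)
  stop_if(!any(sel), "no assigned residues in region [%d, %d]", region[1], region[2])
  m <- mean(profile$scs_ca_ppm[sel])
  structure(list(region = as.integer(region), mean_scs_ppm = m,
                 percent_helix = 100 * m / reference,
                 n_residues = sum(sel), reference_scs_ppm = reference),
            class = "region_helicity")
}

#' @export
print.region_helicity <- function(x, ...) {
  pct <- round_half_away(min(max(x$percent_helix, 0), 110))
  cat(sprintf("<region_helicity> residues %d-%d: mean SCS %.2f ppm -> %d%% helix (%d residues)\n",
              x$region[1], x$region[2], x$mean_scs_ppm, pct, x$n_residues))
  invisible(x)
}

#' Mean residue ellipticity
#'
#' `MRE = theta * MRW / (10 * l * c)` with the raw ellipticity `theta` in
#' degrees, mean residue weight `MRW` in g/mol, path length `l` in cm and
#' concentration `c` in g/mL; the result is in deg cm^2 dmol^-1.
#'
#' @param raw_theta raw ellipticity (degrees); vectorised.
#' @param mrw mean residue weight (g/mol per residue).
#' @param path_cm cuvette path length (cm).
#' @param conc_g_per_ml peptide concentration (g/mL).
#' @return mean residue ellipticity (deg cm^2 dmol^-1).
#' @export
compute_mre <- function(raw_theta, mrw, path_cm, conc_g_per_ml) {
  stop_if(!is_number(mrw) || mrw <= 0, "mrw must be positive")
  stop_if(!is_number(path_cm) || path_cm <= 0, "path length must be positive")
  stop_if(!is_number(conc_g_per_ml) || conc_g_per_ml <= 0, "concentration must be positive")
  raw_theta * mrw / (10 * path_cm * conc_g_per_ml)
}

#' Construct a mean-residue-ellipticity spectrum
#'
#' @param wavelengths wavelengths (nm); must cover 222 nm (within 1 nm) for
#'   helicity computation.
#' @param mre mean residue ellipticity (deg cm^2 dmol^-1), same length.
#' @param tfe_percent TFE co-solvent concentration (% v/v).
#' @param peptide_id label.
#' @param true_helix_fraction optional generator ground truth.
#' @return object of class `mre_spectrum`.
#' @export
mre_spectrum <- function(wavelengths, mre, tfe_percent = 0,
                         peptide_id = NA_character_, true_helix_fraction = NULL) {
  stop_if(length(wavelengths) != length(mre), "lengths differ")
  structure(list(wavelengths = as.numeric(wavelengths), mre = as.numeric(mre),
                 tfe_percent = tfe_percent, peptide_id = peptide_id,
                 true_helix_fraction = true_helix_fraction),
            class = "mre_spectrum")
}

#' Percent helix from the 222 nm ellipticity
#'
#' Uses the two-point conversion anchored at MRE(222) = -3000 for 0% helix
#' and -42000 for 100% helix: `fraction = -(MRE_222 + 3000) / 39000`
#' (helical signals are negative at 222 nm, so the printed two-point form
#' is evaluated with this sign convention). The fraction is clipped to
#' \[0, 1\] and returned as percent.
#'
#' @param spectrum an [mre_spectrum()], or a single MRE value at 222 nm.
#' @return percent helix in \[0, 100\].
#' @export
helicity_from_mre <- function(spectrum) {
  if (inherits(spectrum, "mre_spectrum")) {
    d <- abs(spectrum$wavelengths - 222)
    stop_if(min(d) > 1, "spectrum does not cover 222 nm (nearest point %.1f nm away)", min(d))
    m222 <- spectrum$mre[which.min(d)]
  } else {
    stop_if(!is_number(spectrum), "expected an mre_spectrum or a single MRE value")
    m222 <- spectrum
  }
  frac <- -(m222 + 3000) / 39000
  100 * min(max(frac, 0), 1)
}

#' Helicity across a TFE titration
#'
#' Applies [helicity_from_mre()] to each spectrum of one peptide and
#' returns the (TFE, percent helix) table ordered by TFE.
#'
#' @param spectra list of [mre_spectrum()] objects for a single peptide with
#'   distinct `tfe_percent` values (>= 2 points).
#' @return data frame with columns `tfe_percent`, `percent_helix`.
#' @export
tfe_titration_summary <- function(spectra) {
  stop_if(length(spectra) < 2L, "a titration needs at least 2 TFE points")
  tfe <- vapply(spectra, function(s) s$tfe_percent, numeric(1))
  stop_if(anyDuplicated(tfe) > 0, "duplicate TFE values in titration")
  out <- data.frame(tfe_percent = tfe,
                    percent_helix = vapply(spectra, helicity_from_mre, numeric(1)))
  out[order(out$tfe_percent), , drop = FALSE]
}

#' Calibration line between CD- and NMR-derived helicity scales
#'
#' OLS of NMR-derived percent helix (response) on CD-derived percent helix
#' (predictor). The fitted line transfers whole-peptide CD helicities onto
#' the NMR (region SCS) scale for variants lacking NMR data.
#'
#' @param nmr_percent NMR-derived percent helix (response), length >= 3.
#' @param cd_percent CD-derived percent helix (predictor), same length.
#' @return object of class `calibration_line` with `slope`, `intercept`,
#'   `r_squared`.
#' @export
fit_calibration <- function(nmr_percent, cd_percent) {
  stop_if(length(nmr_percent) != length(cd_percent), "lengths differ")
  stop_if(length(nmr_percent) < 3L, "calibration needs at least 3 points")
  m <- lm(y ~ x, data = data.frame(x = cd_percent, y = nmr_percent))
  calibration_line(unname(coef(m)[2]), unname(coef(m)[1]), summary(m)$r.squared)
}

#' @rdname fit_calibration
#' @param slope,intercept,r_squared line coefficients (for constructing a
#'   known calibration, e.g. slope 1.538, intercept -14.93).
#' @export
calibration_line <- function(slope, intercept, r_squared = NA_real_) {
  stop_if(!is_number(slope) || !is_number(intercept), "coefficients must be finite")
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared),
            class = "calibration_line")
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf("<calibration_line> Y = %.4gx %+.4g (R^2 %s)\n",
              x$slope, x$intercept,
              if (is.na(x$r_squared)) "?" else sprintf("%.3f", x$r_squared)))
  invisible(x)
}

#' Apply a helicity calibration line
#'
#' Evaluates `slope * x + intercept`; negative results are floored at zero
#' and carry a `floored` attribute.
#'
#' @param line a [calibration_line()].
#' @param cd_percent CD-derived percent helix value(s).
#' @return NMR-scale percent helix (unrounded).
#' @export
apply_calibration <- function(line, cd_percent) {
  stopifnot(inherits(line, "calibration_line"))
  stop_if(any(!is.finite(cd_percent)), "input must be finite")
  y <- line$slope * cd_percent + line$intercept
  floored <- y < 0
  y[floored] <- 0
  if (any(floored)) attr(y, "floored") <- floored
  y
}
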