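# Delimited-text readers and writers for every exchange format the pipeline
# uses: comma-separated, header row, '.' decimal.

#' Write / read a fluorescence trace
#'
#' Two-column CSV `time_s, signal`; mixing metadata travels in the study
#' manifest, not the file.
#'
#' @param trace a [fluorescence_trace()].
#' @param path file path.
#' @return `read_trace()` returns a [fluorescence_trace()].
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(time_s = trace$times, signal = trace$signal),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param partner_conc,labeled_conc mixing concentrations (uM) from the
#'   manifest.
#' @export
read_trace <- function(path, partner_conc = NA_real_, labeled_conc = NA_real_) {
  df <- read.csv(path)
  stop_if(!all(c("time_s", "signal") %in% names(df)),
          "trace file %s needs columns time_s, signal", path)
  fluorescence_trace(df$time_s, df$signal, partner_conc = partner_conc,
                     labeled_conc = labeled_conc)
}

#' Write / read a kobs-vs-concentration series
#'
#' Two-column CSV `conc_uM, kobs_s`, used for both association and
#' displacement series.
#'
#' @param series a [pfo_series()] or [displacement_series()].
#' @param path file path.
#' @return `read_kobs_series()` returns a data frame with `conc_uM`,
#'   `kobs_s`.
#' @export
write_kobs_series <- function(series, path) {
  conc <- if (inherits(series, "displacement_series")) series$displacer_concs
          else series$concs
  write.csv(data.frame(conc_uM = conc, kobs_s = series$kobs_values),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kobs_series
#' @export
read_kobs_series <- function(path) {
  df <- read.csv(path)
  stop_if(!all(c("conc_uM", "kobs_s") %in% names(df)),
          "series file %s needs columns conc_uM, kobs_s", path)
  df
}

#' Write / read an ITC isotherm
#'
#' Three-column CSV `injection_idx, volume_uL, heat_ucal`; the geometry
#' (cell/syringe concentrations, cell volume, temperature) travels in the
#' manifest.
#'
#' @param experiment an [itc_experiment()].
#' @param path file path.
#' @param cell_conc,syringe_conc,cell_volume,temperature geometry for
#'   `read_isotherm()`.
#' @return `read_isotherm()` returns an [itc_experiment()].
#' @export
write_isotherm <- function(experiment, path) {
  write.csv(data.frame(injection_idx = seq_along(experiment$heats),
                       volume_uL = experiment$injection_volumes,
                       heat_ucal = experiment$heats),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_isotherm
#' @export
read_isotherm <- function(path, cell_conc, syringe_conc, cell_volume,
                          temperature = 25) {
  df <- read.csv(path)
  stop_if(!all(c("injection_idx", "volume_uL", "heat_ucal") %in% names(df)),
          "isotherm file %s needs columns injection_idx, volume_uL, heat_ucal", path)
  df <- df[order(df$injection_idx), ]
  itc_experiment(df$volume_uL, df$heat_ucal, cell_volume, cell_conc,
                 syringe_conc, temperature = temperature)
}

#' Write / read a CD spectrum
#'
#' Two-column CSV `wavelength_nm, mre`; TFE percent and peptide id travel in
#' the manifest.
#'
#' @param spectrum an [mre_spectrum()].
#' @param path file path.
#' @param tfe_percent,peptide_id metadata for `read_spectrum()`.
#' @return `read_spectrum()` returns an [mre_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  write.csv(data.frame(wavelength_nm = spectrum$wavelengths, mre = spectrum$mre),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, tfe_percent = 0, peptide_id = NA_character_) {
  df <- read.csv(path)
  stop_if(!all(c("wavelength_nm", "mre") %in% names(df)),
          "spectrum file %s needs columns wavelength_nm, mre", path)
  mre_spectrum(df$wavelength_nm, df$mre, tfe_percent = tfe_percent,
               peptide_id = peptide_id)
}

#' Write / read a chemical-shift table
#'
#' CSV `residue_number, residue_type, ca_ppm, cb_ppm` (empty `cb_ppm`
#' allowed; unassigned residues have empty `ca_ppm`).
#'
#' @param shifts a [chemical_shift_table()].
#' @param path file path.
#' @return `read_shift_table()` returns a [chemical_shift_table()].
#' @export
write_shift_table <- function(shifts, path) {
  write.csv(shifts[, c("residue_number", "residue_type", "ca_ppm", "cb_ppm")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shift_table
#' @export
read_shift_table <- function(path) {
  df <- read.csv(path)
  stop_if(!all(c("residue_number", "residue_type", "ca_ppm") %in% names(df)),
          "shift table %s needs columns residue_number, residue_type, ca_ppm", path)
  chemical_shift_table(df$residue_number, df$residue_type, df$ca_ppm,
                       cb_ppm = if ("cb_ppm" %in% names(df)) df$cb_ppm else NULL)
}

#' Read a per-residue random-coil table
#'
#' CSV `residue_number, rc_ca_ppm, rc_cb_ppm`.
#'
#' @param path file path.
#' @return a [random_coil_table()].
#' @export
read_random_coil <- function(path) {
  df <- read.csv(path)
  stop_if(!all(c("residue_number", "rc_ca_ppm") %in% names(df)),
          "random-coil table %s needs columns residue_number, rc_ca_ppm", path)
  random_coil_table(df$residue_number, df$rc_ca_ppm,
                    rc_cb_ppm = if ("rc_cb_ppm" %in% names(df)) df$rc_cb_ppm else NULL)
}

#' Write a random-coil table
#'
#' @param rc a [random_coil_table()].
#' @param path file path.
#' @export
#' @rdname read_random_coil
write_random_coil <- function(rc, path) {
  write.csv(as.data.frame(rc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
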