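#' Ground truth for synthetic stopped-flow data
#'
#' @param kon association rate constant (uM^-1 s^-1), positive.
#' @param koff dissociation rate constant (s^-1), non-negative.
#' @param fluorescence_amplitude signal change on binding (a.u.).
#' @param baseline signal offset (a.u.).
#' @param noise_sd Gaussian noise SD on the signal (a.u.), non-negative.
#' @param seed integer random seed; identical seed and parameters give
#'   bit-identical output.
#' @return object of class `kinetic_ground_truth`.
#' @export
kinetic_ground_truth <- function(kon, koff, fluorescence_amplitude = 1,
                                 baseline = 0, noise_sd = 0, seed = 1L) {
  stop_if(!is_number(kon) || kon <= 0, "kon must be positive")
  stop_if(!is_number(koff) || koff < 0, "koff must be non-negative")
  stop_if(!is_number(noise_sd) || noise_sd < 0, "noise_sd must be non-negative")
  structure(list(kon = kon, koff = koff,
                 fluorescence_amplitude = fluorescence_amplitude,
                 baseline = baseline, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "kinetic_ground_truth")
}

#' Synthesise a pseudo-first-order stopped-flow trace
#'
#' `signal(t) = baseline + amplitude * exp(-(kon*conc + koff) * t) + noise`,
#' the single-exponential relaxation expected when the unlabeled partner is
#' in large excess. The true kobs is stored on the trace.
#'
#' @param truth a [kinetic_ground_truth()].
#' @param partner_conc partner concentration (uM).
#' @param times strictly increasing time points (s).
#' @param labeled_conc labeled species concentration (uM); defaults to a
#'   tenth of `partner_conc` (the pseudo-first-order boundary).
#' @return a [fluorescence_trace()] with `true_kobs` metadata.
#' @export
gen_trace <- function(truth, partner_conc, times, labeled_conc = partner_conc / 10) {
  stopifnot(inherits(truth, "kinetic_ground_truth"))
  stop_if(any(diff(times) <= 0), "times must be strictly increasing")
  kobs <- truth$kon * partner_conc + truth$koff
  y <- truth$baseline + truth$fluorescence_amplitude * exp(-kobs * times)
  if (truth$noise_sd > 0)
    y <- y + withr::with_seed(truth$seed, rnorm(length(times), 0, truth$noise_sd))
  fluorescence_trace(times, y, partner_conc = partner_conc,
                     labeled_conc = labeled_conc, true_kobs = kobs)
}

#' Synthesise an association kobs series
#'
#' `kobs_i = kon * conc_i + koff` plus optional Gaussian noise on each kobs.
#'
#' @param truth a [kinetic_ground_truth()].
#' @param concs partner concentrations (uM), >= 2 distinct values.
#' @param kobs_noise_sd Gaussian noise SD on each kobs (s^-1).
#' @return a [pfo_series()] carrying the true slope/intercept.
#' @export
gen_association_series <- function(truth, concs, kobs_noise_sd = 0) {
  stopifnot(inherits(truth, "kinetic_ground_truth"))
  stop_if(length(unique(concs)) < 2L, "need at least 2 distinct concentrations")
  k <- truth$kon * concs + truth$koff
  if (kobs_noise_sd > 0)
    k <- k + withr::with_seed(truth$seed, rnorm(length(concs), 0, kobs_noise_sd))
  pfo_series(concs, k, true_kon = truth$kon, true_koff = truth$koff)
}

#' Synthesise a displacement kobs series
#'
#' `kobs(d) = koff + (initial_kobs - koff) * exp(-d / decay_scale)` plus
#' optional noise. The asymptote (the quantity of interest) is the ground
#' truth koff; the exponential decay shape is a modelling convenience, as
#' the asymptote estimate is robust to the exact decay form.
#'
#' @param truth a [kinetic_ground_truth()] (supplies koff and the seed).
#' @param decay_scale concentration scale of the decay (uM), positive.
#' @param initial_kobs kobs at zero displacer (s^-1).
#' @param displacer_concs positive, increasing competitor concentrations (uM).
#' @param kobs_noise_sd Gaussian noise SD on each kobs (s^-1).
#' @return a [displacement_series()] carrying the true koff.
#' @export
gen_displacement_series <- function(truth, decay_scale, initial_kobs,
                                    displacer_concs, kobs_noise_sd = 0) {
  stopifnot(inherits(truth, "kinetic_ground_truth"))
  stop_if(!is_number(decay_scale) || decay_scale <= 0, "decay_scale must be positive")
  k <- truth$koff + (initial_kobs - truth$koff) * exp(-displacer_concs / decay_scale)
  if (kobs_noise_sd > 0)
    k <- k + withr::with_seed(truth$seed, rnorm(length(displacer_concs), 0, kobs_noise_sd))
  displacement_series(displacer_concs, k, true_koff = truth$koff)
}

#' Ground truth for a synthetic ITC experiment
#'
#' @param kd dissociation constant (nM), positive.
#' @param dh binding enthalpy (kJ/mol).
#' @param n stoichiometry, positive.
#' @param cell_conc cell species concentration (uM), positive.
#' @param syringe_conc syringe species concentration (uM), positive.
#' @param cell_volume active cell volume (uL), positive.
#' @param injection_volumes ordered injection volumes (uL), positive;
#'   default is the study schedule of one 0.5 uL injection followed by
#'   seventeen 2 uL injections.
#' @param heat_noise_sd per-injection Gaussian heat noise (ucal).
#' @param seed integer random seed.
#' @return object of class `itc_ground_truth`.
#' @export
itc_ground_truth <- function(kd, dh, n, cell_conc = 10, syringe_conc = 96,
                             cell_volume = 200,
                             injection_volumes = c(0.5, rep(2, 17)),
                             heat_noise_sd = 0, seed = 1L) {
  stop_if(!is_number(kd) || kd <= 0, "kd must be positive")
  stop_if(!is_number(n) || n <= 0, "n must be positive")
  stop_if(any(injection_volumes <= 0), "injection volumes must be positive")
  stop_if(cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0,
          "concentrations and cell volume must be positive")
  structure(list(kd = kd, dh = dh, n = n, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, cell_volume = cell_volume,
                 injection_volumes = as.numeric(injection_volumes),
                 heat_noise_sd = heat_noise_sd, seed = as.integer(seed)),
            class = "itc_ground_truth")
}

#' Synthesise a one-site ITC isotherm
#'
#' Per-injection heats from [one_site_heats()] plus Gaussian heat noise.
#' Warns when the injection schedule cannot titrate past saturation
#' (final molar ratio below `n`).
#'
#' @param truth an [itc_ground_truth()].
#' @return an [itc_experiment()] with the ground truth attached.
#' @export
gen_itc_isotherm <- function(truth) {
  stopifnot(inherits(truth, "itc_ground_truth"))
  h <- one_site_heats(truth$kd, truth$dh, truth$n, truth$cell_conc,
                      truth$syringe_conc, truth$cell_volume,
                      truth$injection_volumes)
  cc <- itc_concentrations(truth$cell_conc, truth$syringe_conc,
                           truth$cell_volume, truth$injection_volumes)
  final_ratio <- cc$Xt[length(cc$Xt)] / cc$Mt[length(cc$Mt)]
  if (final_ratio < truth$n)
    warning(sprintf("incomplete saturation: final molar ratio %.2f < n = %.2f",
                    final_ratio, truth$n))
  h <- as.numeric(h)
  if (truth$heat_noise_sd > 0)
    h <- h + withr::with_seed(truth$seed, rnorm(length(h), 0, truth$heat_noise_sd))
  itc_experiment(truth$injection_volumes, h, truth$cell_volume,
                 truth$cell_conc, truth$syringe_conc,
                 truth = truth[c("kd", "dh", "n")])
}

# two-component CD basis spectra, pinned exactly to the 222 nm anchors
# (helix: -42000; coil: -3000) by a constant offset of plausible band shapes
cd_helix_basis <- function(wl) {
  raw <- function(l) -36000 * exp(-(l - 222)^2 / (2 * 7^2)) -
    34000 * exp(-(l - 208)^2 / (2 * 7^2)) +
    65000 * exp(-(l - 192)^2 / (2 * 5^2))
  raw(wl) + (-42000 - raw(222))
}

cd_coil_basis <- function(wl) {
  raw <- function(l) -38000 * exp(-(l - 198)^2 / (2 * 8^2)) +
    1500 * exp(-(l - 218)^2 / (2 * 10^2))
  raw(wl) + (-3000 - raw(222))
}

#' Synthesise a CD spectrum for a given helix fraction
#'
#' Linear combination of a helix and a coil basis spectrum pinned so that
#' `MRE(222) = -(39000 * helix_fraction) - 3000`, i.e. exactly invertible by
#' [helicity_from_mre()]. The bases are smooth synthetic band shapes (helix:
#' double minimum near 208/222 nm and a positive band near 192 nm; coil:
#' minimum near 198 nm); full spectral realism is not attempted.
#'
#' @param helix_fraction helix fraction in \[0, 1\].
#' @param wavelengths wavelengths (nm), must cover 222 nm.
#' @param noise_sd Gaussian noise SD (MRE units).
#' @param seed integer random seed.
#' @param tfe_percent TFE concentration metadata (% v/v).
#' @param peptide_id label.
#' @return an [mre_spectrum()] with `true_helix_fraction` stored.
#' @export
gen_cd_spectrum <- function(helix_fraction, wavelengths = seq(190, 260, by = 0.5),
                            noise_sd = 0, seed = 1L, tfe_percent = 0,
                            peptide_id = "synthetic") {
  stop_if(!is_number(helix_fraction) || helix_fraction < 0 || helix_fraction > 1,
          "helix_fraction must be in [0, 1]")
  stop_if(min(abs(wavelengths - 222)) > 1, "wavelengths must cover 222 nm")
  mre <- helix_fraction * cd_helix_basis(wavelengths) +
    (1 - helix_fraction) * cd_coil_basis(wavelengths)
  if (noise_sd > 0)
    mre <- mre + withr::with_seed(seed, rnorm(length(wavelengths), 0, noise_sd))
  mre_spectrum(wavelengths, mre, tfe_percent = tfe_percent,
               peptide_id = peptide_id, true_helix_fraction = helix_fraction)
}

#' Per-residue helix-fraction profile
#'
#' @param sequence one-letter amino-acid string.
#' @param per_residue_helix_fraction helix fractions in \[0, 1\], one per
#'   residue.
#' @param first_residue residue number of the first position.
#' @return object of class `helix_profile`.
#' @export
helix_profile <- function(sequence, per_residue_helix_fraction, first_residue = 1L) {
  aa <- strsplit(sequence, "")[[1]]
  stop_if(length(aa) != length(per_residue_helix_fraction),
          "sequence and fraction lengths differ")
  f <- as.numeric(per_residue_helix_fraction)
  stop_if(any(f < 0 | f > 1), "helix fractions must lie in [0, 1]")
  structure(list(sequence = sequence, residue_type = aa,
                 residue_number = seq_along(aa) + as.integer(first_residue) - 1L,
                 fraction = f),
            class = "helix_profile")
}

#' Synthesise a chemical-shift table from a helix profile
#'
#' Observed C-alpha shift = random-coil C-alpha + fraction * full-helix SCS
#' (+ noise); C-beta shifts stay at their random-coil values (+ noise), as
#' helix formation barely moves C-beta.
#'
#' @param profile a [helix_profile()].
#' @param random_coil a [random_coil_table()] covering every residue of the
#'   profile; defaults to the generic reference expanded over the profile's
#'   sequence.
#' @param full_helix_scs SCS of a 100% helical residue (ppm), default 3.1.
#' @param noise_sd Gaussian noise SD on shifts (ppm).
#' @param seed integer random seed.
#' @return a [chemical_shift_table()].
#' @export
gen_shift_table <- function(profile, random_coil = NULL, full_helix_scs = 3.1,
                            noise_sd = 0, seed = 1L) {
  stopifnot(inherits(profile, "helix_profile"))
  rc <- random_coil %||% random_coil_for_sequence(profile$sequence,
                                                  profile$residue_number[1])
  idx <- match(profile$residue_number, rc$residue_number)
  stop_if(anyNA(idx), "no random-coil entry for residue(s): %s",
          paste(profile$residue_number[is.na(idx)], collapse = ", "))
  ca <- rc$rc_ca_ppm[idx] + profile$fraction * full_helix_scs
  cb <- rc$rc_cb_ppm[idx]
  if (noise_sd > 0) {
    eps <- withr::with_seed(seed, rnorm(2 * length(ca), 0, noise_sd))
    ca <- ca + eps[seq_along(ca)]
    cb <- cb + eps[length(ca) + seq_along(cb)]
  }
  chemical_shift_table(profile$residue_number, profile$residue_type, ca, cb)
}
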