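#' Published reference tables for the RCD1-RST:DREB2A variant study
#'
#' Returns the printed per-variant summary tables for the DREB2A(244-272)
#' variant panel (WT, R266G, R266A, D267A, D267L) binding RCD1-RST(499-572),
#' shipped as plain-text CSVs with the package:
#'
#' * `kinetics` — `kon` (uM^-1 s^-1), `koff` (s^-1) and `Kd` (nM) with
#'   standard errors at 100 mM NaCl, 10 C.
#' * `salt_series` — `kon`/`koff` across 50-800 mM NaCl (long format).
#' * `basal_rates` — printed basal (electrostatics-free) rate constants.
#' * `thermo` — ITC `Kd`, `N`, `dH`, `-TdS`, `dG` at 300 mM NaCl, 25 C.
#' * `helicity` — region-averaged secondary-shift helicities (free state
#'   D262-R266, bound state V261-D267), CD helicities at 0% TFE, and the
#'   calibrated NMR-scale helicities.
#'
#' These serve as worked-example inputs and as fixed points for the
#' pipeline's arithmetic (Kd derivation, basal-rate extrapolation,
#' calibration transfer).
#'
#' @return named list of data frames.
#' @export
#' @examples
#' ref <- reference_tables()
#' ref$kinetics
reference_tables <- function() {
  rd <- function(f) read.csv(system.file("extdata", f, package = "helixbind"),
                             stringsAsFactors = FALSE)
  list(
    kinetics    = rd("dreb2a_kinetics.csv"),
    salt_series = rd("dreb2a_salt_series.csv"),
    basal_rates = rd("dreb2a_basal_rates.csv"),
    thermo      = rd("dreb2a_thermo.csv"),
    helicity    = rd("dreb2a_helicity.csv")
  )
}

#' Generic random-coil chemical-shift reference
#'
#' Per-residue-type random-coil C-alpha and C-beta shifts (ppm), a generic
#' literature-style lookup used as the default baseline for secondary
#' chemical shifts. Sequence-dependent neighbour corrections are not
#' applied; supply your own table via the `rc` argument of [compute_scs()]
#' (or a `random_coil` file in a study config) when corrected values are
#' available.
#'
#' @return data frame with columns `residue_type`, `rc_ca_ppm`, `rc_cb_ppm`.
#' @export
random_coil_reference <- function() {
  read.csv(system.file("extdata", "random_coil_shifts.csv", package = "helixbind"),
           stringsAsFactors = FALSE)
}

#' Synthetic stand-in sequence for the DREB2A(244-272) peptide
#'
#' A 29-residue sequence numbered 244-272 used by the demonstration study.
#' It preserves the motif positions discussed in the study (V261, D262,
#' L264, L265, R266, D267) but is otherwise an invented disordered-looking
#' sequence — it is a synthetic stand-in, not the native DREB2A sequence.
#'
#' @param variant one of `"WT"`, `"R266G"`, `"R266A"`, `"D267A"`, `"D267L"`;
#'   the corresponding substitution is applied at position 266 or 267.
#' @return named list with `sequence` (one-letter string) and
#'   `first_residue` (244).
#' @export
synthetic_dreb2a_sequence <- function(variant = "WT") {
  # positions 244..272; motif residues at 261..267 as named in the study
  base <- "SEGSESADSGAQEGKSEVDLLSQELSAGE"
  stopifnot(nchar(base) == 29L)
  s <- strsplit(base, "")[[1]]
  names(s) <- as.character(244:272)
  s["261"] <- "V"; s["262"] <- "D"; s["263"] <- "E"; s["264"] <- "L"
  s["265"] <- "L"; s["266"] <- "R"; s["267"] <- "D"
  sub <- switch(variant,
    WT = NULL,
    R266G = c("266" = "G"), R266A = c("266" = "A"),
    D267A = c("267" = "A"), D267L = c("267" = "L"),
    stop("unknown variant: ", variant))
  if (!is.null(sub)) s[names(sub)] <- sub
  list(sequence = paste(s, collapse = ""), first_residue = 244L)
}
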