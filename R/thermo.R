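#' Construct an ITC experiment
#'
#' Injection-level heats with the cell/syringe geometry needed by the
#' one-site model. The syringe holds the titrant and the cell the binding
#' partner (the model is symmetric in the two roles).
#'
#' @param injection_volumes ordered injection volumes (uL), positive.
#' @param heats per-injection heats (ucal), same length.
#' @param cell_volume active cell volume (uL).
#' @param cell_conc cell species concentration (uM).
#' @param syringe_conc syringe species concentration (uM).
#' @param temperature temperature (C).
#' @param first_injection_excluded whether fits should drop the first
#'   (small, diffusion-compromised) injection; default TRUE.
#' @param truth optional generator ground truth (list with kd, dh, n).
#' @return object of class `itc_experiment`.
#' @export
itc_experiment <- function(injection_volumes, heats, cell_volume, cell_conc,
                           syringe_conc, temperature = 25,
                           first_injection_excluded = TRUE, truth = NULL) {
  stop_if(length(injection_volumes) != length(heats), "volumes and heats lengths differ")
  stop_if(any(injection_volumes <= 0), "injection volumes must be positive")
  stop_if(cell_conc <= 0 || syringe_conc <= 0 || cell_volume <= 0,
          "concentrations and cell volume must be positive")
  structure(list(injection_volumes = as.numeric(injection_volumes),
                 heats = as.numeric(heats), cell_volume = cell_volume,
                 cell_conc = cell_conc, syringe_conc = syringe_conc,
                 temperature = temperature,
                 first_injection_excluded = first_injection_excluded,
                 truth = truth),
            class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf("<itc_experiment> %d injections, cell %g uM / %g uL, syringe %g uM, %g C\n",
              length(x$heats), x$cell_conc, x$cell_volume, x$syringe_conc,
              x$temperature))
  invisible(x)
}

# total concentrations in the active volume after injection i, under the
# displaced-volume (overfilled cell) convention used by instrument software
itc_concentrations <- function(cell_conc_uM, syringe_conc_uM, cell_volume_uL,
                               injection_volumes_uL) {
  V0 <- cell_volume_uL * 1e-6          # L
  dV <- cumsum(injection_volumes_uL) * 1e-6
  list(Mt = cell_conc_uM * 1e-6 * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0)),
       Xt = syringe_conc_uM * 1e-6 * (dV / V0) / (1 + dV / (2 * V0)))
}

#' One-set-of-sites ITC heats (Wiseman model)
#'
#' Predicted per-injection heats for a single class of `n` identical sites.
#' After injection i the cumulative heat in the cell is
#' `Q(i) = n*Mt*dH*V0/2 * (1 + r + k - sqrt((1 + r + k)^2 - 4r))` with
#' `r = Xt/(n*Mt)` and `k = Kd/(n*Mt)`, where `Mt`/`Xt` are the running
#' cell/titrant concentrations diluted by the displaced-volume convention.
#' The observed heat of injection i corrects for the heat carried out with
#' the displaced volume:
#' `dQ(i) = Q(i) - Q(i-1) + (dV_i/V0) * (Q(i) + Q(i-1)) / 2`.
#'
#' @param kd dissociation constant (nM), positive.
#' @param dh binding enthalpy (kJ/mol).
#' @param n stoichiometry (sites per cell-species molecule), positive.
#' @param cell_conc cell species concentration (uM).
#' @param syringe_conc syringe species concentration (uM).
#' @param cell_volume active cell volume (uL).
#' @param injection_volumes ordered injection volumes (uL).
#' @return numeric vector of per-injection heats (ucal), with the cumulative
#'   heats (ucal) attached as attribute `"q_cumulative"`.
#' @export
one_site_heats <- function(kd, dh, n, cell_conc, syringe_conc, cell_volume,
                           injection_volumes) {
  stop_if(!is_number(kd) || kd <= 0, "kd must be positive")
  stop_if(!is_number(n) || n <= 0, "n must be positive")
  cc <- itc_concentrations(cell_conc, syringe_conc, cell_volume, injection_volumes)
  V0 <- cell_volume * 1e-6
  Kd <- kd * 1e-9
  dH_cal <- dh * 1000 / .CAL_J                      # cal/mol
  r <- cc$Xt / (n * cc$Mt)
  k <- Kd / (n * cc$Mt)
  disc <- (1 + r + k)^2 - 4 * r
  stop_if(any(disc < 0), "internal error: negative discriminant in binding polynomial")
  Q <- n * cc$Mt * dH_cal * V0 / 2 * (1 + r + k - sqrt(disc))   # cal
  Qp <- c(0, Q[-length(Q)])
  dV <- injection_volumes * 1e-6
  dQ <- Q - Qp + (dV / V0) * (Q + Qp) / 2
  out <- dQ * 1e6                                    # ucal
  attr(out, "q_cumulative") <- Q * 1e6
  out
}

#' Fit the one-set-of-sites model to an ITC isotherm
#'
#' Nonlinear least squares over (Kd, dH, N) against the observed
#' per-injection heats, with Kd parameterised as log10(Kd) for positivity
#' and conditioning. Initialisation: `N` from the molar ratio at the
#' steepest heat change, `dH` from the first usable heat per mole injected,
#' `Kd` from a tenth of the cell concentration. The first injection is
#' dropped when the experiment flags it. Standard errors come from the fit
#' covariance (delta method for Kd); derived `dG` and `-TdS` are attached
#' via [derive_thermo()]. A Wiseman c-value (`n * cell_conc / Kd`) outside
#' \[1, 1000\] triggers a warning that Kd is poorly determined.
#'
#' @param experiment an [itc_experiment()].
#' @return a [thermo_params()] object.
#' @export
fit_one_site <- function(experiment) {
  stopifnot(inherits(experiment, "itc_experiment"))
  use <- seq_along(experiment$heats)
  if (isTRUE(experiment$first_injection_excluded)) use <- use[-1]
  stop_if(length(use) < 6L, "need at least 6 usable injections after first-injection removal")
  h <- experiment$heats[use]
  vols <- experiment$injection_volumes
  if (max(abs(h)) < 1e-9) {
    warning("all heats are zero: dH ~ 0 and Kd is unidentifiable")
    return(thermo_params(kd = NA_real_, n = NA_real_, dh = 0,
                         temperature_K = experiment$temperature + 273.15))
  }
  cc <- itc_concentrations(experiment$cell_conc, experiment$syringe_conc,
                           experiment$cell_volume, vols)
  ratio <- cc$Xt / cc$Mt
  # initial guesses
  i_steep <- use[which.max(abs(diff(h)))]
  n0 <- min(max(ratio[i_steep], 0.1), 10)
  mol_inj1 <- vols[use[1]] * 1e-6 * experiment$syringe_conc * 1e-6   # mol
  dh0 <- (h[1] * 1e-6 / mol_inj1) * .CAL_J / 1000                    # kJ/mol
  kd0 <- experiment$cell_conc * 1e3 / 10                             # nM
  model <- function(logkd, dh, n)
    one_site_heats(10^logkd, dh, n, experiment$cell_conc,
                   experiment$syringe_conc, experiment$cell_volume, vols)[use]
  fit <- tryCatch(
    minpack.lm::nlsLM(h ~ model(logkd, dh, n),
                      start = list(logkd = log10(kd0), dh = dh0, n = n0),
                      lower = c(-6, -Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("one-site fit did not converge: ", conditionMessage(fit), call. = FALSE)
  cf <- coef(fit)
  kd <- 10^cf[["logkd"]]
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  kd_se <- kd * log(10) * unname(ses["logkd"])
  cval <- cf[["n"]] * experiment$cell_conc * 1e3 / kd
  if (!is.na(cval) && (cval < 1 || cval > 1000))
    warning(sprintf("Wiseman c-value %.3g outside [1, 1000]: Kd poorly determined", cval))
  thermo_params(kd = unname(kd), kd_se = kd_se,
                n = unname(cf[["n"]]), n_se = unname(ses["n"]),
                dh = unname(cf[["dh"]]), dh_se = unname(ses["dh"]),
                temperature_K = experiment$temperature + 273.15)
}

#' Derive binding free energy and entropy term
#'
#' `dG = R*T*ln(Kd in molar)` and `-TdS = dG - dH`, with
#' R = 8.314 J mol^-1 K^-1; both in kJ/mol.
#'
#' @param kd dissociation constant (nM), positive.
#' @param dh binding enthalpy (kJ/mol).
#' @param temperature_K absolute temperature (K).
#' @return list with `dg` and `minus_tds` (kJ/mol).
#' @export
derive_thermo <- function(kd, dh, temperature_K = 298.15) {
  stop_if(!is_number(kd) || kd <= 0, "kd must be positive")
  dg <- .R_GAS * temperature_K * log(kd * 1e-9) / 1000
  list(dg = dg, minus_tds = dg - dh)
}

#' Binding thermodynamics container
#'
#' Holds fitted `Kd`, `N`, `dH` with standard errors plus the derived `dG`
#' and `-TdS` (computed here so the identity `dG = dH + (-TdS)` holds to
#' machine precision).
#'
#' @param kd,kd_se dissociation constant (nM) and SE.
#' @param n,n_se stoichiometry and SE.
#' @param dh,dh_se binding enthalpy (kJ/mol) and SE.
#' @param temperature_K absolute temperature (K).
#' @param variant_id optional label.
#' @return object of class `thermo_params` with `dg` and `minus_tds` filled
#'   in (NA when `kd` is unavailable).
#' @export
thermo_params <- function(kd, kd_se = NA_real_, n = NA_real_, n_se = NA_real_,
                          dh = NA_real_, dh_se = NA_real_,
                          temperature_K = 298.15, variant_id = NA_character_) {
  derived <- if (is_number(kd) && kd > 0) derive_thermo(kd, dh, temperature_K)
             else list(dg = NA_real_, minus_tds = NA_real_)
  structure(list(variant_id = variant_id, kd = kd, kd_se = kd_se,
                 n = n, n_se = n_se, dh = dh, dh_se = dh_se,
                 dg = derived$dg, minus_tds = derived$minus_tds,
                 temperature_K = temperature_K),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> %s: Kd %s nM, N %s, dH %s kJ/mol, dG %s, -TdS %s kJ/mol (T %g K)\n",
              x$variant_id, signif(x$kd, 3), signif(x$n, 3), signif(x$dh, 3),
              signif(x$dg, 3), signif(x$minus_tds, 3), x$temperature_K))
  invisible(x)
}
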