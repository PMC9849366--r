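#' Construct a stopped-flow fluorescence trace
#'
#' One averaged stopped-flow time course under pseudo-first-order mixing,
#' with the mixing metadata the downstream fits need.
#'
#' @param times numeric vector of times (s), strictly increasing, length >= 10.
#' @param signal fluorescence signal (arbitrary units), same length.
#' @param partner_conc concentration of the excess (unlabeled) partner (uM).
#' @param labeled_conc concentration of the labeled species (uM).
#' @param temperature temperature (C).
#' @param salt NaCl concentration (mM).
#' @param true_kobs optional known observed rate constant (s^-1) when the
#'   trace was synthesised; carried as metadata only.
#' @return object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, signal, partner_conc = NA_real_,
                               labeled_conc = NA_real_, temperature = NA_real_,
                               salt = NA_real_, true_kobs = NULL) {
  stop_if(length(times) != length(signal), "times and signal lengths differ")
  stop_if(length(times) < 10L, "a trace needs at least 10 points")
  stop_if(any(diff(times) <= 0), "times must be strictly increasing")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 partner_conc = partner_conc, labeled_conc = labeled_conc,
                 temperature = temperature, salt = salt, true_kobs = true_kobs),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %d points, t = [%g, %g] s, partner %g uM\n",
              length(x$times), min(x$times), max(x$times), x$partner_conc))
  invisible(x)
}

#' Construct a pseudo-first-order kobs series
#'
#' @param concs partner concentrations (uM); at least two distinct values.
#' @param kobs_values observed rate constants (s^-1), same length.
#' @param kobs_ses optional standard errors on kobs (s^-1).
#' @param variant_id optional label.
#' @param true_kon,true_koff optional ground-truth slope/intercept metadata.
#' @return object of class `pfo_series`.
#' @export
pfo_series <- function(concs, kobs_values, kobs_ses = NULL, variant_id = NA_character_,
                       true_kon = NULL, true_koff = NULL) {
  stop_if(length(concs) != length(kobs_values), "concs and kobs lengths differ")
  stop_if(length(unique(concs)) < 2L, "need at least 2 distinct concentrations")
  structure(list(concs = as.numeric(concs), kobs_values = as.numeric(kobs_values),
                 kobs_ses = kobs_ses, variant_id = variant_id,
                 true_kon = true_kon, true_koff = true_koff),
            class = "pfo_series")
}

#' Construct a displacement kobs series
#'
#' Observed rate constants from mixing preformed labeled complex with
#' increasing concentrations of unlabeled competitor; at saturating
#' competitor kobs approaches koff.
#'
#' @param displacer_concs competitor concentrations (uM), positive.
#' @param kobs_values observed rate constants (s^-1), same length.
#' @param variant_id optional label.
#' @param true_koff optional ground-truth asymptote metadata.
#' @return object of class `displacement_series`.
#' @export
displacement_series <- function(displacer_concs, kobs_values,
                                variant_id = NA_character_, true_koff = NULL) {
  stop_if(length(displacer_concs) != length(kobs_values),
          "concs and kobs lengths differ")
  stop_if(length(displacer_concs) < 3L,
          "asymptote fit needs at least 3 points")
  stop_if(any(displacer_concs <= 0), "displacer concentrations must be positive")
  structure(list(displacer_concs = as.numeric(displacer_concs),
                 kobs_values = as.numeric(kobs_values),
                 variant_id = variant_id, true_koff = true_koff),
            class = "displacement_series")
}

#' Fit a single exponential to a stopped-flow trace
#'
#' Least-squares fit of `signal = offset + amplitude * exp(-kobs * t)`.
#' Initial values: `offset` from the mean of the final 5% of points,
#' `kobs` from `ln 2 / t_half` at the half-amplitude crossing. A fit whose
#' amplitude is indistinguishable from zero (|amplitude| <= 3 x residual
#' noise estimate) is flagged as failed and reports no kobs.
#'
#' @param trace a [fluorescence_trace()].
#' @return object of class `rate_fit` with fields `kobs`, `kobs_se`,
#'   `amplitude`, `offset`, `residual_sse`, `ok`, `message`.
#' @export
fit_single_exponential <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (is_number(trace$partner_conc) && is_number(trace$labeled_conc) &&
      trace$partner_conc < 10 * trace$labeled_conc)
    warning("pseudo-first-order condition violated: partner_conc < 10 x labeled_conc")
  t <- trace$times; y <- trace$signal
  n_tail <- max(2L, ceiling(0.05 * length(y)))
  offset0 <- mean(tail(y, n_tail))
  amp0 <- y[1] - offset0
  # half-amplitude crossing for the rate guess
  if (abs(amp0) > 0) {
    past_half <- which(abs(y - offset0) <= abs(amp0) / 2)
    t_half <- if (length(past_half)) t[past_half[1]] else max(t) / 2
    k0 <- log(2) / max(t_half, diff(range(t)) / length(t))
  } else k0 <- 1 / max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ offset + amplitude * exp(-kobs * t),
                      start = list(offset = offset0, amplitude = amp0, kobs = k0),
                      lower = c(-Inf, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(rate_fit_failed(paste("fit did not converge:", conditionMessage(fit))))
  cf <- coef(fit)
  res <- residuals(fit)
  noise <- sd(res)
  if (!isTRUE(abs(cf[["amplitude"]]) > 3 * noise))
    return(rate_fit_failed("amplitude indistinguishable from zero"))
  se <- tryCatch(summary(fit)$coefficients["kobs", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(kobs = unname(cf[["kobs"]]), kobs_se = unname(se),
                 amplitude = unname(cf[["amplitude"]]),
                 offset = unname(cf[["offset"]]),
                 residual_sse = sum(res^2), ok = TRUE, message = NULL),
            class = "rate_fit")
}

rate_fit_failed <- function(msg) {
  warning(msg, call. = FALSE)
  structure(list(kobs = NA_real_, kobs_se = NA_real_, amplitude = NA_real_,
                 offset = NA_real_, residual_sse = NA_real_, ok = FALSE,
                 message = msg),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  if (x$ok)
    cat(sprintf("<rate_fit> kobs = %.4g +/- %.2g s^-1\n", x$kobs, x$kobs_se))
  else cat("<rate_fit> FAILED:", x$message, "\n")
  invisible(x)
}

#' Association rate constant from a pseudo-first-order series
#'
#' Ordinary least squares of kobs on partner concentration; the slope is
#' `kon` (uM^-1 s^-1) and the intercept estimates `koff` (s^-1). With only
#' two points the line is exact and the standard errors are reported as NA.
#'
#' @param series a [pfo_series()].
#' @return list with `kon`, `kon_se`, `intercept`, `intercept_se`,
#'   `r_squared`.
#' @export
fit_association <- function(series) {
  stopifnot(inherits(series, "pfo_series"))
  stop_if(length(unique(series$concs)) < 2L, "singular design: all concentrations equal")
  m <- lm(kobs ~ conc, data = data.frame(conc = series$concs, kobs = series$kobs_values))
  sm <- summary(m)$coefficients
  se_ok <- nrow(sm) == 2L && length(series$concs) > 2L
  list(kon = unname(coef(m)[2]), kon_se = if (se_ok) sm["conc", 2] else NA_real_,
       intercept = unname(coef(m)[1]),
       intercept_se = if (se_ok) sm["(Intercept)", 2] else NA_real_,
       r_squared = summary(m)$r.squared)
}

#' Dissociation rate constant from a displacement series
#'
#' Fits `kobs(d) = koff + A * exp(-d / scale)` and reports the asymptote
#' `koff`. Initialisation: asymptote at `min(kobs)`, amplitude at the range,
#' scale at the median displacer concentration. A non-decreasing series
#' (Spearman rho >= 0) triggers a warning; an essentially constant series is
#' returned directly as its mean with zero amplitude.
#'
#' @param series a [displacement_series()].
#' @return list with `koff`, `koff_se`, `amplitude`, `decay_scale`, `ok`,
#'   and `flagged` (TRUE when the fitted koff is non-positive).
#' @export
fit_displacement <- function(series) {
  stopifnot(inherits(series, "displacement_series"))
  d <- series$displacer_concs; k <- series$kobs_values
  if (sd(k) < 1e-10 * max(abs(k), 1)) {
    return(list(koff = mean(k), koff_se = 0, amplitude = 0,
                decay_scale = NA_real_, ok = TRUE, flagged = mean(k) <= 0))
  }
  rho <- suppressWarnings(cor(d, k, method = "spearman"))
  if (is.finite(rho) && rho >= 0)
    warning("displacement series is not overall decreasing (Spearman rho >= 0)")
  fit <- tryCatch(
    minpack.lm::nlsLM(k ~ koff + A * exp(-d / cs),
                      start = list(koff = min(k), A = diff(range(k)), cs = median(d)),
                      lower = c(-Inf, -Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("displacement fit did not converge: ", conditionMessage(fit), call. = FALSE)
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["koff", "Std. Error"],
                 error = function(e) NA_real_)
  flagged <- cf[["koff"]] <= 0
  if (flagged) warning("fitted koff is non-positive; flagged")
  list(koff = unname(cf[["koff"]]), koff_se = unname(se),
       amplitude = unname(cf[["A"]]), decay_scale = unname(cf[["cs"]]),
       ok = TRUE, flagged = flagged)
}

#' Equilibrium dissociation constant from rate constants
#'
#' `Kd (nM) = koff / kon * 1000` for `koff` in s^-1 and `kon` in
#' uM^-1 s^-1. The standard error is propagated in quadrature from the
#' relative errors of the two rate constants. A non-positive `koff` is
#' flagged (at `koff = 0` the Kd is reported as 0).
#'
#' @param kon association rate constant (uM^-1 s^-1), positive.
#' @param koff dissociation rate constant (s^-1).
#' @param kon_se,koff_se optional standard errors.
#' @return list with `kd_nM`, `kd_se`, `flagged`.
#' @export
compute_kd <- function(kon, koff, kon_se = NA_real_, koff_se = NA_real_) {
  stop_if(!is_number(kon) || kon <= 0, "kon must be a positive number")
  flagged <- koff <= 0
  if (flagged) warning("koff <= 0: Kd reported at face value and flagged")
  kd <- koff / kon * 1e3
  se <- if (is_number(kon_se) && is_number(koff_se) && koff > 0)
    kd * sqrt((kon_se / kon)^2 + (koff_se / koff)^2) else NA_real_
  list(kd_nM = kd, kd_se = se, flagged = flagged)
}

#' Per-variant binding kinetics summary
#'
#' The row type of a kinetics report: `kon`, `koff` and the derived `Kd`
#' (always recomputed here as `koff/kon`, unit-converted) with standard
#' errors.
#'
#' @param variant_id label.
#' @param kon,kon_se association rate constant (uM^-1 s^-1) and SE.
#' @param koff,koff_se dissociation rate constant (s^-1) and SE.
#' @return object of class `binding_kinetics`.
#' @export
binding_kinetics <- function(variant_id, kon, kon_se = NA_real_,
                             koff, koff_se = NA_real_) {
  kd <- compute_kd(kon, koff, kon_se, koff_se)
  structure(list(variant_id = variant_id, kon = kon, kon_se = kon_se,
                 koff = koff, koff_se = koff_se,
                 kd_nM = kd$kd_nM, kd_se = kd$kd_se, flagged = kd$flagged),
            class = "binding_kinetics")
}

#' @export
print.binding_kinetics <- function(x, ...) {
  cat(sprintf("<binding_kinetics> %s: kon %s uM^-1 s^-1, koff %s s^-1, Kd %s nM\n",
              x$variant_id, signif(x$kon, 2), signif(x$koff, 2), signif(x$kd_nM, 2)))
  invisible(x)
}

#' Fold change between two rate constants
#'
#' Plain ratio `rate_a / rate_b`; report at two significant figures at the
#' presentation layer (internal value is unrounded).
#'
#' @param rate_a,rate_b positive rates in the same units.
#' @return the unrounded ratio.
#' @export
fold_change <- function(rate_a, rate_b) {
  stop_if(!is_number(rate_b) || rate_b <= 0, "denominator rate must be positive")
  rate_a / rate_b
}

#' Construct an ionic-strength rate series
#'
#' @param nacl_mM NaCl concentrations (mM), positive; at least 3 points.
#' @param rate_values rate constants (uM^-1 s^-1 for association, s^-1 for
#'   dissociation).
#' @param rate_kind `"association"` or `"dissociation"`.
#' @param variant_id optional label.
#' @return object of class `salt_series`.
#' @export
salt_series <- function(nacl_mM, rate_values, rate_kind = c("association", "dissociation"),
                        variant_id = NA_character_) {
  rate_kind <- match.arg(rate_kind)
  stop_if(length(nacl_mM) != length(rate_values), "lengths differ")
  stop_if(length(nacl_mM) < 3L, "basal-rate extrapolation needs at least 3 salt points")
  stop_if(any(nacl_mM <= 0), "NaCl concentrations must be positive")
  structure(list(nacl_mM = as.numeric(nacl_mM), rate_values = as.numeric(rate_values),
                 rate_kind = rate_kind, variant_id = variant_id),
            class = "salt_series")
}

#' Basal (electrostatics-free) rate constant by ionic-strength extrapolation
#'
#' Fits `ln k` linearly in `I^(-1/2)` (the high-screening Debye-Hueckel
#' limit), with the ionic strength I taken as the NaCl molarity. The basal
#' rate — the rate constant with electrostatic steering fully screened — is
#' the `I -> Inf` extrapolation, `exp(intercept)`; its standard error comes
#' from the intercept SE by the delta method.
#'
#' @param series a [salt_series()].
#' @return object of class `basal_rate_fit` with `basal_rate`, `basal_se`,
#'   `slope_beta`, `r_squared`.
#' @export
fit_salt_dependence <- function(series) {
  stopifnot(inherits(series, "salt_series"))
  stop_if(any(series$rate_values <= 0), "all rates must be positive for the log fit")
  I <- series$nacl_mM / 1000
  x <- 1 / sqrt(I)
  m <- lm(lk ~ x, data = data.frame(x = x, lk = log(series$rate_values)))
  sm <- summary(m)
  basal <- exp(unname(coef(m)[1]))
  structure(list(basal_rate = basal,
                 basal_se = basal * sm$coefficients["(Intercept)", 2],
                 slope_beta = unname(coef(m)[2]),
                 r_squared = sm$r.squared,
                 rate_kind = series$rate_kind, variant_id = series$variant_id),
            class = "basal_rate_fit")
}

#' @export
print.basal_rate_fit <- function(x, ...) {
  cat(sprintf("<basal_rate_fit> %s %s: basal %.3g +/- %.2g (R^2 %.3f)\n",
              x$variant_id, x$rate_kind, x$basal_rate, x$basal_se, x$r_squared))
  invisible(x)
}

#' Linear free-energy relationship across variants
#'
#' OLS of `log10(kon)` and of `log10(koff)` on `log10(Kd)` across a variant
#' panel. When every Kd is computed as `koff/kon` the two slopes differ by
#' exactly 1 (an algebraic identity); a koff slope near 1 with a kon slope
#' near 0 indicates that affinity changes are carried by the complex
#' lifetime, not by association.
#'
#' @param kinetics list of [binding_kinetics()] objects (>= 3), or a data
#'   frame with columns `kon`, `koff`, `kd_nM`.
#' @return object of class `lfer_result` with slopes, SEs, intercepts and
#'   R^2 for both regressions.
#' @export
lfer_regression <- function(kinetics) {
  df <- if (is.data.frame(kinetics)) kinetics else
    do.call(rbind, lapply(kinetics, function(b)
      data.frame(kon = b$kon, koff = b$koff, kd_nM = b$kd_nM)))
  stop_if(nrow(df) < 3L, "LFER needs at least 3 variants")
  x <- log10(df$kd_nM)
  fit1 <- lm(y ~ x, data = data.frame(x = x, y = log10(df$kon)))
  fit2 <- lm(y ~ x, data = data.frame(x = x, y = log10(df$koff)))
  g <- function(m) {
    sm <- summary(m)$coefficients
    list(slope = unname(coef(m)[2]), slope_se = sm[2, 2],
         intercept = unname(coef(m)[1]), r_squared = summary(m)$r.squared)
  }
  a <- g(fit1); b <- g(fit2)
  structure(list(slope_kon_vs_kd = a$slope, slope_kon_se = a$slope_se,
                 intercept_kon = a$intercept, r_squared_kon = a$r_squared,
                 slope_koff_vs_kd = b$slope, slope_koff_se = b$slope_se,
                 intercept_koff = b$intercept, r_squared_koff = b$r_squared),
            class = "lfer_result")
}

#' @export
print.lfer_result <- function(x, ...) {
  cat(sprintf("<lfer_result> slope(log kon ~ log Kd) = %.3f +/- %.3f; slope(log koff ~ log Kd) = %.3f +/- %.3f\n",
              x$slope_kon_vs_kd, x$slope_kon_se, x$slope_koff_vs_kd, x$slope_koff_se))
  invisible(x)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3; both non-constant.
#' @return R^2 in \[0, 1\].
#' @export
pearson_r2 <- function(x, y) {
  stop_if(length(x) != length(y), "lengths differ")
  stop_if(length(x) < 3L, "need at least 3 points")
  stop_if(sd(x) == 0 || sd(y) == 0, "correlation undefined for constant input")
  cor(x, y)^2
}
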