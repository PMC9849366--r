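---
title: "Methods: residual helicity and binding of an IDP motif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual helicity and binding of an IDP motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixbind)
```

## The system and the question

Many intrinsically disordered regions bind their partners through short
linear motifs that fold into an α-helix in the complex. In the free state
the motif is not fully disordered: it populates a *residual* helix some
fraction of the time. helixbind implements the quantitative chain that
connects that fractional helicity to binding kinetics and thermodynamics
for a variant panel of one such motif, the DREB2A(244–272) region binding
the RCD1-RST domain. Substitutions at the C-terminal end of the motif helix
(R266G, R266A, D267A, D267L) raise or lower the helix population without
changing the binding interface, which makes the panel a controlled probe of
what residual structure buys: the analyses here ask whether it changes how
fast the complex forms (`kon`), how long it lives (`koff`), and how the
binding free energy splits into enthalpy and entropy.

## Kinetic model and assumptions

Stopped-flow traces are fitted to a single exponential,
`S(t) = offset + amplitude·exp(−kobs·t)`. This presumes pseudo-first-order
conditions — the unlabeled partner at ≥10× the labeled species — and
`fit_single_exponential()` warns when a trace's metadata violates that
ratio. Association experiments across partner concentrations give
`kobs = kon·c + koff`; `fit_association()` takes the unweighted OLS slope.
Dissociation is measured by displacement: preformed labeled complex mixed
with excess unlabeled competitor relaxes with a `kobs` that falls toward
`koff` as the competitor saturates rebinding. `fit_displacement()` fits a
three-parameter exponential `koff + A·exp(−d/c)` with a free asymptote.
The exponential shape is a modelling convenience — the measured quantity is
the asymptote, which is robust to the exact decay form, and the generator
uses the same shape so asymptote recovery can be tested independently of
shape correctness (a two-stage grid oracle in the test suite checks the
asymptote without assuming the fitted model's parameterisation).

`Kd` is always derived as `koff/kon` (reported in nM), never fitted
separately, so the identity `kd = koff/kon` holds exactly in every report
row before rounding; its SE combines the two relative errors in quadrature,
which assumes independent errors — reasonable since slope and asymptote
come from different experiments.

All OLS fits are unweighted. Per-point errors are available in the data
structures but deliberately unused by default, matching common practice for
these small series where per-point SEs are themselves noisy.

### Ionic strength and basal rates

Electrostatic steering accelerates association between the negatively
charged motif and the positively charged domain surface. We model the salt
dependence as `ln k` linear in `I^(−1/2)`, the high-screening limit of
Debye–Hückel theory, and take the ionic strength to be the NaCl molarity
alone, ignoring the constant 50 mM buffer contribution — the choice of I
convention shifts all points together and barely moves the extrapolated
intercept. The basal rate is `exp(intercept)` at `I^(−1/2) → 0`, i.e.
infinite screening, with its SE by the delta method
(`basal·SE(intercept)`). On the packaged printed salt series this
reproduces all four published basal rates within their stated errors
(association: R266G, WT, D267L; dissociation: WT), which is the empirical
justification for the functional form — the published tables state no
functional form for the extrapolation.

### LFER

`lfer_regression()` regresses `log10(kon)` and `log10(koff)` on
`log10(Kd)` across variants. Because `log Kd = log koff − log kon`, the two
slopes must differ by exactly 1 whenever Kd is derived from the same rate
constants; the package preserves this identity to machine precision and
the tests assert it on random panels. On the printed five-variant values
the slopes are 0.008 and 1.008: affinity differences across the panel are
carried essentially entirely by `koff`.

## Helicity from NMR and CD

`compute_scs()` subtracts a random-coil reference from observed Cα shifts.
The packaged reference (`random_coil_reference()`) is a generic
per-residue-type table; sequence-dependent neighbour-corrected values, when
available from an external predictor, are supplied as a file and override
it. Unassigned residues are excluded from region means, never imputed.
`region_helicity()` averages SCS over an inclusive residue interval
(defaults: free state D262–R266, bound state V261–D267, full-protein
numbering) and converts by `100·mean/3.1`, with 3.1 ppm the reference SCS
of a fully formed helix. The stored percent is unrounded and unclipped —
region means slightly above the reference occur in fully folded complexes
and print as values just over 100% — and the reporting layer clips to
[0, 110] and rounds half-away-from-zero to integers.

For CD, `compute_mre()` applies `[θ]λ = θ°·MRW/(10·l·c)` and
`helicity_from_mre()` converts the 222 nm ellipticity through the
two-point anchors −3000 (coil) and −42000 (full helix). The printed
two-point formula, read literally as `([θ]222 + 3000)/39000`, yields
negative fractions for helical (negative) ellipticities; the implementation
evaluates `−([θ]222 + 3000)/39000`, the sign convention under which the
anchors and all the published 11–19% values are reproduced. The nearest
spectral point within 1 nm of 222 nm is used; fractions are clipped to
[0, 1].

The two helicity scales measure different things — region-average SCS
versus whole-peptide CD — so `fit_calibration()` regresses the NMR-scale
percent on the CD percent and `apply_calibration()` transfers CD values
onto the NMR scale for variants lacking isotope-labeled samples. The
NMR-side values entering the calibration are accepted as data, not derived,
since they live on a whole-peptide scale that region averages do not
reproduce.

## ITC model

`one_site_heats()` implements the one-set-of-sites isotherm: after
injection i the cumulative heat is

```
Q(i) = n·Mt·ΔH·V0/2 · [1 + r + k − sqrt((1 + r + k)² − 4r)],
r = Xt/(n·Mt),  k = Kd/(n·Mt)
```

with `Mt`, `Xt` the running cell and titrant concentrations under the
displaced-volume convention (`Mt = M0·(1 − v/2V0)/(1 + v/2V0)`,
`Xt = X0·(v/V0)/(1 + v/2V0)` for cumulative injected volume v), and the
observed per-injection heat corrected for the liquid expelled from the
active volume: `ΔQ(i) = Q(i) − Q(i−1) + (dVi/V0)·(Q(i)+Q(i−1))/2`. This is
the standard instrument-software convention, so fitted parameters are
comparable with vendor fits. Heats are handled in µcal internally and ΔH
converted to kJ/mol (4.184 J/cal) only at the interface.

`fit_one_site()` optimises `(log10 Kd, ΔH, N)` — the log parameterisation
enforces positivity and conditions the search — initialised with N at the
molar ratio of the steepest heat change, ΔH from the first usable heat per
mole injected, and Kd at a tenth of the cell concentration. The first
injection (small volume, diffusion across the syringe tip) is excluded by
default, mirroring instrument practice. SEs come from the fit covariance,
with the Kd SE mapped back by the delta method. A Wiseman c-value
(`N·[cell]/Kd`) outside [1, 1000] triggers a warning that Kd is poorly
determined; an all-zero isotherm short-circuits to `ΔH = 0` with Kd
reported unidentifiable. `ΔG = RT·ln Kd` and `−TΔS = ΔG − ΔH` are computed
in `thermo_params()` so the identity `ΔG = ΔH + (−TΔS)` is structural.

## The synthetic generators

Each generator draws from one explicit integer seed
(`withr::with_seed`), making every output bit-reproducible; noise is
additive i.i.d. Gaussian on the signal (traces), on kobs (series), on
heats (ITC), on MRE (CD) and on shifts (NMR) — the simplest model
consistent with instrument-averaged data. What they emulate, and what they
do not:

* **Traces** are ideal single exponentials plus noise. No dead time,
  photobleaching drift, or double-exponential character — so passing
  recovery tests shows the fitting chain is correct, not that real traces
  are single-exponential.
* **Displacement series** decay exponentially in competitor concentration
  with the true `koff` as asymptote; the real concentration dependence is
  unknown, so only asymptote recovery, not shape, is evidence.
* **CD spectra** are two fixed basis shapes (helix: 208/222 nm double
  minimum, positive 192 nm band; coil: 198 nm minimum) pinned exactly to
  the 222 nm anchors so the Eq.-2 round trip is the identity; band shapes
  elsewhere are plausible but not calibrated.
* **Shift tables** place observed Cα at coil + fraction·3.1 ppm; Cβ stays
  at coil. Real SCS profiles taper at helix ends.
* **ITC isotherms** come from the same forward model the fitter uses, so
  noiseless round trips test the optimiser, and the independent root-finder
  oracle in the tests guards the forward model itself.

`simulate_study()` materialises a five-variant demonstration study with
ground truths set to the published values (rates from the kinetics table;
region helix fractions from the published SCS averages; CD fractions from
the 0% TFE helicities with a monotone TFE ramp
`f(TFE) = f0 + (0.9 − f0)·TFE/100`; ITC parameters from the thermodynamics
table; a WT salt series generated from the basal-rate model anchored at
the 100 mM rates with basal rate 5). Default noise levels: 1% of the
fluorescence amplitude per trace point, 1% of `koff` per displacement
point, 100 MRE units per CD point, 0.05 µcal per injection, noiseless
shift tables — values a practitioner would call clean but realistic for
averaged data, chosen once. The demonstration sequence is a synthetic
stand-in that preserves the motif positions (V261–D267) but is not the
native sequence; it only feeds the random-coil lookup, which cancels in
the SCS round trip.

## Numerical choices and degenerate inputs

* Exponential trace fits: Levenberg–Marquardt (`minpack.lm::nlsLM`,
  maxiter 200), `kobs` bounded positive, initial `kobs = ln 2/t_half` from
  the half-amplitude crossing and offset from the final 5% of points. A
  fitted amplitude not exceeding 3× the residual SD is flagged as failure
  and no kobs is reported (a constant trace fails this test by
  construction).
* Displacement: near-constant series (relative spread < 1e−10) return
  their mean directly; otherwise nlsLM with the scale bounded positive. A
  non-decreasing series warns (Spearman ρ ≥ 0); a non-positive fitted
  asymptote is flagged.
* ITC: `log10 Kd` bounded below at 10⁻⁶ nM; maxiter 500.
* Two-point association series fit exactly; their SEs are reported NA
  rather than 0.
* Rounding happens only at reporting boundaries: rates and Kd at two
  significant figures, percent helix as integers (half away from zero),
  energies at one decimal. Internal values are never rounded, which
  matters because several published integers (e.g. a bound-state 79% from
  a printed 2.4 ppm mean) are only consistent with unrounded means.

Problem sizes in the shipped tests and demonstration: 250-point traces
(150 in the test run), six association concentrations, twelve displacement
points, the 0.5 + 17×2 µL injection schedule, 100-seed recovery ensembles —
sizes chosen to match the study design where stated and to keep recovery
statistics meaningful.

## Known limitations

No global multi-trace fitting, dead-time correction, or induced-fit versus
conformational-selection flux modelling; no CD deconvolution beyond the
two-point 222 nm conversion; no multi-site or competitive ITC models and
no raw-thermogram integration; the random-coil reference is generic rather
than sequence-corrected. The free-vs-bound helicity and helicity–koff
correlations are reported on both axis conventions (linear and log koff)
because three- to five-point regressions are sensitive to that choice; the
package reports what it computes and does not force agreement with any
particular printed correlation.
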