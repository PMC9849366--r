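# helixbind

Quantitative analysis of coupled folding and binding for intrinsically
disordered protein (IDP) motifs, built around the interaction between the
RST domain of the plant hub protein RCD1 and the disordered transcription
factor region DREB2A(244–272). Variants of the DREB2A helix region (WT,
R266G, R266A, D267A, D267L) tune the *residual* α-helix population of the
free peptide; the package quantifies that helicity and links it to binding
kinetics and thermodynamics.

It is written for biophysicists analysing stopped-flow fluorescence, NMR
chemical shifts, far-UV CD and ITC data on such systems — and it ships
seeded synthetic generators for every input, so the entire pipeline is
testable by parameter recovery without instrument data.

## What it computes

**Kinetics.** Under pseudo-first-order mixing a binding trace relaxes as a
single exponential, `S(t) = S∞ + A·exp(−k_obs·t)`. Association series give
`k_obs = k_on·[partner] + k_off`, so `k_on` is the OLS slope; displacement
series decay to the asymptote `k_off`; and

```
K_d (nM) = k_off / k_on × 10³,   SE(K_d) = K_d·√((SE_on/k_on)² + (SE_off/k_off)²)
```

Ionic-strength series are analysed as `ln k` linear in `I^(−1/2)`
(high-screening Debye–Hückel limit, I = NaCl molarity); the intercept
exponentiates to the *basal* rate constant — the rate with electrostatic
steering fully screened. A linear free-energy relationship (LFER) regresses
`log₁₀ k_on` and `log₁₀ k_off` on `log₁₀ K_d` across variants; when every
K_d comes from `k_off/k_on` the two slopes differ by exactly 1.

**NMR helicity.** Secondary Cα chemical shifts, `SCS = δCα(obs) −
δCα(coil)`, average over a residue region and convert to percent helix
against the 3.1 ppm full-helix reference: `% helix = 100·mean(SCS)/3.1`
(free-state region D262–R266, bound-state region V261–D267).

**CD helicity.** Mean residue ellipticity `[θ]λ = θ°λ·MRW/(10·l·c)`, and
percent helix from the 222 nm anchors (−3000 for coil, −42000 for full
helix): `fraction = −([θ]₂₂₂ + 3000)/39000`. A fitted calibration line
(published: `Y = 1.538x − 14.93`) transfers whole-peptide CD helicities
onto the NMR region scale.

**ITC.** The one-set-of-sites (Wiseman) model with displaced-volume
bookkeeping predicts per-injection heats; nonlinear least squares recovers
`K_d`, `N` and `ΔH`, and `ΔG = RT·ln K_d`, `−TΔS = ΔG − ΔH` follow.

## Worked example

```r
library(helixbind)

# published R266G rate constants -> Kd with propagated SE
kd <- compute_kd(kon = 230, koff = 0.70, kon_se = 15, koff_se = 0.01)
c(kd$kd_nM, kd$kd_se)
#> [1] 3.0434783 0.2031938        # printed as 3.0 ± 0.2 nM

# a full synthetic five-variant study with published ground truths
cfg <- simulate_study(file.path(tempdir(), "study"), seed = 1)
rep <- run_study(cfg)
rep
#> <study_report> 5 variants
#> kinetics:
#>   variant_id kon koff kd_nM
#> 1         WT 240 0.18  0.74
#> 2      R266G 230 0.70  3.00
#> 3      R266A 250 0.38  1.50
#> 4      D267A 220 0.07  0.31
#> 5      D267L 240 0.03  0.13
#> <lfer_result> slope(log kon ~ log Kd) = 0.008 +/- 0.016; slope(log koff ~ log Kd) = 1.008 +/- 0.016
```

The kinetics table is the study's Table-1 analogue, recovered from noisy
synthetic traces: every rate constant lands within 2% of its ground truth
at 1% trace noise, the Kd column is exactly `koff/kon` (unit-converted),
and the LFER slopes say that affinity differences across the variant panel
live almost entirely in `k_off` — residual helicity tunes complex lifetime,
not association. `rep$thermo_table`, `rep$salt_table` and
`rep$correlations` hold the ITC, basal-rate and helicity–koff analyses of
the same run.

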