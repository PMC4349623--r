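# bindspec

Quantitative analysis of protein–ligand binding from calorimetry and
fluorescence spectroscopy, in one tested R package.

Binding studies of calcium-sensor proteins (calmodulin and its chimeras
with troponin C are the motivating system) routinely combine five
measurement modalities, each with its own model and its own vendor fitting
software:

* **ITC** — per-injection heats fitted with an identical-sites
  ("one set of sites": N, K_a, ΔH) or sequential two-site
  (K_a1 ≥ K_a2, ΔH1, ΔH2) isotherm, after subtracting a titrant-dilution
  blank; thermodynamic linkage ΔG = −RT ln K_a, ΔS = (ΔH − ΔG)/T, and the
  buffer-ionization decomposition ΔH_app = ΔH_b + n·ΔH_i.
* **TCSPC lifetimes** — photon-count decay histograms fitted by
  reconvolution of I(t) = A + Σ αᵢ·exp(−t/τᵢ) with the measured prompt,
  Poisson-weighted, with fractional intensities fᵢ = αᵢτᵢ/Σαⱼτⱼ, the
  amplitude-average lifetime ⟨τ⟩ = Σαᵢτᵢ²/Σαᵢτᵢ, and the strict reduced
  χ² < 1.2 acceptance rule.
* **Stern–Volmer quenching** — F₀/F = 1 + K_sv[Q] (and the per-lifetime
  analogue), bimolecular rate constant k_q = K_sv/τ₀, and a
  dynamic-vs-static classifier.
* **Stopped-flow kinetics** — single-exponential dissociation traces
  giving k_off, with a mono- vs bi-exponential adequacy check.
* **Spectra** — whole-spectrum integral fold-enhancement, refined λ_max,
  CD ellipticity ratio θ220/θ209, differential spectra, scan averaging.

`bindspec` implements all of these behind one consistent interface, plus
seeded synthetic-data generators for every modality, so each fitter can be
validated by exact round trips against known ground truth. See the methods
vignette (`vignettes/binding-analysis.Rmd`) for the models, numerical
choices, and limitations.

## Worked example

Simulate a peptide-into-protein titration (30 µM cell, 1 mM syringe,
20 × 10 µL injections) from known parameters, blank-correct it, and fit:

```r
library(bindspec)

sched <- titration_schedule(cell_conc_M = 30e-6, syringe_conc_M = 1e-3,
                            injection_volumes_L = rep(10e-6, 20))
truth <- binding_model("one_set_of_sites", N = 2.05, K_a = 8.92e5, dH = -5.02)
sim <- simulate_itc(sched, truth, noise_sd_ucal = 0.2, seed = 42)
tg  <- dilution_correct(sim$sample, sim$blank)
fit <- fit_isotherm(tg, "one_set_of_sites")
fit
#> Isotherm fit (one_set_of_sites)
#> Binding model: one set of sites
#>   N = 2.04, K_a = 8.92e+05 1/M, dH = -5.01 kcal/mol
#>   RSS = 1.118 ucal^2 over 20 injections; converged: TRUE
fit$thermo
#> dG = -8.118 kcal/mol, dH = -5.013 kcal/mol, dS = +10.41 cal/(mol K) at 298.15 K
```

At 0.2 µcal heat noise the fitter recovers the generating stoichiometry
(N ≈ 2 peptides per protein), affinity and enthalpy, and the derived
entropy is positive (~+10 cal mol⁻¹ K⁻¹): binding favored by both enthalpy
and desolvation entropy.

Quenching and kinetics work the same way — simulate, fit, read off:

```r
sr <- simulate_quench_series(baseline = 100, K_sv = 13.5,
                             noise_frac = 0.02, seed = 7)
stern_volmer_fit(sr, tau0_ns = 6.4)
#> Stern-Volmer fit (acrylamide): K_sv = 13.6 +/- 0.12 1/M (R^2 = 0.9984)
#>   k_q = 2.12e+09 1/(M s) (tau0 = 6.4 ns)

tr <- simulate_stopped_flow(1.41, duration_s = 2, dt_s = 0.002,
                            noise_frac = 0.02, seed = 7)
fit_single_exponential(tr)
#> Kinetics fit: k_off = 1.418 +/- 0.011 1/s, amplitude = 1, offset = 0.2
```

A K_sv of ~13.5 M⁻¹ is a fully solvent-exposed chromophore; a k_off of
~1.4 s⁻¹ is a peptide residence time of ~0.7 s. `run_pipeline()` chains
all stages on seeded synthetic data and `write_report()` serializes the
results deterministically (JSON or markdown); `read_thermogram()`,
`read_decay()`, `read_quench()`, `read_trace()` and `read_spectrum()`
ingest the documented CSV schemas for real instrument exports.

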