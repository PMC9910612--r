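# destfit

Two-pool exchange modeling of dark-state saturation transfer and relaxation
NMR data.

## The problem

Some solution species are invisible to NMR: assemblies whose transverse
relaxation is so fast that their resonance is broadened below the detection
limit. Aqueous phosphate is a striking case — the ³¹P line *broadens* on
heating, R₂ exceeds R₁ by one to two orders of magnitude, and
saturation-transfer (CEST/DEST) Z-spectrum dips are several times wider
than the no-exchange baseline of twice the nutation frequency. All of this
is explained by a small, temperature-promoted population of spectroscopically
dark assemblies in fast exchange with the visible monomers.

`destfit` is for spectroscopists who want to fit that model quantitatively.
It provides:

* a **two-state thermodynamic–kinetic parameterization** of the
  monomer ⇌ assembly equilibrium: dark fraction
  `pB = exp(−ΔG/RT) / (1 + exp(−ΔG/RT))` with `ΔG = ΔH − TΔS`, Arrhenius
  forward rate `kf = k0 exp(−Ea/RT)`, detailed-balance backward rate
  `kb = kf (1 − pB)/pB`, and the fast-exchange relation
  `R2,obs ≈ R2A + pB·ΔR2`;
* a **two-pool Bloch–McConnell simulator** for continuous-wave saturation:
  Z-spectra by exact matrix-exponential propagation, dip-width measurement,
  and observed R₁/R₂ under exchange by eigen-analysis;
* the **joint fitting pipeline** (`fit_r2_series()` + `joint_refine()`)
  that recovers ΔH, ΔS, k₀, Eₐ and a linear dark-pool R₂ᴮ(T) schedule from
  an R₂ temperature series plus Z-spectra, with a parameter-recovery report;
* **DOSY tools**: Stejskal–Tanner attenuation, log-linear diffusion fits
  with a multi-component flag, and gradient-schedule design;
* **hydrodynamic conversions**: Stokes–Einstein and
  Stokes–Einstein–Debye diameters, BPP random-field relaxation curves,
  linewidth ↔ R₂, and hydration-water counting;
* a **synthetic-study generator** with known ground truth, so the entire
  pipeline is testable end to end without instrument data.

## Worked example

The reference parameter set (ΔH = 25 kJ/mol, ΔS = 30 J/(mol K),
k₀ = 20,000 s⁻¹, Eₐ = 10 kJ/mol) pins the dark pool at about 0.1–0.7% of
the phosphate population over 293–353 K:

```r
library(destfit)

tp <- thermo_params(dH = 25e3, dS = 30, k0 = 2e4, Ea = 10e3)
signif(dark_population(tp, c(293, 353)), 2)
#> [1] 0.0013 0.0073
signif(forward_rate(tp, c(298, 353)), 2)
#> [1] 350 660
```

A tiny dark pool with R₂ᴮ in the several-hundred s⁻¹ range dominates the
observed relaxation — at 293 K the visible pool alone would relax at
0.3 s⁻¹, but exchange nearly triples that — and widens the CEST dip far
beyond the no-exchange factor-of-two:

```r
sys <- spin_system_at(tp, 298, R1A = 0.29, R2B = 496)
observed_rates(sys)
#>    R1obs    R2obs
#> 0.290000 1.045913

zs <- simulate_z_spectrum(sys, saturation_scheme(nutation = 150, duration = 5))
dip_width(zs)    # Hz; compare with 2 x 150 = 300 Hz without exchange
#> [1] 590.0448
```

The full closed loop — generate a synthetic study from known truth, fit the
R₂ series, refine jointly against the Z-spectra, and compare with truth:

```r
truth <- default_truth()
study <- generate_study(truth, study_design(noise_sigma = 0, seed = 1))
fit <- fit_r2_series(study$relaxation[c("temperature_K", "R2")],
                     function(T) r1a_at(truth, T))
refined <- joint_refine(fit, study$zspectra)
recovery_report(truth, refined)
#>        parameter truth    estimate relative_error
#> 1   dH_J_per_mol 25000 24999.99961  -1.550041e-08
#> 2 dS_J_per_mol_K    30    30.00054   1.786580e-05
#> 3       k0_per_s 20000 20001.12469   5.623430e-05
#> 4   Ea_J_per_mol 10000 10000.03939   3.939073e-06
#> 5 R2B_293K_per_s   450   449.97094  -6.456783e-05
#> 6 R2B_353K_per_s  1000   999.93541  -6.458524e-05
```

The DOSY/hydration chain: the measured diffusion coefficients at 293 and
343 K, converted through Stokes–Einstein with the water viscosity at each
temperature, show the hydrodynamic diameter shrinking by ~1.8 Å on heating
— a loss of six hydration waters (of eleven at infinite dilution):

```r
d1 <- stokes_einstein_diameter(7.5e-10, hydro_context(293))
d2 <- stokes_einstein_diameter(3.2e-9, hydro_context(343))
round((d1 - d2) * 1e10, 2)   # Angstrom
#> [1] 1.78
hydration_water_loss(d1, d2, r_w = 1.4e-10)$count
#> [1] 6
```

A command-line interface wraps the same functions
(`inst/scripts/destfit.R`; subcommands `simulate`, `zspec`, `fit`, `dosy`,
`hydro`, `recover`), reading and writing plain CSV with `#`-metadata
headers and JSON results.

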