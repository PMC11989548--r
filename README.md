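# statinfde

Fractional-order (Caputo) simulation of statin action on LDL-driven lipid
peroxidation and arterial mineralization.

Statins lower low-density lipoprotein (LDL) and with it the peroxidation
of arterial membrane lipids, whose diagnostic end product —
malondialdehyde (MDA) — shows up in FTIR spectra of atheromatic plaque as
the aldehyde CHO stretch at 1744 cm⁻¹.  Their benefit is dose-dependent
and *reverses* beyond a threshold dose.  `statinfde` is for modellers who
want to explore that behavior quantitatively: it treats the order γ ∈
(0, 1) of a Caputo fractional derivative as the statin concentration
indicator, so that drug exposure enters the dynamics as the strength of
the system's power-law memory.

The core pieces:

* **Lipid compartment** — coupled Caputo system for (HDL, Ox, LDL):

  D^γ HDL = s_h β·HDL·LDL,  D^γ Ox = −θβ·HDL·Ox − Ox,
  D^γ LDL = (1−θ)β·LDL + Ox

  with the observable MDA(t) = c·E₁₇₄₄·Ox(t)·LDL(t), E₁₇₄₄ = 4.98
  kcal/mol the molar bond energy of the diagnostic band.
* **Plaque compartment** — arterial wall deformation
  D^γ h = (k₁/A)·h·Ox·M, with the mineralization observable weighted by
  the phosphate band at 976 cm⁻¹ (2.79 kcal/mol).
* **Solver** — fractional Adams–Bashforth–Moulton PECE
  (predict–evaluate–correct–evaluate), validated against Mittag-Leffler
  closed forms E_γ(λt^γ) and reducing exactly to the classical
  Euler/trapezoidal scheme at γ = 1.
* **Dose sweep** — peak response across a γ grid; the toxic reading of
  the dose (1/γ) produces the non-monotonic reversal of the
  dose-response curve, located by a strict decrease-then-increase
  detector.
* **Spectral registry** — the nine characteristic FTIR bands of
  atherosclerotic coronary arteries, with energies E = 2.85914×10⁻³·W
  kcal/mol re-derived from physical constants, plus a Morse
  bond-energy evaluator.

## Worked example

```r
library(statinfde)

# A hyperlipidemic patient (serum LDL:HDL = 160:50 mg/dL) at dose
# indicator gamma = 0.8, under the shipped "paper-qualitative" calibration
sim <- simulate_patient(patient_profile(160, 50), order = 0.8)
sim
#> Lipid peroxidation simulation - profile 160:50 - order 0.8
#>   peak MDA 113.2 at t = 0.42 (interior)

# Dose sweep with the toxic 1/gamma transform enabled: the response
# improves up to the threshold region and then reverses
sw <- gamma_sweep(seq(0.605, 0.795, by = 0.005), transform = TRUE)
sw
#> Dose-response sweep (lipid model): 39 orders in [0.605, 0.795], toxic transform on
#>   reversal at gamma = 0.705

head(band_registry(), 3)
#>   wavenumber_cm1                             assignment energy_kcal_mol
#> 1           1744 Aldehydes (CHO) - peroxidation product            4.98
#> 2           1685              beta-sheet, anti-parallel            4.82
#> 3           1657                    Amide I alpha-helix            4.74
```

The peak MDA value (arbitrary units) is the height of the peroxidation
burst; its time 0.42 is in model time units.  Raising the order (more
statin) lowers that peak and shifts it right — the treatment hysteresis —
until the toxic term takes over just above γ = 0.70 and the dose-response
curve turns back up.

A shell interface wraps the same functions
(`exec/statinfde bands | simulate | sweep | fixtures`, configured by YAML
via `--config`); outputs are CSV trajectories with JSON provenance
sidecars, byte-reproducible apart from a timestamp.

## Layout

* `R/` — spectral registry, Mittag-Leffler evaluator, fractional PECE
  solver, lipid and plaque dynamics, dose sweep, configuration/IO/CLI.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles (closed forms, a directly coded classical scheme).
* `vignettes/fractional-statin-model.Rmd` — the model, its assumptions,
  the shipped calibration and its rationale, numerical conventions, and
  known limitations.
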