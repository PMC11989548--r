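---
title: "Fractional-order modelling of statin dose response: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional-order modelling of statin dose response: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinfde)
```

## The model

Atherogenesis is driven by the peroxidation of low-density lipoprotein
(LDL) under oxidative stress: reactive oxygen species attack
polyunsaturated membrane lipids, and malondialdehyde (MDA) — detectable in
FTIR spectra of arterial tissue through the aldehyde CHO stretch at
1744 cm⁻¹ — is the canonical end product.  High-density lipoprotein (HDL)
plays the protective role.  Statins lower LDL, but their benefit is
dose-dependent and reverses at high dose.

`statinfde` models this with Caputo fractional differential equations.
The Caputo operator of order $\gamma \in (0, 1)$ replaces the local time
derivative with a power-law-weighted memory of all past states, which is
the natural description for a process whose present rate depends on
accumulated biochemical history.  The fractional order itself is read as
the *statin concentration indicator*: the memory strength stands in for
drug exposure.

The lipid compartment solves, for state $(HDL, Ox, LDL)$,

$$D^\gamma HDL = s_h\,\beta\,HDL\cdot LDL,\qquad
  D^\gamma Ox = -\theta\beta\,HDL\cdot Ox - Ox,\qquad
  D^\gamma LDL = (1-\theta)\beta\,LDL + Ox,$$

with $\beta$ the plaque-accumulation rate, $\theta \in [0,1]$ the
oxidative-coupling fraction, and $s_h = -1$ by default so LDL *depletes*
HDL (its protective role).  The sign is exposed as a parameter
(`hdl_sign`) because with $s_h = +1$ HDL would grow with LDL, which
contradicts the protective-role reading; the default is a deliberate
reconstruction and is recorded in every output sidecar.

The observable is the band-energy-weighted product

$$MDA(t) = c \cdot E_{1744} \cdot Ox(t) \cdot LDL(t),
  \qquad E_{1744} = 4.98\ \text{kcal/mol},$$

i.e. oxidative stress acting on its LDL substrate, in arbitrary units.
The definition of the observable is itself a modelling choice: MDA is the
peroxidation product of LDL under oxidative stress, and the bond energy of
the diagnostic band is the stated weighting constant.  Bond energies come
from the FTIR registry (`band_registry()`), where energy is proportional
to wavenumber, $E = N_A h c W = 2.85914\times 10^{-3}\,W$ kcal/mol — the
constant is both hard-coded and re-derived from exact SI constants
(`derive_conversion_factor()`), and the two must agree to six significant
figures.  Anharmonic bond stretching is available through the standard
Morse well $E(r) = D(1 - e^{-a(r-r_0)})^2$ with $a = \sqrt{k/2D}$
(`morse_energy()`).

The plaque (mineralization) compartment reduces a tube-domain deposition
balance to a scalar equation for the arterial wall deformation $h(t)$,

$$D^\gamma h = \frac{k_1}{A}\, h \cdot Ox \cdot M,$$

with $k_1$ the LDL formation rate, $A$ the lesion area and $M$ the
deposited mass.  The spatially resolved intermediate quantities of that
derivation (the plaque field, the progression field, the deposition speed
$u = dh/dt$) are not solved separately; their consistency with the solved
$h$ is checked by `integrate_velocity_check()`, whose finite-difference
residual must vanish linearly with the step.  The mineralization
observable swaps the band weight for the phosphate stretch at 976 cm⁻¹
($E_{976} = 2.79$ kcal/mol): $mineral(t) = c\,E_{976}\,Ox(t)\,h(t)$.

## The solver

`solve_fde()` implements the fractional Adams–Bashforth–Moulton
predictor–corrector (PECE): a product-rectangle (fractional Euler)
predictor with weights $(n{+}1{-}j)^\gamma - (n{-}j)^\gamma$ scaled by
$h^\gamma/\Gamma(\gamma{+}1)$, and a product-trapezoidal corrector with
weights built from $(\cdot)^{\gamma+1}$ differences scaled by
$h^\gamma/\Gamma(\gamma{+}2)$, the right-hand side being re-evaluated at
the corrected value after each step (the terminal E of PECE).  At
$\gamma = 1$ the weights collapse exactly to the classical composite
Euler/trapezoidal coefficients; the test suite checks agreement to
1e−12 against an independently coded classical scheme.  Note the
reduction is to the classical Adams method in *cumulative* (whole-interval
quadrature) form: a stepwise classical implementation differs by
$O(h^3)$ per step because the fractional predictor sums corrected history
values.

Design choices:

* **Uniform grids only**; `t_end/step` must divide evenly (deviations
  below 1e−9 are rounded with a warning).  History sums make the cost
  quadratic in step count; the shipped grids (≤ a few thousand nodes)
  solve in well under a second.
* **Orders in (1, 2]** are supported with a second initial condition
  (`initial_slope`, default zero), because the toxic reading
  $\gamma \to 1/\gamma$ of the dose indicator can push an effective order
  above 1.
* **Determinism**: the solver holds no hidden state; identical problems
  give bit-identical trajectories.
* **Failure reporting**: a non-finite right-hand side aborts with the
  step index; model wrappers attach the patient label.

Validation is against the Mittag-Leffler function
$E_\gamma(z) = \sum_j z^j/\Gamma(\gamma j + 1)$, the exact solution kernel
of linear Caputo problems ($D^\gamma y = \lambda y$,
$y(t) = y_0 E_\gamma(\lambda t^\gamma)$).  `mittag_leffler()` evaluates
the defining series where it is numerically benign (non-negative
arguments; any argument at order ≥ 1 up to the documented magnitude
limits) and the complete-monotonicity spectral integral

$$E_\alpha(-x) = \frac{\sin \alpha\pi}{\alpha\pi}\int_0^\infty
  \frac{e^{-(xu)^{1/\alpha}}}{u^2 + 2u\cos \alpha\pi + 1}\,du$$

for negative arguments at order < 1, where the alternating series is
cancellation-catastrophic.  The two routes are cross-checked against each
other and against the closed form $E_{1/2}(z) = e^{z^2}\mathrm{erfc}(-z)$;
accuracy is better than 1e−10 for $|z| \le 5$.  Empirical convergence of
the solver (`empirical_order()`) reproduces the theoretical PECE order
$\min(2, 1+\gamma)$ on the linear test problem.

## The shipped calibration

No parameter values for $\beta$, $\theta$, the initial conditions or the
observables are published; the defaults are a *calibration* chosen once so
that the qualitative clinical behaviors hold, and are labelled as such.
They are not a reproduction of any measured curve.  The choices:

* Initial lipoproteins are the printed serum profiles divided by 100
  (dimensionless), $Ox(0) = 8$, $\beta = 0.2$, $\theta = 0.7$, horizon
  $t_{end} = 6$ arbitrary time units at step 0.01.  With these, every
  fixture profile shows an interior MDA peak that rises and decays within
  the horizon; peak height is ordered by the LDL:HDL ratio
  (160:50 ≥ 140:50 ≥ 90:60); and raising $\gamma$ lowers the peak and
  shifts it to the right (treatment hysteresis).  The delayed-peak
  direction emerges from the dynamics: at low order the fractional memory
  kernel accelerates the early transient ($t^\gamma$ growth for $t<1$), so
  the peroxidation burst happens earlier and higher, while stronger memory
  (higher $\gamma$, more statin) postpones and flattens it.
* Plaque: $k_1 = 0.3$, $A = M = Ox = 1$, $h_0 = 0.1$.  The growth rate is
  kept small enough that at the fixed horizon a lower order yields less
  accumulated deformation (the mineralization delay), and in coupled mode
  (lipid $Ox(t)$ driving $h$) the mineral observable peaks after the MDA
  peak — organic deposition precedes mineralization.
* Dose sweep: grid default 0.05 on [0.10, 0.95].  The toxic reading of the
  dose is the composite response
  $R(\gamma) = peak(\gamma)\,(1 + c_{tox}\max(0, 1/\gamma_c - 1/\gamma))$
  with $\gamma_c = 0.70$, $c_{tox} = 0.03$.  Nothing computable links
  $1/\gamma$ to the dynamics, so this surrogate is explicit
  reconstruction: monotone improvement below the threshold, reversal just
  above it (at $\gamma = 0.705$ on a 0.005-step grid under the shipped
  calibration).  Setting $c_{tox} = 0$ removes the reversal.  The reversal
  detector (`find_reversal()`) requires a strict increase after a strict
  decrease at a relative tolerance of 1e−9; plateaus do not trigger.

```{r calibration-demo}
profs <- make_fixtures(0)
sapply(profs, function(p) simulate_patient(p, order = 0.8)$peak$peak_value)
gamma_sweep(seq(0.605, 0.795, by = 0.005), transform = TRUE)$reversal_gamma
```

## What the fixtures do and do not emulate

`make_fixtures()` emits the three printed serum profiles (plus the 160:40
variant) and, optionally, seeded ±10% multiplicative jitter around them —
a stand-in for inter-patient variability in a small cohort.  The jitter is
the package's only randomness.  The fixtures do **not** emulate
longitudinal serum measurements, assay noise in MDA quantification, or any
pharmacokinetics of named statin compounds; passing tests therefore show
that the *model* behaves as described under its calibration, not that the
calibration describes any individual patient.

## Numerical and degenerate-input conventions

* Time grids: uniform; the coupled plaque run requires the identical grid
  as the lipid run feeding it (checked, not resampled); within a step the
  driving $Ox$ is interpolated linearly.
* Peak ties break to the earliest time; boundary maxima are flagged
  non-interior.  Monotone observables can be located in time by
  `half_rise_time()` instead.
* $k_1 = 0$ (no formation), $Ox(0) = 0$ (no oxidation source) and a zero
  right-hand side are all exact: the solution is constant to the last bit.
* Configuration is YAML over explicit defaults; unknown keys are rejected
  by name.  Therapeutic lipid runs require order ≤ 1; orders in (1, 2] are
  admitted only with the toxic transform enabled.
* Outputs are CSV plus a JSON sidecar carrying the full parameter echo, a
  canonical configuration hash, and a note for every reconstructed choice
  in effect; reruns are byte-identical apart from the sidecar timestamp.

## Known limitations

* The quadratic-cost history sum is unaccelerated (no FFT convolution);
  grids beyond ~1e5 nodes become slow.
* The toxic-reversal location depends on the surrogate constants; only its
  existence, its threshold behavior and its approximate location are
  asserted, and the constants are part of the shipped calibration.
* Time is in arbitrary model units; no mapping to days or to mg doses of
  specific statins is attempted.
* Only the Caputo operator is implemented (initial conditions in ordinary
  derivatives); there is no Riemann–Liouville variant, no adaptive
  stepping, and no spatially resolved plaque field.
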