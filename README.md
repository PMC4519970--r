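# lumifret

Förster-theory and time-gated luminescence analysis for lanthanide FRET
biosensors.

## The problem

Protease biosensors built from a Tb³⁺/terbium-binding-peptide donor and a
fluorescent-protein acceptor, joined by a cleavable linker, report enzyme
activity as a loss of FRET. Their analysis mixes several calculations that
are usually scattered across notebooks and vendor software:

* **Förster theory over conformational ensembles.** With quantum yield
  `Q_D = tau_D / tau_DR`, orientation factor `kappa² = 2/3`, refractive
  index `n`, and overlap integral
  `J = ∫ F_D(λ) ε_A(λ) λ⁴ dλ` (M⁻¹ cm⁻¹ nm⁴), the Förster radius is
  `R0⁶ = 9000 ln10 κ² Q_D J / (128 π⁵ N_A n⁴)`, and each donor–acceptor
  distance `r` maps to a rate `k_T = (1/τ_D)(R0/r)⁶`, an efficiency
  `E = k_T/(τ_D⁻¹ + k_T)` and a quenched lifetime `τ_DA = τ_D (1 − E)`.
  `lumifret` applies these per frame over a distance ensemble and returns
  weighted means, histograms and cumulative curves.
* **Time-gated detection.** A delay `t_d` and gate `g` integrate each decay
  component to `A τ (e^(−t_d/τ) − e^(−(t_d+g)/τ))` in closed form; a 100 µs
  delay removes nanosecond prompt fluorescence (< 10⁻¹⁰ of its yield)
  while keeping most of the millisecond sensitized emission.
* **Spectral processing.** Reabsorption (inner-filter) correction
  `I_corr = I · 10^(D/2)`, photobleach-control subtraction with clamp
  accounting, and overlap-integral quadrature.
* **Binding analysis.** Constrained nonlinear least-squares fits of
  `I = Imax·[Tb]/(Kd + [Tb])` with bootstrap intervals, plus the
  tangent-intersection estimate of the saturating concentration.

Seeded synthetic-data generators (freely jointed / worm-like chain linker
distances, Gaussian line/band spectra with closed-form overlap integrals,
noisy titrations, multi-exponential decays) stand in for the trajectory and
the instrument, so the full pipeline is testable end to end.

## Worked example

```r
library(lumifret)

# photophysics of a Tb3+ -> red-FP sensor
p <- fret_parameters(J = 3.22591e15, tau_D = 0.33, tau_DR = 3.5)
p
#> FRET parameters: Q_D = 0.09429, kappa2 = 0.6667, n = 1.4,
#>   J = 3.22591e+15 M^-1 cm^-1 nm^4, tau_D = 0.33 ms, R0 = 4.084 nm

# a noisy titration and its fit
s <- synth_titration(titration_design(noise_sd = 4.75, seed = 11))
fit_binding(s, seed = 2)
#> One-site binding fit:
#>   Kd   = 17.8 +/- 4.1 uM   (95% CI 12.2-27.3)
#>   Imax = 94.7 +/- 9 a.u. (95% CI 81.7-114)
#>   residual sd = 4.79; saturation (tangent intersection) = 13.2 uM

# the whole chain in one call
run_demo(pipeline_config(seed = 11), n_boot = 200)
#> End-to-end sensor demo
#>   donor quantum yield  Q_D      = 0.0943
#>   Foerster radius      R0       = 4.08 nm
#>   ensemble mean E               = 0.986 (tau_DA = 0.00462 ms)
#>   identity check: tau_D(1-E)    = 0.00462 ms
#>   binding fit          Kd       = 16.2 +/- 4 uM (true 17)
#>                        Imax     = 92 +/- 9 a.u. (true 95)
#>   saturation (tangents)         = 12.8 uM
```

Reading the demo: the quantum yield is the lifetime ratio 0.33/3.5; the
Förster radius follows from the parameter set; the ensemble means come from
20,000 freely-jointed-chain linker conformations (a compact chain, hence
the high transfer efficiency — see the methods vignette for what the chain
model does and does not emulate); and the binding fit recovers the
generating `Kd = 17 µM` / `Imax = 95 a.u.` from a simulated gated
titration within its noise-limited uncertainty. The quoted `tau_D(1-E)`
line surfaces the exact linear identity linking mean efficiency and mean
quenched lifetime.

The methods vignette (`vignettes/lumifret-methods.Rmd`) documents the
models, unit conventions, defaults and their rationale, and the
limitations of the synthetic generators.

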