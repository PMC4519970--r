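---
title: "Models and methods behind lumifret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lumifret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumifret)
```

## The system and the problem

`lumifret` analyses lanthanide-based FRET biosensors in which a Tb³⁺ ion,
chelated by a terbium-binding peptide and sensitized through a tryptophan
antenna, acts as a millisecond-lived donor, and a red fluorescent protein
chromophore acts as the acceptor. The two are joined by a flexible
19-residue linker carrying a caspase-3 cleavage motif, so loss of FRET
reports protease activity. Because the donor decays on the millisecond scale
while directly excited acceptor fluorescence and cellular autofluorescence
decay within nanoseconds, pulsed excitation plus a delayed detection gate
isolates the sensitized acceptor emission essentially background-free.

The package implements four connected pieces: (1) Förster theory over
conformational distance ensembles; (2) spectral processing (overlap
integral, reabsorption correction, photobleach subtraction); (3) time-gated
detection of multi-exponential decays and the sensitized-acceptor
reconstruction pipeline; (4) hyperbolic saturation-binding fits. A fifth
piece, the synthetic-data generators, emulates every input so the whole
chain is testable without instrument data.

## Förster theory core

For a donor–acceptor separation $r$ the transfer rate is

$$k_T(r) = \frac{1}{\tau_D}\left(\frac{R_0}{r}\right)^6, \qquad
R_0^6 = \frac{9000\,\ln 10}{128\,\pi^5 N_A n^4}\,\kappa^2\,Q_D\,J,$$

with efficiency $E = k_T/(\tau_D^{-1}+k_T)$ and quenched donor lifetime
$\tau_{DA} = \tau_D(1-E)$. `forster_radius()` evaluates the constant
exactly in CGS units ($N_A = 6.02214076\times 10^{23}$; $J$ converted from
M⁻¹ cm⁻¹ nm⁴). The familiar Ångström-unit shortcut constant
$8.79\times10^{-5}$ is a rounded form of the exact
$8.78513\times10^{-5}$; the package keeps the exact route as the
implementation and exposes `rate_constant_explicit()` so the unit
bookkeeping of the two algebraically equivalent routes can be
cross-checked numerically (they agree to better than $10^{-6}$ relative).

Default parameters, all overridable: $\tau_D = 0.33$ ms and
$\tau_{D,R} = 3.5$ ms, giving $Q_D = \tau_D/\tau_{D,R} = 0.094$;
$J = 3.22591\times10^{15}$ M⁻¹ cm⁻¹ nm⁴; $\kappa^2 = 2/3$, appropriate for
a freely rotating pair (per-frame orientational dynamics are out of scope).
The refractive index is not part of the sensor's published characterisation;
we default to $n = 1.4$, the common protein-FRET convention. The choice
matters at the few-percent level: moving from $n = 1.4$ to $n = 1.33$
shifts $R_0$ up by about 3.5% (the $n^{-4/6}$ dependence), which users can
probe by passing their own `n` to `fret_parameters()`. With the defaults,
$R_0 = 4.08$ nm.

`ensemble_fret()` applies these maps frame-by-frame to a
`distance_ensemble` (imported from a trajectory via
`read_distance_series()` or sampled, below), with optional per-frame
weights (uniform by default — no reweighting scheme is implied by the
physics). Weighted means obey $\overline{\tau_{DA}} =
\tau_D(1-\overline{E})$ *exactly*, by linearity; the test suite asserts
this to machine precision. In particular any ensemble whose mean efficiency
is 0.43 necessarily has a mean quenched lifetime of
$0.33\times0.57 = 0.1881 \approx 0.19$ ms. Histograms use Freedman–Diaconis
bins by default (`bin_width` overrides); cumulative curves come from the
weighted empirical distribution, not the histogram, so they are exact and
nondecreasing from 0 to 1.

## Spectral processing

`overlap_integral()` computes
$J = \int F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,d\lambda$ with
the donor emission area-normalised on the shared grid, trapezoidal
quadrature, and linear interpolation onto a common grid (1 nm default —
typical fluorimeter sampling). This is the only convention consistent with
reporting $J$ in M⁻¹ cm⁻¹ nm⁴. No integration limits are imposed beyond
the spectra's shared support, and the range actually integrated is reported
alongside $J$. Halving the step changes $J$ by well under 0.1% for bands
resolved by ten or more points (asserted in the tests).

Reabsorption correction uses $I_{corr}(\lambda) = I(\lambda)\,
10^{D(\lambda)/2}$, per wavelength, the half path-length factor
corresponding to emission from the centre of the cuvette. Photobleach
subtraction is a pointwise difference on the common grid; negative
residuals are physically meaningless noise artifacts, so they are clamped
to zero but *counted* (attribute `n_clamped`) so that a pathological
subtraction remains visible.

## Time-gated detection and the reconstruction pipeline

A detection gate with delay $t_d$ and width $g$ integrates an exponential
component $A e^{-t/\tau}$ to $A\tau(e^{-t_d/\tau} - e^{-(t_d+g)/\tau})$,
in closed form (`gated_intensity()`), summing linearly over components.
With the default 100 µs delay, a 3 ns prompt component retains less than
$10^{-10}$ of its photon yield — the quantitative basis for treating
directly excited acceptor fluorescence as absent. The sensitized acceptor
emission is modelled with the quenched-donor lifetime (≈0.19 ms), since
energy transfer makes the acceptor inherit the donor's slow decay; the
acceptor's intrinsic nanosecond decay is folded into the prompt component.
The excitation pulse is treated as a delta at $t=0$.

`reconstruct_sensitized_series()` reproduces the measurement chain: correct
the intact sample's spectrum for reabsorption, *then* subtract the
photobleached control, then read the intensity at the read-out wavelength
(606 nm default, linear interpolation). The order matters and is fixed:
the correction applies to the non-bleached sample only, because only its
chromophore still absorbs. For the same reason the synthetic forward model
(`simulate_gated_titration()`) attenuates only the intact sample's spectrum
by $10^{-D/2}$ and gives the bleached control the same donor lines
unattenuated — which makes the reconstruction exactly invertible and lets
the end-to-end round trip (simulate → reconstruct → fit) be tested against
the generating parameters. The shared `absorbance` spectrum is
concentration-independent (the protein, not the titrant, absorbs); the
reconstruction also accepts a per-concentration list where per-point
absorbances were recorded.

## Binding isotherm fitting

`fit_binding()` fits $I = I_{max}[L]/(K_d + [L])$ by constrained
Levenberg–Marquardt least squares: positivity bounds, initialisation
$I_{max,0} = \max I$ and $K_{d,0}$ at the concentration nearest
half-maximum, convergence tolerance $10^{-12}$ on both step and gradient,
500 iterations maximum. Free-ligand depletion by the protein is ignored
(free ≈ total), the same simplification the isotherm itself makes; at
protein concentrations comparable to $K_d$ this biases $K_d$ upward, a
known limitation. Standard errors come from the local linearisation;
95% intervals from a seeded residual bootstrap (percentile method,
1000 replicates by default) or Wald intervals when `n_boot = 0`.
Uncertainties are quoted as estimate ± SE. The fit warns when the
concentration grid does not bracket the fitted $K_d$ (no point below it,
or none beyond twice it).

`saturation_by_tangents()` implements the graphical "intersection of
tangents" estimate of the saturating concentration as an empirical secant
construction: OLS lines through the first and last `k_points` of the fitted
curve over the measured grid. The analytic tangent-at-origin/plateau pair
intersects exactly at $K_d$; secants through a still-rising tail land
elsewhere (around 13 µM on the default design), and graphical estimates of
this kind reported for real sensors (e.g. ≈24 µM) depend strongly on which
points are declared "linear". The estimate is therefore *reported* for
comparability, never asserted against, and `k_points` is exposed.

## Synthetic-data generators

The generators define the study conditions for every test:

* **Linker distances.** The 19-residue linker is coarse-grained to 19
  virtual Cα–Cα bonds of 0.38 nm (standard polypeptide geometry).
  `sample_linker_distances()` draws end-to-end distances from a freely
  jointed chain (exact $\langle r^2\rangle = Nb^2 = 2.744$ nm²) or a
  discretised worm-like chain (successive bond directions correlated with
  $\langle\cos\theta\rangle = e^{-b/l_p}$, bends drawn from the equilibrium
  Kratky–Porod density). Fixed `end_offsets` added along the end-to-end
  direction express donor-ion and chromophore positions beyond the linker
  termini, since which atoms define the "distance" in a trajectory is a
  user convention. The FJC at these defaults is compact relative to
  $R_0 = 4.08$ nm and therefore transfers almost completely
  ($E \approx 0.99$); reproducing an all-atom trajectory's particular
  distance distribution (and hence its mean $E \approx 0.43$) is a
  calibration exercise for the offsets and stiffness, not something the
  desk-scale sampler claims. What the tests *do* establish is exact moment
  agreement with chain theory, the contour-length bound, and the
  efficiency–lifetime identities for any ensemble whatsoever.
* **Spectra.** Gaussian lines/bands chosen so every overlap integral has a
  closed form (testability over spectroscopic realism): Tb³⁺ lines at
  490/545/585/620 nm (σ = 4 nm), acceptor extinction/absorbance band at
  555 nm (σ = 18 nm, peak $10^5$ M⁻¹ cm⁻¹), acceptor emission at 584 nm
  (σ = 16 nm). Real spectra have vibronic asymmetry and baselines that
  these bands do not emulate; passing tests demonstrate correct quadrature
  and plumbing, not band-shape fidelity.
* **Titrations.** The isotherm forward model on a 12-point grid spanning
  1–50 µM (the measured range of the sensor's titration; a realistic
  fluorimetric design with denser sampling below $2K_d$), true
  $K_d = 17$ µM, $I_{max} = 95$ a.u., Gaussian noise (analog fluorimeter)
  with negative draws clamped at zero; Poisson noise is available for the
  decay generator (photon counting). All stochastic generators take an
  explicit seed, restore the caller's RNG state, and are bit-reproducible.

## Numerical choices and degenerate inputs

Trapezoidal quadrature and linear interpolation throughout; no
extrapolation outside a spectrum's support, ever. Duplicate wavelengths,
nonpositive distances, negative optical densities, zero-area donors,
disjoint spectral supports, all-zero titrations, and unphysical lifetime
orderings ($\tau_D > \tau_{D,R}$) are rejected with specific errors rather
than propagated. Rates are ms⁻¹ and donor lifetimes ms throughout the
Förster module; gate times and decay lifetimes are µs in the gated module
(0.003 µs = 3 ns prompt; 190 µs sensitized emission); the conversion
constants live in one place.

## Problem sizes used by the packaged checks

The test-suite replicate experiments use 200 noisy titration fits (and a
50-replicate spectral round trip) for median-recovery checks, a
50 × 300 residual-bootstrap experiment for interval coverage, and $10^5$
chain samples for moment checks — sizes at which the binomial/Monte-Carlo
noise of each check is several times smaller than the tolerance it asserts.

## Known limitations

No instrument response deconvolution, baseline correction, smoothing, or
vendor file formats; no Hill/multi-site binding; no per-frame orientation
factors; no trajectory-file readers (distances are imported as plain text).
The ensemble statistics are only as representative as the distance ensemble
supplied.
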