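---
title: "Models and methods behind micellab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind micellab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micellab)
```

micellab quantifies the self-assembly of chaperone proteins into equilibrium
micelles from three orthogonal measurements: single-particle mass photometry
(particle masses), sedimentation-velocity analytical ultracentrifugation
(sedimentation coefficients), and microfluidic diffusional sizing (mean
hydrodynamic radii over time). This vignette explains the models the package
implements, the defaults and why they were chosen, what the synthetic-data
generator does and does not emulate, and the numerical choices that matter.

## The population model

A micelle-forming protein above its critical micelle concentration (cmc)
maintains a free monomer pool at roughly the cmc while the excess subunit
mass lives in micelles of many coexisting sizes. The generative truth object
(`MicellePopulation`) stores number concentrations $C_N$ per aggregation
number $N$, constrained by exact subunit mass balance:

$$c_{mono} + \sum_N N\,C_N = c_{total}.$$

No closed-form size-distribution law is established for protein micelles, so
the package uses the simplest shape consistent with the observed phenomenology
— a *discretized Gaussian in N*, truncated below $N_{min} = 5$ (small
aggregation numbers are unstable because they cannot bury their hydrophobic
surface) and renormalized. The pH 4 preset is a two-Gaussian mixture, since
the measured distribution at that pH is bimodal.

Key defaults of `populationParams()`:

* `cmc = 0.12` uM and `monomerMass = 26.9` kDa — the measured cmc and subunit
  mass of the DNAJB6b-type chaperone the model emulates.
* `meanNRef = 20`, `concExponent = log10(2)/2` — for the near-neutral presets
  the number-weighted mean follows
  $\mu_N = 20\,(c_{total}/1\,\mu M)^{0.1505}$, the power law that doubles
  $\mu_N$ (20 to 40) between 1 and 100 uM, as observed. The exponent is a
  modeling choice; the data constrain only the factor-of-two endpoint.
* `relativeWidth = 0.30` — $\sigma_N = 0.3\,\mu_N$ reproduces both the "broad
  maximum" character of the distribution and a mass-weighted mean
  $\langle N\rangle \approx \mu_N(1 + 0.3^2) \approx 35$ at 30 uM.
* pH presets: pH 2-3 fixed $(\mu_N, \sigma_N) = (10, 2)$ with water fraction
  0.90; pH 4 bimodal (main mode $(10,2)$ plus 15 % of the number weight at
  $(40,8)$) with water fraction 0.88; pH 5-8 the concentration-dependent law
  with water fraction 0.65. The water fractions per regime follow the
  hydration values inferred from packing densities; the 15 % minor-mode
  weight at pH 4 is a free choice (only "a small peak" is observed).

Number- versus mass-weighting matters throughout: absorbance-detected
sedimentation data are mass-weighted, single-particle counting is
number-weighted. `toMassWeighted()` converts by multiplying bin counts by
$N$; for any population the number-weighted mean never exceeds the
mass-weighted mean.

## Simulated measurements

`sampleMPEvents()` draws each landing event's true $N$ with probability
proportional to *number* concentration (the monomer pool included), then adds
Gaussian mass noise with the affine model $\sigma(m) = 9 + 0.02\,m$ kDa. The
single printed anchor for this model is the width of a 669 kDa standard's
peak, FWHM $= 2.355\,\sigma = 52$ kDa, i.e. $\sigma(669) \approx 22$ kDa; the
affine form is the simplest extrapolation across the mass range and its two
coefficients split the width into a floor and a proportional part. An
optional, off-by-default bias hook adds $12\,e^{-(m-20)/10}$ kDa below
40 kDa, reproducing the direction (overestimation) of the known low-mass
calibration artifact — qualitative only.

`forwardAUC()` maps a population to a sedimentation distribution: each
N-mer's radius comes from the packing model (below), its $s$ from the
Svedberg equation, its amplitude from $N C_N$ (mass weighting), and each
species is smeared with a 5 % relative-width Gaussian in $s$, a typical
resolution for finite-element sedimentation analysis. The free monomer enters
with a folded-protein radius of 3.3 nm rather than the micellar packing
model.

`simulateDissociation()` generates $\langle R_H\rangle(t) = a e^{-k(T)t} + c$
with $k(T)$ from the Arrhenius law through (`kRef`, `tRef`) and additive
Gaussian noise of 0.3 nm per point — the scale of replicate scatter in
diffusional-sizing data. Defaults: $E_a = 250$ kJ/mol and
$k_{ref} = 1/(20\ \mathrm{min})$ at 310.15 K (the fitted barrier and the
37 °C dissociation time scale), plateaus 4.5 nm at 22 °C and 3.3 nm at 40 °C
and amplitudes 5.0-5.7 nm, linearly interpolated in temperature between those
anchors (plateaus and starting radii are printed at the interval endpoints
only). Time grids span five decay times in 25 points.

What the generator does **not** emulate: optical contrast physics (events are
generated in mass units; a linear contrast layer exists solely to exercise
the calibration chain), landing-rate/surface kinetics, Lamm-equation
sedimentation dynamics, micellization thermodynamics (the size distribution
is imposed, not derived from a free-energy model), and instrument drift.
Passing tests therefore validate the analysis chain's correctness and
statistical behaviour, not these physical effects in real data.

## Hydrodynamics and the fusion procedure

The Svedberg equation for an equivalent sphere,

$$s = \frac{m_p\,(1 - \rho_w/\rho_p)}{6\pi\eta R_H},$$

uses $\rho_p = 1.39$ g/ml and $\rho_w = 1.00$ g/ml by default (both
configurable). Water viscosity comes from a 4-40 °C table at 1 °C resolution
(generated from the standard log-ratio correlation anchored at
$\eta(20°C) = 1.002$ mPa s) with linear interpolation; water density from
Kell's polynomial. Temperature correction to $s_{20,w}$ applies both the
viscosity ratio and the buoyancy-density ratio; a `viscosityOnly` flag
provides the viscosity-only variant since published corrections sometimes
omit the (small) density factor. Distributions store their raw $s$ values
with the measurement temperature, and correction is an explicit, flagged
step — provenance stays auditable.

**Fusion.** The mass histogram and the sedimentation distribution describe
the same sample in different coordinates. No standard algorithm exists for
aligning them, so the package uses monotone *quantile matching*: both
mass-weighted distributions are normalized to cumulative weight 1, and each
sedimentation bin is paired with the mass at the equal cumulative quantile
(piecewise-linear inversion of the mass CDF within bins; flat runs from
empty bins are collapsed so the inverse is single-valued). This choice is
parameter-free, order-preserving (larger mass pairs with larger $s$ by
construction) and degenerate-safe; it assumes both weightings are strictly
comparable, which is why the contracts demand mass weighting and an
$s_{20,w}$-corrected input. Sedimentation bins carrying $< 10^{-4}$ of the
total weight are dropped — the quantile map is ill-conditioned in the far
tails.

From each fused (mass, $s$) pair, the Svedberg inversion gives $R_H$, the
packing density follows as $m_p / (\tfrac{4}{3}\pi R_H^3)$, and the water
mass fraction as

$$f = \frac{\rho_w(1/d - 1/\rho_p)}{\rho_w(1/d - 1/\rho_p) + 1},$$

the exact inverse of the generator's packing model (volume = anhydrous
protein volume + water volume), so the closed-loop identity
`waterMassFraction(packingDensity(m, packingRadius(m, f))) == f` holds to
numerical precision.

## Kinetics

`fitDecay()` performs weighted nonlinear least squares of
$y(t) = a e^{-kt} + c$ with deterministic initialization ($c_0$ = last value,
$a_0$ = first − last, $k_0 = 1/\mathrm{span}$) and a fixed three-point
multi-start grid on $k_0$ ($\times 0.3, 1, 3$) — no randomness in fitting.
Inverse-variance weights are used when per-point standard deviations are
supplied. A series whose value range is below three times its median
standard deviation carries no rate information and is returned as the
degenerate fit $(a, k) = (0, 0)$ with a flag, rather than an unstable
estimate. `fitArrhenius()` is plain OLS of $\ln k$ on $1/T$
($E_a = -\mathrm{slope}\cdot R$); errors-in-variables corrections are
deliberately omitted, matching how Arrhenius plots are conventionally
evaluated, and rate constants from different reporters (hydrodynamic radius,
oligomer-mass) can be pooled via their source tags.

## Solution chemistry

Net charge uses the Henderson–Hasselbalch sum over ionizable groups with a
model-compound pKa set (D 3.5, E 4.2, C 6.8, Y 10.3, H 6.6, K 10.5, R 12.0,
N-term 8.0, C-term 3.3). The set is an explicit, swappable, provenance-
labeled input because predicted charges (e.g. the pH at which a given
protein reaches +40) depend mildly on the chosen table; structure-based pKa
shifts are out of scope. The packaged FASTA
(`inst/extdata/jb6b_synthetic.fasta`) is a **synthetic stand-in**: a
241-residue sequence whose ionizable-residue composition reproduces the
charge profile of the DNAJB6b-type chaperone (≈ +40 at pH 2, weakly negative
at pH 8). It is not the real sequence, which is deliberately not embedded —
real analyses should supply their protein's FASTA.

Phosphate speciation uses pKa 2.15/7.21/12.33 (only pKa2 matters near
pH 8), sodium by electroneutrality, and $I = \tfrac12\sum c_i z_i^2$; the
Debye length is computed from fundamental constants rather than the
$0.304/\sqrt{I}$ nm shortcut, which serves as an independent oracle in the
tests. dn/dc is an ordinary least-squares slope.

## Numerical and testing choices

* Units are fixed package-wide (uM, kDa, nm, Svedbergs, kJ/mol) with all
  conversions in one constants table; the FWHM constant is 2.355 as
  conventionally printed (not $2\sqrt{2\ln 2}$ at higher precision;
  difference < 0.02 %).
* Histograms anchor bin centers at integer multiples of the bin width, so
  with the default monomer-mass bins the $N$ assignment is exact for
  noiseless data.
* One global seed expands into per-stage substreams by stage name
  (`stageSeed`), so toggling pipeline stages does not shift other stages'
  randomness; identical configuration and seed give bit-identical outputs.
* Test problem sizes: $10^4$ events for histogram statistics, $2\times10^4$
  noiseless events for fusion recovery, 21 decay series (7 temperatures ×
  3 replicates) for barrier recovery, 200 random draws for the
  rate-recovery property — sizes at which the stochastic checks are stable
  at their stated tolerances while the whole suite runs in seconds.

## Known limitations

* The equivalent-sphere assumption ignores shape and frictional-ratio
  effects; densities and water fractions inherit that approximation.
* Quantile fusion assumes both distributions sample the same underlying
  population with compatible weighting; systematic inter-technique biases
  (e.g. mass-dependent detection efficiency) would propagate into $R_H$.
* The sub-40 kDa regime of mass photometry is flagged, not corrected — no
  correction model for the low-mass nonlinearity is provided, only the
  `validMassMin` boundary and event flags.
* The single-exponential model presumes one rate-limiting dissociation
  step; multi-step mechanisms (stepwise monomer loss chains) are out of
  scope.
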