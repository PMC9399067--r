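---
title: "Cellular dosimetry and radiobiology with celldosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular dosimetry and radiobiology with celldosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldosim)
```

## The problem

When prostate-cancer cells are incubated with an alpha-emitting
([^225^Ac]Ac-PSMA) or beta-emitting ([^177^Lu]Lu-PSMA) radioligand, the
biologically relevant quantity is the absorbed dose to the cell nucleus,
not the activity concentration in the medium. `celldosim` implements the
full computational chain from bench measurements to nucleus dose and
relative biological effectiveness (RBE): decay-chain physics, cellular
S values, uptake/clearance kinetics, MIRD-scheme dose accumulation,
clonogenic dose-response fitting, and DNA-damage (53BP1) focus counting.
A seeded synthetic-data module generates every input the pipeline
consumes, so each stage has an end-to-end recovery test.

This vignette records the model assumptions, the tunable parameters with
their defaults and units, the numerical choices, and the limits of what
the synthetic tests demonstrate.

## Decay data and Bateman activities

Nuclear data are embedded constants from a standard evaluated
compilation: half-lives, mean emission energies (MeV) and yields per
decay for Lu-177 (half-life 6.647 d) and the Ac-225 cascade (9.92 d;
Ac-225 → Fr-221 → At-217 → Bi-213 → 97.8% Po-213 / 2.2% Tl-209 → Pb-209
→ stable Bi-209). The cascade carries exactly four alpha emissions per
parent decay (≈27.5 MeV) when weighted over the Bi-213 branch.
Conversion and Auger electrons are lumped per nuclide; beta emissions
carry both a mean energy (used for all energy bookkeeping) and an
endpoint energy (used only by the transport engine, below). Photons are
tracked in the tables but never transported: at cellular dimensions
their interaction probability is negligible.

Activities follow the closed-form Bateman solution with branching,
decomposed over linear paths. Near-degenerate decay constants are nudged
apart by one part in 10^9^ to keep the alternating coefficient sums
well-conditioned; values at `t = 0` are set exactly to the initial
condition, and magnitudes below 10^-12^ of the largest activity are
truncated to zero to remove cancellation residue. The test suite holds
the solution against an independent stiff ODE integration (`deSolve`,
relative tolerance 10^-12^) to better than 10^-6^ relative error over
ten days — a demanding check given the 10^10^ spread of decay constants
(At-217 lives 32 ms, Ac-225 ten days).

A practical consequence of the two-step Bateman solution: Fr-221, the
gamma-counting surrogate for Ac-225, reaches 98% of its equilibrium
activity ratio after about 27 minutes, which is why samples rest at
least 30 minutes before counting.

## Cell geometry

Two set-ups are modelled. During the radioactive incubation the cells
are in suspension and spherical: nucleus radius `R_N` concentric in a
cell of radius `R_C`, plus a 7.5-nm bound-membrane shell. During colony
growth the cells are attached and ellipsoidal: nucleus semi-axes
`(a, b, h/2)` with the height `h` restricted to 3, 4 or 5 µm, inside a
cytoplasm ellipsoid sharing the `a/b` ratio and preserving the
floating-cell volume.

The exact cell dimensions behind the study are not published in
machine-readable form, so the defaults are explicit, documented
assumptions (`default_cell_geometry()`, fully overridable): floating
`R_C` = 7, 8.7, 10 µm for the minimum/average/maximum classes (the
average reproduces the ~0.027% suspension occupancy of 100,000 cells in
1 mL), nucleus `a = b` chosen so the volume-equivalent nucleus radii are
3, 4, 5 µm. For the attached model the cytoplasm height is fixed at the
nucleus height plus a 0.5-µm margin — a flat adherent morphology — and
the in-plane semi-axes are solved to preserve the floating volume
exactly. An optional basal nucleus offset exists for sensitivity
studies; it is off by default.

Cell radii can also be measured from brightfield images with the
bundled Hough circle transform (`detect_circle_radii()`): Sobel edge
extraction, ring-kernel accumulation over a radius sweep, greedy peak
picking with non-maximum suppression at 1.2× radius, and parabolic
radius refinement. Intensities are range-normalized first, so detection
is invariant to affine intensity rescaling; on synthetic fields of 100
cells the radius error stays below one pixel.

## The S-value engine

S values (absorbed dose rate to the nucleus per unit activity,
Gy·(Bq·s)⁻¹) are computed with a deliberately desk-scale transport
model rather than a general-purpose Monte Carlo code:

* **Alphas** travel on straight chords and deposit energy by the
  continuous-slowing-down approximation. The range–energy relation is a
  Bragg–Kleeman power law `R(E) = 2.768 E^1.611` µm anchored to
  evaluated liquid-water CSDA ranges (47 µm at 5.8 MeV, 85 µm at
  8.4 MeV). No straggling, no delta rays: sub-percent effects at these
  geometries.
* **Electrons** (mean-beta, conversion, Auger) use Cole's empirical
  range–energy relation `R = 0.0431 (E_keV + 0.367)^1.77 − 0.007` µm
  along straight chords — the classical basis of analytic cellular
  S-value models, and the package's choice over a radially scaled
  point-kernel formulation because it shares the chord machinery with
  the alpha transport at equal accuracy for these source–target
  distances.
* **Beta spectra are sampled, not collapsed to the mean.** Transporting
  the mean beta energy concentrates all energy at exactly one CSDA
  range, which distorts both the near-source dose (too little from the
  missing low-energy, high-LET part of the spectrum) and the
  100–500 µm cross dose (an artificial end-of-range pile-up). The
  engine draws beta energies from a scaled Beta(1, b) distribution on
  `[0, Q]` whose mean matches the evaluated mean energy — a
  flat-at-zero density mirroring the Coulomb-enhanced low-energy shape
  of beta-minus spectra. Energy bookkeeping (e.g. the medium S value)
  still uses the evaluated means.

All chain members are simulated at equilibrium and co-located with the
parent (no daughter relocation). Sources are sampled uniformly in the
membrane shell or the cytoplasm (or on the cytoplasm surface for
attached cells) with isotropic directions; the dose is the deposited
energy divided by the nucleus mass at unit density. Default statistics
mirror usual practice: 10^6^ histories for electron-only chains, 10^5^
for alpha chains, targeting a relative MC error below 0.5% (a warning
flags unconverged runs). Fixed seeds make every run bit-reproducible.

The **medium source** is analytic: charged-particle ranges (< 1 mm) are
small against the 1-mL medium, so the nucleus receives the medium's
equilibrium dose, `S = E_charged × 1.602·10⁻¹³ / m_medium`. This
reproduces the reference values 2.30·10⁻¹¹ (Lu-177) and 4.57·10⁻⁹
(Ac-225) Gy·(Bq·s)⁻¹ within 3%.

The **cross dose** from neighbouring cells in suspension uses the
published lattice configuration: spheres of `R_C` = 8 µm, `R_N` = 4 µm
at 0.027% occupancy in a 500-µm cube (16 cells). Each neighbour carries
1 Bq distributed over its cell volume; directions are
importance-sampled in the cone subtending the central nucleus, and the
result is averaged over random placements (the estimator's variance is
dominated by the nearest-neighbour distance, hence the default of
several hundred placements). The Lu-177 value converges to ≈1.35·10⁻⁶
Gy·(Bq·s)⁻¹, within 20% of the reference 1.13·10⁻⁶; the Ac-225 cross
dose is orders of magnitude below its self dose, consistent with
neglecting it.

**Accuracy envelope.** Against the bundled reference S values (a full
Geant4-based simulation of the same assay), the engine agrees within
±25% for all floating-geometry cells (alpha chains within ±23%). The
attached set-up is less settled: the reference shows membrane sources
delivering *more* dose than cytoplasm sources (the reverse of the
floating pattern), which no volume-preserving ellipsoid configuration
we scanned reproduces simultaneously with the cytoplasm column —
attached membrane values sit ~45% low and the maximum-size cytoplasm
~50% high. Because the true attached-cell dimensions are unpublished,
the package treats this as a geometry-assumption gap: the bundled
reference table (`reference_svalues()`) is the default input for dose
accumulation, and the engine is the validated alternative
(`svalue_source = "engine"`).

## Kinetics and time-integrated activity

Uptake is instant and constant during the 3-h incubation: the bound
activity per cell is `A_cell = c · V · (u/100) / 10⁵` with `u` = 1.87
%AA per 100,000 cells (the average of the 1-h and 3-h measurements,
shared by both radioligands, which bind indistinguishably). The bound
activity splits between membrane and cytoplasm at a fixed
membrane-to-internalized ratio of 0.76 (fractions 0.432/0.568).

After incubation the cells retain
`r(t) = p + (1 − p)·exp(−ln 2 · t/T_bio)` with defaults `p` = 0.41 and
`T_bio` = 2.3 h, fitted from excretion series by Levenberg–Marquardt
least squares (`fit_clearance()`; a flat series is returned flagged
rather than fitted, and fits converging outside the physical domain
raise an error). The plateau is extrapolated over the full 7-day colony
window — the measured series ends at 120 h, so this is an explicit
modelling choice.

The time-integrated activity has the closed form
`Ã = A₀·[(1 − p)(1 − e^{−(λp+λb)T})/(λp+λb) + p(1 − e^{−λp T})/λp]`,
with zero-rate limits handled exactly; tests hold it against adaptive
quadrature to 10⁻⁸ relative error over a parameter grid. Time is
seconds internally; interfaces take hours.

## MIRD dose accumulation

Per concentration and size class the absorbed dose to the nucleus is
the sum of: membrane and cytoplasm self-dose during incubation
(floating S values), the medium contribution (incubation only), the
cross dose (Lu-177, incubation only — the alpha cross dose is
negligible and colony-phase cells are too sparse), and membrane and
cytoplasm self-dose during the 168-h colony phase (attached S values,
clearance applied). The geometry switch is instantaneous at the end of
incubation.

The structure of the resulting table is exact by construction and
verified to machine precision: doses are linear in concentration (the
0.5/0.1 MBq/mL ratio is exactly 5), size-class columns are proportional
across concentrations, and the total equals the component sum. Absolute
totals computed from the printed kinetic inputs land at 0.70× (Lu-177)
and 1.28× (Ac-225) of the published 7-day totals — within the factor
1.5 the pipeline treats as its soft agreement band. The residual
normalization of uptake to cell number in the clonogenic tubes is
not fully specified in the published protocol, so only ratio structure is
treated as exact. The medium contribution relative to the published
totals evaluates to 3.3% (Lu-177) and 2.2% (Ac-225), matching the
published "2.6% / 1.6%" within two percentage points.

## Dose response and RBE

Survival fractions normalize mean colony counts to untreated controls;
their standard deviations assume Poisson statistics on the mean counts,
`sd = SF·√(1/mean_t + 1/mean_u)`. The dose-response model is pure
log-linear, `SF = exp(−αD)`, fitted through the origin by weighted
least squares on the ln scale with inverse-variance weights (an
optional quadratic term exists but is off by default: only α is
scientifically reported for this assay). Zero-SF points cannot be
log-transformed and are dropped with a warning, carrying a one-sided
95% upper bound instead; the highest activity concentrations are
flagged and excluded from fits. Because the Poisson variances are
known rather than estimated, the standard error of α uses the
fixed-variance GLS form `se(α) = (Σ w D²)^{−1/2}`.

RBE is the slope ratio α_test/α_reference with first-order error
propagation; the delta-method SE agrees with a Monte Carlo ratio
distribution within 5%. With the generating slopes 0.67 and 0.16 Gy⁻¹
the synthetic pipeline's median RBE over 50 seeded experiments falls
within 10% of 4.19, with propagated uncertainties within a factor two
of the reference ±0.46 (the synthetic noise model reproduces the
published standard errors only up to the unpublished inter-experiment
variability).

## Foci imaging

The counting pipeline mirrors a standard confocal macro: maximum
projection of the z-stack; Otsu segmentation of the nuclear channel
with hole filling, a 500-px minimum area and watershed splitting of
touching nuclei; then, per nucleus, an adaptive threshold at
`mean + k·SD` of the raw damage signal inside the mask. The threshold
is applied to a 1-px Gaussian-smoothed copy of the channel (killing
single-pixel noise excursions), supra-threshold components are split by
watershed on the intensity relief (tolerance 25% of the relief height,
separating touching foci), and components of at least 4 px count as
foci. Every step is affine-equivariant, so counts are invariant under
linear intensity rescaling.

The SD multiplier defaults to `k = 1`. The macro's threshold constant is not published (it is described only
as arbitrary); at the observed focus density (18.1 ± 7.4 per nucleus) a multiplier of 2 fails structurally —
the foci themselves inflate the in-nucleus SD until the threshold
clears the focus peaks and heavily damaged nuclei count zero — while
`k = 1` keeps a wide margin above smoothed background noise and
recovers counts from 0 to 30+ foci. On synthetic stacks generated at
mean 18.1 over 100+ nuclei the detected mean is within 15%, and the
regression slope of detected on generated means is 0.99 over the 2–25
range.

## Synthetic data: what it does and does not show

All generators are seeded and bit-reproducible, record their generating
parameters, and write JSON metadata sidecars next to file output.
Colony counts are Poisson around `450 × 0.5 × exp(−αD)` (plating
efficiency 0.5, a typical value for this cell line; not published);
excretion and displacement series carry 3% and 5% multiplicative
Gaussian noise in the published replication structures (2×3 and 3×3);
focus counts are negative-binomial matched to mean 18.1, SD 7.4
(overdispersed, as printed); nuclei are rotated ellipses with Gaussian
foci of σ 0.3 µm at SNR 5 on a 0.1 µm/px grid, with z-stacks built by
scaling a single noisy master plane so the analytic stack envelope is
exact.

Passing the recovery suites therefore demonstrates that the estimators
are unbiased and correctly weighted *under the stated noise model* —
multiplicative Gaussian and Poisson counting noise, ideal optics, no
cell-to-cell uptake heterogeneity, no focus colocalization ambiguity.
Real data add inter-experiment variability, microscope PSF and
background structure, and possibly non-Poisson colony statistics; the
published error bars are matched within a factor of two, not
reproduced.

## Numerical choices, in brief

Degenerate decay constants: relative nudge 10⁻⁹. Bateman round-off:
zeros below 10⁻¹² of the maximum. MC seeds: mandatory arguments;
sub-seeds derived by fixed offsets. Hough ties: highest accumulator
wins, suppression radius 1.2×. Clearance fit: unconstrained
Levenberg–Marquardt with post-hoc domain validation (box constraints
trip a spurious singular-gradient error on zero-residual data in the
underlying solver). IC50: one-site competition on log10 concentration,
signal normalized to the lowest-competitor mean (hence scale-invariant),
free Hill slope by default, flagged when flat or out of range. Zero-SF
survival points: dropped from ln fits, upper bound reported.

## Known limitations

* Attached-cell S values depend on unpublished geometry; see the
  accuracy envelope above.
* Electron transport is analytic (no scatter detour, no energy-loss
  straggling); agreement with condensed-history Monte Carlo is ±25-30%
  at worst in the configurations tested.
* No microdosimetry: the stochastic single-cell specific-energy
  distribution of alpha hits is out of scope; doses are mean doses.
* No cell proliferation or oxygenation effects in the dose-response
  model; clearance is extrapolated beyond the last measured time point.
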