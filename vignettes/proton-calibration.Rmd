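---
title: "Methods: medium-thickness-dependent proton dose calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: medium-thickness-dependent proton dose calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoncal)
```

`protoncal` models a standard radiobiology irradiation problem: a
monolayer of adherent cells at the bottom of a water-filled dish is
irradiated from above by monoenergetic protons, and the dose the cells
(or their nuclei) absorb must be calibrated against the reading of an
external ionization chamber. The calibration coefficient is the dose
ratio R = D_A/D_E, with both doses expressed as track-length energy
deposition per unit mass (MeV/g) per emitted source particle. Because the
proton stopping power rises steeply near the end of the range (the Bragg
peak), R depends strongly on the thickness of the medium layer above the
cells; mapping that dependence over 10–35 MeV and 100–5000 µm is the
purpose of the package.

## Physics model

**Stopping power.** Electronic mass stopping power from the Bethe
formula, with per-element ICRU mean excitation energies combined by Bragg
additivity over the material's mass fractions. Condensed-phase I-value
overrides follow standard practice: water 75 eV, dry air 85.7 eV, PMMA
74 eV, SiO₂ 139.2 eV. Shell and Barkas corrections are omitted — they are
sub-percent above 1 MeV and only the last few micrometres of any track
fall below that. Below ~0.06 MeV the Bethe logarithm can turn negative
for high-I materials; the stopping number is floored at a small positive
value there, entirely below the transport cutoff.

**Ranges.** CSDA ranges are accumulated by trapezoidal quadrature of
1/S(E) on an 800-point log-spaced grid from the 0.05 MeV cutoff to
50 MeV. Refining the grid tenfold changes the ranges by well under 0.2%
(asserted in the tests). The computed water ranges at 10/15/20 MeV are
1214/2517/4232 µm, within 1–2% of standard tabulations.

**Transport.** Condensed-history stepping along vertical rays. The step
is capped at `min(material cap, 2% of the residual range)` and floored at
0.5 µm; bulk materials use a 20 µm cap (1000 µm in low-density air), the
cell compartments a 0.5 µm cap so the 5 µm cells are resolved. The mean
step loss comes from the CSDA range difference via log-log-interpolated
tables; for steps much shorter than the residual range (< 0.5%) the
product S(E)·Δt is used instead, which avoids the numerical cancellation
of subtracting two nearly equal ranges (without this branch the cavity
dose of the chamber, whose air steps consume ~10⁻⁴ of the residual range,
is biased by tens of percent). A proton whose energy falls below the
0.05 MeV cutoff deposits its remainder locally. Protons travel in
straight lines: multiple Coulomb scattering moves a ≤35 MeV proton
laterally by only a few micrometres per millimetre of water, negligible
against the 15 µm cell footprint and the millimetre-scale chamber, and a
uniform broad beam stays uniform under small-angle scattering. Secondary
particles (neutrons, photons, delta rays) are not produced or
transported, and nuclear (nonelastic) proton interactions are not
modeled; consequences are discussed under *Limitations*.

**Straggling.** Energy-loss fluctuations use the Bohr variance,
σ² = K·m_ec²·(Z/A)·Δt, linear in the traversed mass. The per-step loss is
drawn from a Gamma distribution with the exact CSDA mean and that
variance. The Gamma choice is deliberate: a Gaussian truncated to
non-negative losses — the textbook recipe — acquires a large positive
bias exactly where this model must be unbiased, in the sub-micrometre
steps inside the cell compartments, where the Bohr σ exceeds the ~keV
mean loss. The Gamma density is strictly non-negative, reproduces the
mean exactly at any step size, and converges to the Gaussian in the
thick-step limit where the classical treatment is valid. A `"vavilov"`
option multiplies the variance by the relativistic large-κ factor
(1−β²/2)/(1−β²); at these path lengths κ is large and the Vavilov
distribution is near-Gaussian, so this Gaussian-limit treatment stands in
for full Vavilov sampling behind the same interface. Straggling `"off"`
reduces the engine to the deterministic CSDA limit, which the tests pin
against an independent fine-step ODE oracle to 0.1%.

## Geometry

**Cell array.** Nine identical cells on a 3×3 lattice at the bottom of a
550 µm-radius water dish on a 0.2 µm glass substrate, irradiated through
a 1 µm air gap by a parallel, uniform 1 cm-radius disk source. Cells are
half ellipsoids (lateral semi-axes 15 µm, vertical 5 µm, flat side down —
the printed axis triple 5/15/15 µm is read this way because a vertical
15 µm axis is not an adherent-cell morphology) with ellipsoidal nuclei
(7/7/1.5 µm). Choices the source description leaves open, fixed here as
explicit configurable defaults: nucleus center 2.0 µm above the substrate
(the 1.5 µm semi-axis then fits inside the 5 µm cap with margin), lattice
pitch 40 µm (10 µm gap between neighbours, everything well inside the
dish), medium thickness measured above the 5 µm cell plane (the cells sit
underneath the medium layer; the plane is water-filled around and above
the cells). Compartment volumes are closed-form (cell 2356.19 µm³,
nucleus 307.88 µm³) and are cross-checked by rejection sampling in the
tests.

**Compositions.** The printed five-element compositions do not state
their convention. Cytoplasm percentages (59.6% H) are only plausible as
*atom* fractions (hydrogen is ~60% of the atoms of water-like tissue, not
60% of its mass) and nucleus percentages (10.64% H) only as *mass*
fractions; PMMA's triple matches the C₅H₈O₂ atom counts. Each material
records its convention and both are selectable. Densities not printed
take standard values: tissue compartments 1.00, glass 2.20, dry air
1.205×10⁻³ g/cm³.

**Ionization chamber.** A Farmer-type thimble: 3.05 mm outer radius,
23 mm length, 0.425 mm PMMA wall *inside* that radius (the resulting
air cavity is 0.498 cm³, matching the quoted ~0.5 cm³), irradiated
side-on at mid-length — the standard orientation for a cylindrical
chamber, with the quoted wall read as the radial wall. Stem, central
electrode and end caps are not modeled. Rays decompose into
wall-chord / cavity-chord / wall-chord by the circle-chord formula.

## Normalization and importance sampling

Both doses are normalized per particle emitted by the same 1 cm source
disk, so the geometric factor cancels in R. Because rays are vertical, a
ray can only deposit energy in a scoring region if its entry point lies
over that region's footprint: the 15 µm disk of a cell, or the
chamber-width strip of the source disk. Entry points are therefore
sampled uniformly *within* those footprints and each tally carries the
analytic area weight (footprint/source-disk); this is an exact
reweighting, not an approximation, and it is what makes the model
desk-scale — a cell subtends 2×10⁻⁶ of the source disk, so naive source
sampling would waste essentially every history. `histories` counts
transported rays; the equivalent emitted-particle count is larger by the
inverse area fraction (~4×10⁵ per cell).

Uncertainties are per-history standard errors from the tallied second
moments (histories are independent, so this equals the batch-mean
estimate in expectation); group averages combine the member-cell spread
with the tally errors in quadrature. R errors combine the two dose errors
in quadrature. A single global seed is expanded into per-(energy,
thickness, cell) substreams by integer hashing, so any subset of a sweep
reproduces the full-sweep numbers bit for bit.

## Problem sizes

The package defaults and the reproduction script use 10⁵ transported
rays per (energy, thickness) point and 2×10⁵ for each detector energy;
at these sizes every tallied relative error in the study window is below
1%, comfortably beyond the 2% bar used for the acceptance checks. The
test suite runs smaller but still converged cases (order 10³–2×10⁴ rays)
chosen so that the asserted tolerances exceed the statistical errors by
a wide margin.

## What the simulated conditions do and do not show

The model reproduces the structure of the calibration: Bragg-peak-like
R-vs-thickness curves for 10–20 MeV with coarse-grid maxima at
1000/2500/4000 µm, collapse to R = 0 beyond the range, near-constant
curves for 25–35 MeV, negligible cell-to-cell variation, and fine-grid
Bragg-condition maxima above 7 (cytoplasm) and 6 (nucleus).

Two systematic differences against full nuclear-capable transport codes
are documented rather than hidden. First, absolute R at high energies:
with the chamber as printed, the thin-medium R is bounded below by the
tissue-to-air stopping-power ratio (~1.1) times geometry factors, and
this package finds R(100 µm) ≈ 1.26–1.32 at 30–35 MeV and a 25 MeV grid
maximum of ~2.5–2.6, whereas reference values reported for comparable
setups are ~15–40% lower — a normalization difference consistent with
additional dose contributions in the chamber cavity (e.g. secondary
particles and nuclear products) that this package deliberately does not
transport. The relative shape across energies and thicknesses agrees.
Second, nonelastic nuclear removal (a few percent of 25–35 MeV protons
over 5 mm of water) slightly reduces deep cell doses; it is not modeled.

Other known limitations: no chamber stem/electrode, no medium meniscus,
no cell-shape variability, no temperature/pressure corrections for the
air cavity, no LET or RBE output (only dose is scored), and validity
restricted to 0.05–50 MeV protons.

## A small worked sweep

```{r sweep, eval = FALSE}
sw <- sweep_R(15, c(100, 1500, 2500, 3000),
              config = transport_config(histories = 2e4, seed = 1))
glance(sw)
autoplot(sw)
```

`glance()` reports, per compartment, the thickness of the maximum
cell-averaged R and its value; `autoplot()` draws the R-vs-thickness
curves per energy and compartment; `per_cell_R()` and `detector_dose()`
expose the underlying per-cell records and D_E table.
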