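---
title: "Quasi-monochromatic elemental imaging with balanced filter pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-monochromatic elemental imaging with balanced filter pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rossfilter)
```

## The problem

Most laboratory X-ray tubes emit a broad bremsstrahlung spectrum and cannot
be tuned.  Elemental mapping by K-edge subtraction (KES) — imaging a sample
just below and just above the absorption edge of the element of interest —
normally needs a monochromatic, tunable beam.  A balanced (Ross) filter
pair synthesises a narrow energy band from a broad spectrum: two foils of
adjacent-Z elements are given thicknesses such that their transmissions
agree at every energy *except* between their two K-edges.  Subtracting the
two filtered images then leaves only the flux inside that band.  Two such
pairs, one isolating a band just below the target element's K-edge and one
just above it, turn a fixed-spectrum tube into a KES instrument.

This package simulates and analyses that experiment end to end for the
reference configuration: a 40 kVp tungsten-anode source, an Nb 30 µm /
Mo 24 µm pair isolating 18.99–20.00 keV, a Pd 25 µm / Ag 27 µm pair
isolating 24.35–25.52 keV, and rhodium (K-edge 23.2 keV, between the two
bands) as the target element, with nickel (K-edge 8.3 keV, far away) as
the confounder.

## Physics components

**Attenuation database.**  Linear attenuation coefficients µ(E) for Al,
Ni, Zr, Nb, Mo, Rh, Pd, Ag and Sn over 5–60 keV are interpolated log-log
from compact embedded tables, split into below-edge and above-edge
branches so interpolation never crosses the K-edge discontinuity.  The
tables were computed at build time from Cromer–Liberman photoabsorption
cross-sections plus a Klein–Nishina incoherent term and a small coherent
estimate, and validated against standard tabulations (few-percent
agreement at the energies that matter here; see
`data-raw/make_attenuation_tables.py`).  Edge energies are stored to three
decimals.  Tungsten is deliberately absent: its L-edges inside 5–60 keV do
not fit the two-branch model, and only the *shape* of the tungsten-anode
spectrum is ever needed.

**Source spectrum.**  `simulate_spectrum()` uses the Kramers form
S(E) ∝ (kVp − E)/E with tungsten L lines (8.40, 9.67 keV) as Gaussian
peaks, zero above the tube voltage (40 keV) and below a detector-induced
low-energy cut-off (default 8 keV).  The measured source spectrum of a
real instrument is not published, so absolute band fluxes are
model-dependent; `load_spectrum()` accepts a measured two-column CSV and
rebins it conservatively when one is available.  The default grid is
0.05 keV bins over 5–60 keV, resolving the ~1 keV passbands with ≥ 20
bins.

**Forward radiography.**  Detected counts follow the polychromatic
Beer–Lambert model, `sum_E S(E) T_filter(E) T_sample(E) D(E)`, with an
ideal photon-counting response D = 1 by default and an optional
energy-integrating D ∝ E mimicking a scintillator/CCD.  Exposure is
calibrated so the naked beam delivers ~10⁴ counts/pixel, *shared* by all
four filters of an acquisition — the between-filter flat differences are
the signal the subtraction uses.  Poisson noise is sampled only when a
seed is supplied; flats use an independently derived stream (seed + 1).

## The subtraction pipeline and its two key choices

Given flat-corrected images through the pair's two filters, the band
absorbance is, per pixel,

    A = -ln( (I_high - c * I_low) / (I0_high - c * I0_low) )

where `high` is the higher-K-edge foil (the one transmitting more inside
the band) and `I0` are the flats.  Two numerical choices deserve
explanation because the plain textbook subtraction does not reproduce the
reference results:

**Out-of-band rebalancing (`c`).**  With stock foil thicknesses (24 µm Mo
instead of the computed optimum 23.6 µm) the two arms are ~1.5%
mismatched outside the band.  Because both filters transmit the *same*
out-of-band sample spectrum, scaling the low-edge image by the known
out-of-band flux ratio `c = out_of_band_ratio(spectrum, pair)` cancels
that leakage for any sample to first order.  Without it the overlap error
below inflates from ~2% to ~17%.  This is the classical Ross balancing
condition enforced in software; `rebalance = FALSE` disables it.

**Matrix-cancellation weight.**  The two bands sit ~5.4 keV apart, so a
smooth absorber like Ni changes its µ by a factor ~2 between them and
would survive a plain difference `F = A₊ − A₋` at the tens-of-percent
level — incompatible with the reference experiment, where the Ni foil
perturbs the Rh map by only a few percent.  The pipeline therefore
combines the bands as

    F = A_plus - w * A_minus,    w = (Ebar_minus / Ebar_plus)^3

with `Ebar` the flux-weighted band centres (19.47 and 24.91 keV here, so
w ≈ 0.48).  Since photoelectric attenuation scales approximately as E⁻³,
the contribution of *any* element without an edge between the bands
cancels, while the target element — whose µ jumps at its K-edge — remains.
This is the standard two-energy material-cancellation weighting of KES;
`subtraction = "plain"` gives the unweighted difference, and the exponent
is configurable.  Thickness recovery divides the map by the consistent
coefficient `µ(Ē₊) − w µ(Ē₋)`.

The 2% pedestal threshold (zeroing pixels below 2% of the image maximum)
is applied to the high-band pair's raw images before subtraction,
suppressing stray scattered background; whether the reference workflow
applied it before or after flat correction is not stated, and we apply it
before.  Pixels whose band intensity difference is non-positive (possible
under noise) are clamped at 10⁻⁶ of the flat band intensity, flagged in a
mask, and excluded from ROI statistics.

## Quality metrics

Over configured rectangular regions of the final map:

* `snr()` — |⟨F_signal⟩ − ⟨F_background⟩| / √(σ²_signal + σ²_background);
* `eps_res()` — 100 · |⟨F_residue⟩| / ⟨F_target⟩, the trace the smooth
  element leaves where it lies alone;
* `eps_over()` — 100 · (⟨F_target⟩ − ⟨F_overlap⟩) / ⟨F_target⟩ (signed),
  the perturbation where the two elements overlap.

On the noise-free 512² two-foil fixture (Rh 12 µm, Ni 18 µm, 11 µm
pixels) the pipeline gives ε_over ≈ 2% and ε_res ≈ 1%.  Sweeping the
overlayer (`eps_over_curve()`) separates edge-adjacent from smooth
elements: Zr, whose K-edge (18.0 keV) sits against the filter edges,
produces a strong monotone overlap error (−10% at 18 µm, sign convention:
overlap *increases* the apparent Rh signal), while Ni and Sn stay within
~2% of zero at all thicknesses up to 30 µm.  Because the Ni and Sn curves
are near-perfect cancellations, their relative order is not a robust
prediction of the model and we do not assert one.

## Tomography

`forward_project()` rotates the voxel phantom slice-wise (bilinear
interpolation), accumulates per-element path lengths along parallel rays,
and applies the same polychromatic forward model; the geometry is the
parallel-beam idealisation of the instrument's cone beam, which is
adequate for method validation but ignores magnification.  The default
angle set is 181 projections in 1° steps over 0–180°; the 180° view
duplicates 0° in parallel geometry and is dropped during reconstruction.
`fbp()` implements Ram-Lak filtered back-projection (band-limited
spatial-domain ramp, optional Hann window) with linear interpolation, and
returns 1/cm given the detector pixel size.  `elemental_ct()` runs the
band subtraction on every projection and reconstructs the F-sinograms;
since FBP is linear, subtracting before or after reconstruction is
equivalent to machine precision, which the tests exploit as a
cross-check.  Beam hardening is present by construction (polychromatic
forward model, monochromatic-style reconstruction) and no correction is
applied.

The 3D fixture is an aluminium foam cube (porosity 0.4, spherical voids
of 3–8 voxel radius carved by a seeded process, shrinking as the target
void fraction approaches so the result lands within ±1%) with a rhodium
rod spanning about a quarter of the cube width.  The cube edge is 0.68 of
the grid so the rotated sample stays inside the field of view.  The
reference experiment's actual foam statistics and insert geometry are
unpublished; this fixture is illustrative, not a replica, and the CT
checks are property-based (contrast ratio, order-independence,
conservation) rather than image-matching.

## What the synthetic data do and do not emulate

The generator reproduces the acquisition parameters (40 kVp, 8 keV
cut-off, 512² images at 11 µm, 10⁴ flat counts, 181 angles, foil
thicknesses) and Poisson counting statistics.  It does not model the
measured spectrum's fine structure, detector blur, scatter beyond the
pedestal-level background, cone-beam geometry, filter-texture artefacts
(striations in rolled foils), or metal-streak corrections.  Passing tests
therefore demonstrate the correctness and internal consistency of the
method's algorithmic chain under the stated physics, not detector-level
agreement with any particular instrument's images — which is also why the
published experimental images are covered by property-based checks rather
than pixel comparisons.

## Problem sizes and numerical choices

Unit tests run on reduced geometries (32–128 px images, 48³ voxel grids,
21–91 angles); the acceptance suite additionally runs the full 512² foil
study, a 256² averaging study over 1–50 frames, and one full 128³ / 181
angle elemental CT.  Frame sets in the averaging study are nested (the
N = 5 average reuses the frames of N = 1), as when subsetting one
acquired series; its SNR comparison allows 10% Monte-Carlo jitter on the
residue-error monotonicity.  Scalar thickness matching uses Brent search
on [0.1, 500] µm with 0.01 µm tolerance (the objective is unimodal for
adjacent-Z pairs; verified at test time) and reports to 0.1 µm, matching
foil manufacturing precision.  All randomness flows from user-supplied
integer seeds.

## Known limitations

* µ tables are few-percent accurate; derived absolute absorbances inherit
  that, though the headline quantities (edge energies, thickness ratios,
  relative errors) are insensitive to it.
* The E⁻³ cancellation weight is exact only for an idealised photoelectric
  power law; residual ε_over of ±2% for smooth elements is intrinsic.
* Parallel-beam geometry; no detector PSF; no scatter simulation.
* Elements whose K-edge falls inside either passband (e.g. Ru next to Rh)
  cannot be separated — a limitation of the method, not the code.
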