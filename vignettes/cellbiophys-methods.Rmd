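---
title: "Models and methods behind cellbiophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cellbiophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellbiophys)
```

cellbiophys quantifies five biophysical readouts of cultured cells —
membrane transport kinetics, Laurdan membrane order, AFM indentation
elasticity, AFM single-cell adhesion, and AFM topographic morphometry —
plus wound-closure migration and qPCR knockdown. This vignette explains the
underlying models, the tunable parameters and their defaults, the numerical
choices, and what the bundled synthetic-data generator does and does not
emulate.

## Osmotic transport kinetics

The cell is modelled as a single well-mixed compartment with an osmotically
inactive volume fraction $\beta$, ideal dilute solutions, and constant
membrane area. With volumes relative to the resting volume $V_0$:

$$\frac{dV_w}{dt} = -P_f \frac{A}{V_0} V_w^{mol} (Osm_{out} - Osm_{in}),
\qquad
\frac{dN_s}{dt} = P_{gly} \frac{A}{V_0} (c_{out} - N_s/V_w),$$

with $Osm_{in} = (N_{imp} + N_s)/V_w$ and $V_{rel} = \beta + V_w + v_s
N_s$. An impermeant challenge (mannitol) drives pure shrinkage toward the
linear-osmometer equilibrium $\beta + (1-\beta)\,Osm_{iso}/Osm_{final}$; a
permeant challenge (glycerol) produces the characteristic fast shrinkage
followed by re-swelling as solute and water re-enter, ending at
$V_{rel} = 1$.

Parameter choices:

* `area_to_volume` defaults to $3/r$ for a spherical cell of radius
  10 µm (3000 cm⁻¹). The literature for this assay gives no cell geometry,
  so a sphere is the neutral choice; the ratio only rescales the fitted
  permeabilities, it does not change orderings between conditions.
* `nonosmotic_fraction` defaults to 0 (fully osmotic cell), configurable.
* The permeant solute's partial molar volume `molar_volume_solute`
  defaults to 0. Including glycerol's ~73 cm³/mol would raise the
  re-swelling endpoint by about 2%; with the default the canonical
  $V_{rel} \to 1$ endpoint is exact. The parameter is exposed for users who
  want the volume-corrected variant.

The forward model is integrated with `deSolve::lsoda` (relative tolerance
$10^{-8}$). $P_f$ is fitted on the impermeant challenge by 1-D
least squares over $\log_{10} P_f \in [-6, -1]$; $P_{gly}$ is then fitted on
the glycerol challenge with $P_f$ held at the matched mannitol estimate.
Both fits are golden-section searches — the problem is one-dimensional and
smooth, so no gradient-based machinery is needed. Traces without a
detectable response (shrinkage, or re-swelling, smaller than 5 trace noise
SDs) return a diagnostic instead of a number.

Peroxide influx is summarized as the first-order rate constant $k$: the
least-squares slope of $\ln F$ versus time. The quasi-linear fit window can
be set explicitly or found automatically: the window starts where the local
slope of the smoothed $\ln F$ first reaches half its maximum (the challenge
onset) and ends where it falls below half its at-onset value. The local
slope uses a running-median smoother and a wide centered difference
(~1/20 of the trace), which keeps the window stable at realistic noise
(2% multiplicative).

## Laurdan generalized polarization

$$GP = \frac{I_{blue} - G\,I_{red}}{I_{blue} + G\,I_{red}}$$

with $I_{blue}$ the 400–460 nm and $I_{red}$ the 470–530 nm emission
channel, dark counts already subtracted (the image reader's contract). $G$
is calibrated from a Laurdan-in-DMSO measurement by solving the GP equation
for the unique $G$ returning the reference value $GP_{DMSO} = 0.0357$. GP is
bounded in $[-1, 1]$ for any non-negative intensities and $G > 0$; pixels
whose denominator falls below `min_denominator` carry no usable signal and
are flagged invalid rather than zeroed. A practical threshold is ~5× the
dark-count noise SD.

Membrane ROIs are extracted automatically: the summed channels are smoothed
(Gaussian, σ = 1 px), thresholded by Otsu's rule, labelled into connected
components above a size floor (200 px), holes filled, and each cell's mask
taken as the *inward* band of `rim_width` (default 5 px) from the component
boundary. An inward band rather than a band centered on the boundary is
deliberate: the plasma-membrane signal of an adherent cell lies inside the
detected footprint edge, and a centered band would place half its pixels in
the background. Manual ROI drawing, the usual practice, is not reproducible;
the automated rim is, and it is validated against the generator's truth
masks (≥ 90% rim coverage, ≤ 10% interior contamination).

Per-cell GP is the arithmetic mean of pixel GP values over valid masked
pixels — not the GP of mean intensities, which is a different (and biased)
statistic. Condition summaries report mean ± SEM over cells and warn below
the 50-cell design floor.

## AFM indentation elasticity

Piezo convention: approach positions decrease toward the sample. The chain
is baseline correction → contact point → indentation → Hertz fit:

1. **Baseline**: a line fitted to the leading (non-contact) 40% of the
   approach is subtracted from the whole cycle, removing optical
   interference tilt. Fitted moduli are invariant to any added linear
   baseline by construction.
2. **Contact point**: the first position from which the force exceeds
   3×noise SD and stays above it to the end of the approach. This threshold
   rule is transparent but lags true contact by the distance the force needs
   to climb to 3σ (tens of nm for kPa-soft cells), so the estimate is then
   refined by minimizing the Hertz-fit residual over $z_c$ on a *fixed*
   window (contact region plus 0.2 µm of baseline). Fixing the window
   matters: letting the data window move with $z_c$ biases the optimum
   toward excluding low-force samples. The refinement search spans
   $[z_c - 0.05, z_c + 0.25]$ µm, asymmetric because threshold detection
   only ever lags.
3. **Indentation**: $\delta = (z_c - z) - F/k$, the piezo travel past
   contact minus the cantilever deflection, clipped at 0.
4. **Hertz fit**: paraboloid $F = \tfrac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,
   \delta^{3/2}$ by default ($R$ = 15 nm tip radius, $\nu$ = 0.5
   incompressible), cone and pyramid variants selectable. At fixed geometry
   the law is linear in $E$, so the least-squares estimate is the
   closed-form through-origin regression of force on the unit-modulus model
   — no iterative optimizer, no convergence failures. The fit domain is
   capped at δ ≤ 500 nm to respect small-deformation validity.

Noise-free curves (with or without tilt) are inverted to 0.1%; at 5 pN
Gaussian noise the median recovery error over 50 curves is ~1%.

Tip penetration depth at the 300 pN protocol setpoint is read off by linear
interpolation of the force–indentation record and scales as $E^{-2/3}$
under the paraboloid model. Population stiffness is summarized by a
histogram (Freedman–Diaconis bins) with a Gaussian fitted to bin
centers/counts via Levenberg–Marquardt; the peak is the fitted mean.
Degenerate spreads fall back to the sample median (flagged), and a Gaussian
$R^2 < 0.9$ (e.g. a bimodal population) is flagged as a poor fit rather
than silently reported.

## Single-cell adhesion

Retraction curves are canonicalized to increasing piezo position, baseline
corrected on the trailing (non-adhesive) 20%, and summarized by:

* **Maximum detachment force**: magnitude of the most negative force.
* **Work of detachment**: trapezoidal integral of $-F$ over the adhesive
  ($F < 0$) region, in aJ (1 aJ = 1 pN µm). Only the adhesive region is
  integrated: the positive-force contact region is elastic loading, not
  detachment work.
* **Unbinding events**: a step is a force rise toward zero exceeding
  `step_threshold` (4) × noise SD within ≤ 5 samples. Each raw-rise
  candidate must also pass a confirmation test: the median force over a
  window after the jump minus the median before it, discounted by the rise
  a smooth local trend would produce over the same distance, must clear the
  threshold too. Without this, noise sitting exactly at threshold and the
  steep detachment ramp itself generate overwhelming false positives; with
  it, recall is ≥ 99% and FDR ≈ 8% on seeded curves with ≥ 6σ steps.
  The robust level difference doubles as the step-force estimate.
* **Plateau length**: walking back from the step while the force stays
  within `plateau_tolerance` (4 × noise SD, in pN) of the pre-step level,
  bounded by the previous event. A deviation tolerance is used instead of a
  local slope rule because sample-scale slopes are unmeasurable at
  realistic noise. The measured plateau can overshoot into an adjacent
  ramp by up to tolerance/slope (≈ 0.07 µm for the generator's ramps) —
  well clear of the classification boundary for physiological plateau
  lengths.
* **Classification**: plateau ≥ 0.25 µm ⇒ membrane tether, otherwise jump.
  The boundary value itself is assigned to tether (closed upper set) and
  the threshold is a parameter.

## Topographic morphometry

Height maps are levelled by a least-squares plane through the
lowest-decile pixels (the substrate); the cell mask is the largest
connected component above a floor of 3× the substrate residual SD, with an
absolute guard of 1% of the maximum height so that a noiseless synthetic
substrate does not degenerate the threshold. Metrics:

* **Area**: projected footprint (pixel count × pixel area). 3-D surface
  area is deliberately not the default — projected area is the testable,
  unambiguous convention.
* **Volume**: sum of heights over the mask × pixel area.
* **Elongation**: minor/major axis ratio of the second-central-moment
  equivalent ellipse — rotation- and reflection-invariant, unlike a
  bounding box. 1 for a disk; more elongated cells score lower.
* **Roughness**: Rq (RMS) and Ra (mean absolute) residual after removing a
  detrend surface fitted within the mask — 2nd-order polynomial by default,
  which absorbs the cell's own curvature and leaves membrane texture; plane
  detrend selectable.

## Wound closure and qPCR

Wound closure is normalized to the t = 0 area, `closure(t) = (A0 − At)/A0`;
the migration rate is the through-origin least-squares slope of closure
versus time over the observation window (0/12/24 h by default), reported as
percent of the control's rate. The through-origin definition is a package
choice: rates are reported in the literature only as percent of control,
and any definition proportional to the closure slope yields the same
percentage.

Relative expression uses the efficiency-corrected ratio
$E_t^{\Delta Ct_t} / E_{ref}^{\Delta Ct_{ref}}$ with replicate Cts averaged
first and per-gene efficiencies defaulting to 2 (perfect doubling), where
it reduces exactly to the Livak $2^{-\Delta\Delta Ct}$. Knockdown is
$100(1 - ratio)$, floored at 0.

## The synthetic-data generator

Every analysis input can be generated with known ground truth, and every
generator is inverted by its analysis stage at zero noise — that is the
module's central contract, and the test suite enforces it. Condition
presets (`control`, `siAQP3`, `siAQP5`, `siAQP3_5`) encode the effect
directions of an aquaporin-silencing experiment as configuration: ratios
that are printed as numbers in the source literature (peroxide influx at
30%/30%/15% of control, migration at 11%/14%/8%, knockdown 75%/50%) are
used as defaults; contrasts reported only graphically are set once to
round ±30–50% shifts in the reported direction (e.g. stiffness 2.0 →
1.4 kPa, membrane GP 0.35 → 0.25) and are never treated as published
values.

Noise models are the standard instrument models: multiplicative Gaussian
for volume traces (1%), additive Gaussian for force (5 pN), Poisson for
photon counts, Gaussian for Ct values (0.15 cycles). All are configurable.

One geometric choice deserves a note: synthetic cells in topography are
elliptical *paraboloid* caps (volume $\pi a b H/2$), not spherical caps. A
paraboloid is removed exactly by the 2nd-order polynomial roughness
detrend, so the generated texture Rq is recoverable by construction; a
spherical cap's $\sqrt{\cdot}$ profile leaves ~100 nm of detrend residual
that would swamp any realistic membrane texture. Analytic-shape validation
of the morphometry code itself uses directly constructed hemispheres and
ellipses, independent of the generator.

What the generator does **not** emulate: optical point-spread functions and
spectral bleed-through, AFM tip convolution and viscoelastic response,
cantilever hydrodynamic drag, perfusion dynamics, segmentation-resistant
cell clumping, or any mechanistic aquaporin biology. Passing tests
therefore demonstrate that the estimators invert the stated forward models
at realistic noise — not that those forward models capture every property
of real instrument data.

## Problem sizes and runtime

The default test and demonstration scale generates suites at
`size_factor = 0.1` of the reference design (60 indentation curves, 4
adhesion cells × 5 curves, ~8 GP cells, 6 traces per assay and condition),
which runs the full four-condition pipeline in well under a minute while
leaving every condition contrast detectable by a two-sided rank test at
p < 0.05. Full-scale suites (`size_factor = 1`) reproduce the reference
counts (600 indentation curves, 36 × 5 adhesion curves, ≥ 50 GP cells per
condition).

## Known limitations

* The osmotic model assumes constant membrane area and ideal solutions;
  fitted $P_f$/$P_{gly}$ scale inversely with the assumed $A/V_0$.
* Contact-point refinement assumes the Hertz model holds near contact;
  strongly non-Hertzian curves fall back to the 3σ threshold estimate.
* Plateau lengths are measured with a deviation tolerance and can
  overshoot into adjacent ramps by tolerance/slope.
* The 2-D projected-area → volume helper `area_to_vrel` assumes isotropic
  rescaling, which adherent cells violate; it is provided as a flagged
  approximation only.
* Step detection assumes steps complete within 5 samples; slow multi-stage
  ruptures are reported as single events or missed.
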