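---
title: "Commissioning a TG-43 dose engine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Commissioning a TG-43 dose engine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachyqa)
```

## The problem

Commercial brachytherapy treatment planning systems (TPS) compute dose with
the AAPM TG-43 formalism, driven by tabulated source data: a dose-rate
constant $\Lambda$, a radial dose function $g_L(r)$, and a 2D anisotropy
function $F(r,\theta)$. Vendors ship these tables with the system ("vendor
input data", VID), usually subsampled from a published Monte Carlo data set.
When the anisotropy table is sampled on too few polar angles, the TPS must
interpolate linearly across the steep dose gradients that cable-driven HDR
sources exhibit within roughly 15 degrees of both poles. The resulting
*outcome discrepancies due to interpolation* (ODIN) can reach tens of
percent locally while every standard commissioning check — transverse-axis
point arrays, ABS-style reporting points, even gamma analysis at clinical
criteria — stays green. This package implements the full chain needed to
expose the effect: a TG-43 dose engine, table-comparison tooling,
dose-plane superposition for standard clinical dwell configurations,
2D gamma analysis, and QA point patterns, all testable end to end on a
synthetic data generator.

## The dose model

The engine evaluates the line-source approximation
$$\dot D(r,\theta) = S_k \,\Lambda\,
  \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}\, g_L(r)\, F(r,\theta),$$
with the reference point at $(r_0,\theta_0) = (1\,\mathrm{cm}, 90^\circ)$.
The geometry function is
$$G_L(r,\theta) = \frac{\beta}{L r \sin\theta}, \qquad
  G_L(r,0) = G_L(r,180^\circ) = \left(r^2 - L^2/4\right)^{-1},$$
where $\beta$ is the angle subtended by the active length $L$ at the
calculation point, computed from the two endpoint angles. Angles within a
configurable $\varepsilon$ (default $10^{-4}$ degrees) of a pole are routed
to the on-axis branch; the two poles are handled identically by symmetry.
Units follow the field's conventions throughout: cm for distances, degrees
for angles externally (radians only inside the geometry function),
cGy h$^{-1}$ for dose rate, U ($\mu$Gy m$^2$ h$^{-1}$) for air-kerma
strength.

Interpolation and extrapolation policies are explicit because they are the
very subject of the analysis:

* $F(r,\theta)$ is interpolated bilinearly; queries at tabulated nodes
  return the stored values exactly. Radii outside the tabulated range are
  clamped to the nearest tabulated radius (common TPS behaviour; whether
  real systems clamp or extrapolate radially is generally undocumented, so
  the conservative choice is the default). Angles beyond the tabulated
  range are extrapolated linearly from the two angles nearest the pole and
  floored at $10^{-3}$ to preserve positivity — the same first-order rule
  that vendor pole entries have been observed to match.
* $g_L(r)$ may be a polynomial (the form vendors ship) or a table with
  linear or log-linear interpolation; "log-linear" means linear in
  $\log g$ versus $\log r$, so a query at the geometric mean of two node
  radii returns the geometric mean of the node values. Out-of-range
  queries are rejected by default (a clamping policy is selectable).
* $g(r_0) = 1$ and $F(r, 90^\circ) = 1$ are enforced at load time (1e-6
  and 1e-3 tolerances respectively); tables violating them are rejected
  rather than silently renormalised, unless renormalisation is requested.

The polar angle is measured from the source long axis. Which physical end
carries $\theta = 0$ differs between conventions (AAPM recommends the tip;
vendor tables often index from the cable side), so the orientation is an
explicit flag on the source model and the synthetic tables document theirs
(cable at 0).

## Synthetic study conditions

No vendor or reference Monte Carlo table is redistributable here, so the
`synthetic_data` generator builds the study conditions from a closed-form
emulation:
$$F_{\mathrm{raw}}(r,\theta) = 1 - A_{\mathrm{cable}}(r)\,
  e^{-\theta_c/w_{\mathrm{cable}}} - A_{\mathrm{tip}}(r)\,
  e^{-\theta_t/w_{\mathrm{tip}}},$$
renormalised so $F(r,90^\circ) = 1$ exactly, where $\theta_c,\theta_t$ are
the angular distances to the cable and tip poles. The exponential form is
smooth, monotone toward the poles, and reproduces the
linear-interpolation-underestimate mechanism; it is an emulation target,
not a fit to any published source. The defaults — $A_{\mathrm{cable}} =
0.55$, $w_{\mathrm{cable}} = 6^\circ$, $A_{\mathrm{tip}} = 0.45$,
$w_{\mathrm{tip}} = 8^\circ$, amplitudes declining linearly by 0.4%/0.3%
per cm — were chosen once to match the structure of published tables for
cable-driven HDR Ir-192 sources: pole values in the 0.4–0.7 range, steeper
and deeper depression on the cable side, mild radial dependence. They are
frozen; the pipeline's qualitative findings (interpolation error >10% in
the gaps, discrepancies confined to the pole bands) follow from them rather
than being tuned per run. The amplitudes are linear in $r$ deliberately:
bilinear radial interpolation is then essentially exact and every
discrepancy the pipeline reports is attributable to the *angular* sampling,
which is the effect under study.

The companion pieces:

* `subsample_vendor()` resamples the dense table onto a 17-angle x
  10-radius vendor-style grid whose angle list has no samples inside
  $(1.5^\circ, 25.5^\circ)$ or $(155.5^\circ, 178.5^\circ)$, with the
  mandatory $0^\circ$/$180^\circ$ entries filled by linear pole
  extrapolation. Only 14 of the 17 VID angles are published for the system
  that motivated this layout; the remaining three (55.5, 150.5, 178.5 here)
  were placed so the documented gap structure is preserved, and the whole
  list is configurable.
* `make_alongaway()` evaluates the engine on a 13 x 28 away/along grid
  whose two on-axis points inside the singular zone are excluded, leaving
  exactly 362 valid reference points — the size of the classic reference
  along–away table. The published grid coordinates are not reproduced; the
  layout is synthetic and says so in its provenance.
* The default radial dose model is a frozen quartic with the gentle
  rise-then-fall shape of HDR Ir-192 radial dose functions, normalised to
  $g(1\,\mathrm{cm}) = 1$ exactly.
* Noise is off by default so every downstream oracle is exact; optional
  multiplicative log-normal noise uses a recorded seed and restores the
  caller's RNG state.

What the generator does *not* emulate: Monte Carlo statistical noise in
real tables, encapsulation/cable material differences between sources,
phantom-size scatter effects at large radii, and any dose-to-medium
conversion. Passing tests therefore demonstrate the *pipeline's*
correctness and the *mechanism* of interpolation-driven discrepancies, not
agreement with any specific commercial system's numbers.

## Table comparison and ODIN detection

Tables on different axes are compared after bilinear resampling
(`resample_table()`, provenance-stamped `int-<src>2<dst>`). Differences are
signed per-cell percentages, $100\,(b - a)/\mathrm{den}$, with the
denominator table a configurable choice (the reference/in-house table by
convention); absolute values are a display decision, not a storage one.
`odin_detect()` flags cells beyond the 2% investigation level, classifies
anything beyond 5% as intervention level (the discrepancy limits standard
commissioning guidance recommends), groups flagged cells into contiguous
angular bands, and reports the fraction of the polar-angle domain
$[0^\circ, 180^\circ]$ those bands cover. For bands within 15 degrees of
both poles this fraction is $30/180 \approx 17\%$. A solid-angle-weighted
coverage is reported as a secondary figure; it is not used for headline
reporting because the action bands are defined on polar angle.

Extraction of $F$ from an along–away table uses the formal TG-43
definition, with the transverse-axis denominator computed in closed form
($\Lambda\, G_L(r,\theta_0)/G_L(r_0,\theta_0)\, g_L(r)$) so the table never
needs to be interpolated on the transverse axis. Points within
$L/2 + 0.05$ cm of the source center are excluded as the singular zone
(configurable); the output keeps the original $(y,z)$ indexing with polar
equivalents attached. On generator-produced tables the round trip recovers
the input $F$ to machine precision, which is the pipeline's own
self-consistency check.

## Clinical dwell configurations

Five standard setups are built by `make_setup()`: a single dwell; a 3.5 cm
applicator with 6 dwells (0.7 cm steps, endpoints included); a 9 cm
applicator at 0.5 cm steps (19 dwells); a Fletcher arrangement (6 cm
tandem, two 2 cm ovoids, one dwell per ovoid, axes parallel to the tandem)
with schematic ABS-style reporting points attached; and a parallel
multi-applicator implant (default 5 applicators at 1 cm pitch — the source
publications never specify this geometry, so it is an explicit
configuration default). Dwell weights default to uniform since none of
these setups is described as optimised. Dose planes are superposed
per-dwell with each evaluation point transformed into the dwell's local
polar frame; applicator interiors and per-dwell singular zones are masked.
The default evaluation grid is a 6 cm half-width plane at 0.5 mm spacing;
tests and the acceptance script use 2–3 cm half-width at 1 mm spacing,
which resolves the pole bands while keeping a full run interactive — the
physics does not change with the grid, only the resolution of the map.

The ABS-style points (point A left/right, a point 1.8 cm beyond the tandem
tip, ovoid surface and surface + 0.5 cm, rectal and bladder points) are
schematic configuration defaults on the coronal/sagittal planes, not
patient anatomy; their role is to demonstrate that sparse point-based
checks sit outside the pole bands and therefore miss discrepancies that 2D
maps reveal.

## Gamma analysis

`gamma_2d()` implements the 2D gamma index with *local* dose
normalisation: for each reference point the minimum over candidate
positions of
$$\gamma = \sqrt{\frac{|\Delta x|^2}{\mathrm{DTA}^2} +
  \frac{(D_{\mathrm{eval}}(x) - D_{\mathrm{ref}})^2}
       {(d\%_L \cdot D_{\mathrm{ref}})^2}},$$
searching exhaustively on a lattice of step $0.1 \times \mathrm{DTA}$
within a radius $3 \times \mathrm{DTA}$, over the bilinearly interpolated
evaluated plane. The exhaustive search was chosen over analytic
accelerations because it is deterministic and directly comparable to a
brute-force oracle; the commercial tools used for this analysis in
practice are closed, so pattern-level agreement (monotone pass rates,
medians scaling as $1/d\%$), not value-level agreement, is the correctness
surface. Points whose search disc extends beyond the plane use the
in-bounds portion; no low-dose cutoff is applied by default. Reference
points sit on grid nodes, so the zero offset is always a candidate and
$\gamma(A,A) \equiv 0$ exactly.

Two numerical caveats are documented rather than hidden. First, the
candidate lattices for different DTA values are not nested (the step
scales with DTA), so per-point gamma is not strictly monotone across DTA;
pass-rate monotonicity holds on all tested planes but is an empirical
property, not a lattice guarantee. Second, agreement with a dense-lattice
($0.02 \times \mathrm{DTA}$) brute-force search to $10^{-3}$ requires the
gamma surface to be well resolved at the coarser step; the oracle fixture
planes therefore use gentle gradients, while steep-gradient behaviour is
exercised separately on the clinical plane pairs.

## QA point patterns

`half_star_pattern()` places six rays at $0^\circ$, a configurable angle
inside $(0^\circ, 15^\circ)$ (default $7^\circ$), $45^\circ$, $90^\circ$,
$135^\circ$, and a configurable angle inside $(165^\circ, 180^\circ)$
(default $172^\circ$). The two free rays force the planning system to
display results inside the high-gradient pole zones — exactly where
vendor tables interpolate worst and where the classic array patterns
(`legacy_pattern()`, transverse-mirror-symmetric, no ray inside the pole
bands) are blind. One published description gives the cable-side ray's
interval as $(0^\circ, 20^\circ)$ in a figure caption versus
$(0^\circ, 15^\circ)$ in the text; the text value bounds the default and
the interval is configurable. Pattern evaluation reports signed percent
differences per point with 2%/5% action flags and shell-style exit codes
(0 clean, 3 investigation, 4 intervention) so the pattern can gate a
commissioning script.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the pipeline at fixed,
stated sizes: 21 x 21 planes for gamma-oracle equivalence, 41 x 41 to
51 x 51 planes (1 mm spacing) for the clinical gamma sweeps, 61 x 61
planes for difference maps, and the 362-point along–away grid for
extraction. All randomness (only the optional table noise and the
geometry property draws) derives from a single seed; the default
generator is noiseless, so repeated runs are bit-identical. The
acceptance script recomputes every reported number from scratch at run
time.

## Known limitations

* 2D planes only; no 3D dose grids, DVH or dose-volume indices.
* No Monte Carlo transport, scatter/phantom-size corrections, or
  model-based (TG-186) algorithms; the engine is TG-43 as specified.
* The synthetic generator is a mechanism emulator, not a source model;
  quantitative agreement with any specific commercial system's tables is
  out of scope by design.
* Gamma pass rates depend on the unpublished tables of the motivating
  study and are matched in pattern, not value.
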