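---
title: "spinlyo: models, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spinlyo: models, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinlyo)
```

# The measurement model

A spin-frozen vial carries its formulation as an annular frozen layer on
the inner wall. During primary drying the sublimation front sits at radius
$r_p(\Phi, h, t)$ and moves outward toward the wall at $r_{vial}$. A
time-resolved micro-CT series, resampled onto a cylindrical
$(r, \Phi, h)$ grid, yields per coordinate and scan:

* the frozen-layer thickness $L_{ice} = r_{vial} - r_p$, with $r_p$ the
  inner edge of the innermost bin classified as ice;
* the integrated frozen length $L'_{ice}$, the summed radial length of all
  ice-classified bins. Internal cavities are counted by $L_{ice}$ but not
  by $L'_{ice}$, so $(L_{ice}-L'_{ice})/L_{ice}$ is a per-coordinate
  diagnostic of non-radial sublimation; a field exceeding 0.05 on more
  than 5% of the defined coordinates flips the radial-sublimation verdict
  (both fractions configurable).

The local dried-product resistance follows from a one-dimensional radial
mass-transfer model per $(\Phi, h)$ segment:

$$R_p = \frac{A_p\,(P_i - P_c)}{\dot m_{sub}}, \qquad
  V = \frac{\pi h_{vial}}{n\,m}\left(r_{vial}^2 - r_p^2\right), \qquad
  A_p = \frac{2 \pi h_{vial}}{n\,m} r_p,$$

with $\dot m_{sub} = -\,\mathrm{d}V/\mathrm{d}t \cdot \rho_{ice}\,
\theta_{dr}$ and the front vapour pressure $P_i(T_i)$ from an empirical
Clausius–Clapeyron-type correlation. $T_i$ comes from a single
thermocouple trace and is treated as spatially uniform (a per-coordinate
hook exists but is unused by default). Profiles are reported against the
dried thickness $L_{dr} = L_{ice,0} - L_{ice}$ and binned into 38 bins
over 0–2.5 mm (right edge inclusive; empty bins flagged). The per-bin
statistic is the **median** — robust against crack-induced outliers; the
aggregator is a design choice of this package.

$L_{ice,0}$ is taken from the first available scan. When scanning starts
minutes into drying this underestimates the true initial thickness
slightly; the bias propagates into $L_{dr}$ and is documented rather than
corrected.

# Endpoint simulation

The predictor advances a coupled vial-level heat balance and
per-coordinate mass balance with step $\Delta t$ (default 60 s):

1. solve $P_{tot} = A_{p,vial}(P_i - P_c)/R_{p,vial}\cdot\Delta H_{sub}/M$
   for a single interface temperature $T_i$, with $A_{p,vial}$ the summed
   projected areas of still-active coordinates and $R_{p,vial}$ the per-bin
   median profile evaluated at the mean dried thickness of the active set;
2. per active coordinate, draw $R_{p,i}$ from its clamped interpolating
   spline, compute $\dot m_i = A_{p,i}(P_i - P_c)/R_{p,i}$, and accumulate
   sublimed volume $V_i \mathrel{+}= \dot m_i \Delta t/(\theta_{dr}\rho_{ice})$;
3. invert the segment volume exactly,
   $r_{p,i} = \sqrt{r_{p,0}^2 + V_i\,n\,m/(\pi h_{vial})}$, and mark
   $t_{end}$ when $L_{dr,i} \ge L_{ice,0}$, with sub-step linear
   interpolation of the finishing time;
4. converged coordinates contribute neither area nor mass from the next
   step.

The printed form of the thickness-update equation in the source material
is typographically inconsistent with the segment-volume definition (the
front must move outward as volume sublimes); the exact annular inversion
above is the only reading compatible with the rest of the model, and the
suite verifies the round trip against the forward volume formula to
1e-12 relative.

**Endgame capping.** With fixed delivered power, the active area
eventually becomes too small to absorb $P_{tot}$ below the triple point:
the bracketed residual has no sign change. Physically the interface then
sits at the sublimation limit and surplus power heats the glass; the
stepper caps $T_i$ at 273.16 K and flags the step (`capped` in the
history). The strict solver contract (reject when the bracket has no sign
change) is preserved in `solve_interface_temperature()` itself.

**Energy-limited regime.** Because $P_{tot}$ is fixed, total drying time
is set by the energy ledger $m_{ice}\Delta H_{sub}/(M P_{tot})$, not by
the resistance level: scaling all $R_p$ profiles by a common factor raises
$T_i$ but moves $t_{end}$ by well under 1% (only through the weak
temperature dependence of $\Delta H_{sub}$). The property suite asserts
exactly this, rather than a naive "larger resistance, later endpoint"
monotonicity which holds only for *relative* differences between
coordinates at fixed total power.

# The phantom: what it emulates, and what it does not

The generator renders a glass cylinder (inner radius 10.9 mm by default)
with an annular ice layer of per-coordinate thickness, using three
attenuation levels (air/dried ≈ 0, ice, glass); the dried product is
deliberately indistinguishable from air, since its attenuation is
negligible next to frozen product and glass. Boundary voxels get
area-weighted greyscale, which is what makes half-voxel recovery claims
meaningful. Fields emulate reported intra-vial structure: linear
top–bottom thickness gradients (up to ~20% for insufficient spin rates),
sinusoidal azimuthal eccentricity (off-centre spinning), radial cracks
fully penetrating the layer, internal cavity bands, and gripper-spot
depressions. One integer seed governs every stochastic draw; rendering is
bit-reproducible given spec, seed and frame index.

It does **not** simulate the projection domain: no tomographic
reconstruction, beam hardening, ring artefacts, motion blur or
photon-statistics noise — greyscale noise is i.i.d. Gaussian, stated as a
fraction of the ice/air contrast. The scan histogram of the real
instrument is unknown to us, so contrast and noise defaults are our own.
A green phantom test therefore establishes the correctness of the
*analysis chain* (segmentation through endpoint prediction), not
robustness to reconstruction artefacts.

Demo scale: the reference acquisition (30 µm voxels, 1600 × 1300
segmentation) is far beyond a unit-test budget. The suite uses 100 µm
voxels, a 4 mm vial-height section, a 16 × 10 $(\Phi, h)$ grid, scans
every 50 s and the reference process point ($P_c$ = 10 Pa, $P_{tot}$ =
1.2 W), which dries in ~0.3 h and renders ~23 frames in seconds. The
full-scale values remain the constructors' documented defaults.

# Numerical choices

* **Re-gridding** — trilinear interpolation at cylindrical bin centres
  (half-voxel accuracy without ringing); bins outside the cartesian
  footprint are `NA`. Radial bins default to the voxel size.
* **Axis estimation** — two nested Otsu thresholds isolate the brightest
  (glass) class; the planar centroid of the wall annulus is the axis.
  Accurate to well under a voxel on phantoms as long as the wall lies
  fully inside the volume footprint.
* **Segmentation** — Otsu's threshold over interior ($r < r_{vial}$) bins
  by default, fixed-value override available; a degenerate single-level
  histogram is rejected under the automatic policy. Bins within one radial
  bin of the wall accept ice only by continuity with the bin just inside:
  partial-volume bleed from the much brighter glass otherwise leaves a
  persistent phantom shell of "ice" after a coordinate has dried.
* **Speck filtering** — per radial column, ice runs shorter than
  `min_run` (default 2) bins cannot define $r_p$; implemented per column
  rather than as a 3D connected-component label for pure-R performance.
* **Savitzky–Golay** — degree 3, window 15, for both smoothing and the
  first derivative; uniform cadence is asserted. Edges are handled by
  evaluating the polynomial fitted to the first/last full window, so any
  cubic series passes through exactly, derivatives included. Series
  shorter than the window are rejected by name.
* **Dry-kink guard** — once a coordinate's raw thickness reaches zero,
  samples whose filter window straddles that scan are masked: the
  polynomial fit across the kink biases the rate low and the resistance
  correspondingly high.
* **Masking** — rates at the filter's numerical-noise floor, negative
  rates (non-physical, from noise) and driving pressures below 1 mPa are
  masked invalid, never returned as negative or infinite resistances. A
  fully masked vial is rejected with a diagnostic.
* **Interpolation** — natural cubic splines through populated bin
  centres, clamped to the nearest endpoint value outside the knot range;
  one knot degenerates to a constant, zero knots is an error for that
  coordinate. Interpolated resistances are floored at `rp_min`
  (default 1 m/s) before dividing.
* **Heat balance** — bisection on [180, 273.16] K to a residual of
  1e-9 W; chosen over Newton for guaranteed convergence inside the
  bracket at negligible cost.
* **Coefficient units** — in the parameter table of the source
  correlations, the vapour-pressure coefficient $\beta$ carries kelvin
  (so it enters as $\beta/T_i$), $\delta$ acts as 1/K, and the
  latent-heat $\epsilon$ is in K (squared inside the exponential);
  printed unit labels to the contrary are treated as typos.

# Known limitations

* No pore-scale modelling: $R_p$ lumps all microstructure; cracks appear
  as resistance drops, not as geometry.
* No secondary drying, choked-flow or Knudsen microscale model; no
  vial-to-vial batch simulation.
* The thermal module models temperature ramps phenomenologically (plateau,
  then a linear ramp toward the heater temperature) with i.i.d. noise and
  no emissivity/reflection radiometry; the rise-detection rule (smoothed
  forward difference exceeding the baseline's robust rate by K sigma,
  default K = 5, baseline = first quartile of the record) is this
  package's own pluggable policy — the source material does not specify
  one.
* On-disk interchange is plain text (CSV/JSON); volumes live in memory.
  TIFF/HDF5 bindings were unavailable in the build environment, and the
  module contracts do not depend on the container format.
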