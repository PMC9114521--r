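---
title: "Models and methods behind depmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind depmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depmech)
```

## The measurement this package models

Dielectrophoresis (DEP) stretches a polarizable cell trapped in a strongly
nonuniform AC electric field. An automated trap-array chip makes this a
population measurement: cells are hydrodynamically captured one per port,
stretched for a fixed interval by an AC voltage across micro-electrodes,
imaged at video frame rate, and released by reverse flow — cycle after cycle.
`depmech` implements the quantitative chain from dielectric parameters to a
per-cell Young's modulus, the device physics around it (electric field,
hydraulics, controller), and a synthetic data generator so the whole chain is
testable without hardware.

## Electromechanics

A homogeneous sphere of complex permittivity
$\varepsilon_p^* = \varepsilon_p - j\sigma_p/\omega$ in a medium
$\varepsilon_m^*$ has the Clausius–Mossotti factor

$$f_{cm} = \frac{\varepsilon_p^* - \varepsilon_m^*}
                {\varepsilon_p^* + 2\varepsilon_m^*},$$

whose real part lies in $[-1/2, 1]$ for any admissible parameters and sets
the sign (p-DEP vs n-DEP) and magnitude of the time-averaged force
$F = 2\pi r^3 \varepsilon_m \,\mathrm{Re}(f_{cm})\, \nabla E_{rms}^2$.
We adopt $\omega = 2\pi f$ (angular frequency), the standard convention in
the DEP literature. The sphere model is used throughout; ellipsoidal
depolarization factors and multi-shell (membrane/cytoplasm) models are out
of scope, as are electrorotation and AC electroosmosis.

The stretching stress on a trapped cell is parameterized as

$$\sigma_{stress} = n\, \mathrm{Re}(f_{cm})\, \varepsilon_m E_0^2,
\qquad n = \frac{|E|\, r\, \partial_x |E|}{E_0^2},$$

with $E_0$ a reference field strength (by default the applied voltage over
the smallest electrode gap) and $n$ the dimensionless geometric constant.
This definition of $n$ is the unique combination of the local field
magnitude, its gradient along the stretching axis, and the cell radius that
is dimensionless and yields a stress in Pa; equivalently
$\sigma_{stress} = \mathrm{Re}(f_{cm})\,\varepsilon_m\, |E|\, r\,
\partial_x|E|$. Young's modulus is $E = \sigma_{stress}/\varepsilon$ with
$\varepsilon$ the measured strain; a cell with non-positive strain is
reported unmeasurable, never as an infinite modulus.

Conductivities are handled in S/m internally; helpers convert the bench
unit µS/cm (`us_per_cm_to_s_per_m()`, factor $10^{-4}$). The default
dielectric parameters (medium $\varepsilon_r = 78$, $\sigma = 0.005$ S/m —
a 50 µS/cm isotonic sugar buffer; particle $\varepsilon_r = 60$,
$\sigma = 0.01$ S/m) are placeholders for user measurements, not fitted
values. With these placeholders the crossover frequency is ≈2.9 MHz and
the 12 MHz operating point sits in the n-DEP branch; intact cells, whose
effective high-frequency permittivity exceeds the dilute buffer's, show
p-DEP there. The operating point is a user input, chosen empirically in
practice.

## Field solver and the geometric constant

Commercial finite-element tools are the usual route to $n$; `depmech`
replaces that step with a 5-point finite-difference Laplace solve on a
uniform grid: Dirichlet conditions on rasterized electrode polylines,
second-order mirror (zero normal flux) conditions on the remaining outer
boundary, assembled sparse and solved directly (`Matrix`). The chip's
channel height is uniform (25 µm), so the electrode plane is treated in 2D.

Numerical behaviour, verified in the test suite: the discrete maximum
principle holds on every solve; a parallel-plate geometry reproduces
$|E| = V/d$ to machine precision; a coaxial-wedge geometry matches the
analytic $1/r$ field within 1% at a grid spacing of gap/50 (electrode
rasterization is the dominant error; it converges monotonically under
refinement but degrades the *gradient* of $|E|$ near the staircase rings,
so gradient evaluations should stay a few grid cells away from
electrodes). $n$ is voltage-invariant to $10^{-9}$ relative because the
discrete problem is linear. The demo geometry — two facing needle
electrodes across an 18 µm gap at 10 V — is illustrative only; no
reference value of $n$ exists to compare against, which is why the default
analysis calibrates stress from data instead (below).

## Device hydraulics

In the Stokes regime the channel network is an exact resistor-network
analogue. Per-segment resistances use the rectangular-duct series solution
(odd terms to $k = 99$; truncation error below $10^{-6}$ against a
$k = 9999$ oracle), which is symmetric in width and height and reduces to
the thin-slot limit $12\mu L / (w h^3)$ within 1% for $h/w = 0.01$.

The stated device geometry fixes the widths (100 µm main and bypass
channels, 25 µm height, 10 ports per side at 100 µm pitch, 6 µm narrow /
18 µm wide port mouths) but not the segment lengths outside the trap
region. The network defaults are therefore package choices, made once:

* ports staggered at half-pitch so each of the 20 ports occupies a distinct
  axial station (a shared station would force pairwise-equal pressure
  drops, contrary to the smoothly decaying per-port profile such devices
  show);
* entrance segment 300 µm and release-outlet channel 1300 µm, which puts
  roughly half of the inlet flow into the release outlet during capture;
* bypasses drain only at the downstream junction, which carries short
  (150 µm) channels to the waste outlet and buffer inlet, so the
  waste-outlet short circuit dominates release flow (the capture area takes
  ≈7% of buffer-inlet flow at default geometry);
* the trap channel is a wide 18 × 18 µm segment in series with a narrow
  6 µm segment of length 40 µm. The narrow-segment length is the one
  geometric default with a qualitative constraint behind it: for lengths
  below ≈40 µm the ports pass enough flow that the bypass channels develop
  tail pressure gradients steeper than the main channel's and the per-port
  pressure-drop profile stops decreasing monotonically along the array —
  contrary to the monotone decay expected from CFD studies of this device
  class. 40 µm is the shortest default that preserves the monotone profile.

With these defaults the first-port pressure drop at 3 µL/h is ≈2.6 Pa and
the last ≈0.5 Pa — the right order of magnitude (a few Pa, gentle enough
not to damage trapped cells) but not a quantitative CFD reproduction, which
would require the unpublished full geometry. Deflectors are modelled only
implicitly: they redirect local streamlines rather than adding appreciable
lumped resistance, so they do not appear in the network. A captured cell
blocks its port as an open circuit by default; a finite leak-resistance
multiplier is available because real cells seal imperfectly. Entrance/exit
losses and bends are neglected (low Reynolds number).

## Synthetic device and controller

The generator emulates what the instrument measures, not how it images:

* **Capture.** Each attempt round draws every empty port independently as
  empty / single / multiple. The 6 µm mouth uses the measured
  single-capture efficiency 0.842 as its default; the other mouth-size
  entries are qualitative placeholders. Multiple-occupancy ports are
  blocked but excluded from measurement. Draws are round-based rather than
  a continuous arrival process because the controller triggers on counts,
  not times.
* **Stretch response.** No creep law is published for these cells; the
  generator uses the simplest first-order saturating response
  $L(t) = L_0\,[1 + \varepsilon_{true}(1 - e^{-t/\tau})]$ with default
  $\tau = 2$ s, sampled at 50 fps for 10 s (501 frames inclusive), plus
  i.i.d. Gaussian frame noise (default sd 0.05 µm, sub-pixel detector
  jitter at ≈0.24 µm/px optics). Broken cells (default probability 0.02)
  emit a collapsing trace instead.
* **Populations.** True strains are lognormal (positive, right-skewed) with
  configurable mean and CV (default 0.35); initial lengths are normal
  (16 ± 1.5 µm, suspended-cell scale). The reference group means are
  0.0864 (normal) and 0.1013 (treated) for the endothelial pair and
  0.0684/0.0901 for the epithelial pair.
* **Controller.** A three-state machine — capture until the single-cell
  count reaches the threshold (default 10 of 20 ports; the count threshold
  is a tunable, the published design states no number), stretch for exactly
  10 s, release with per-cell efficiency 1.0 by default. The event log is
  append-only, one `capture → stretch → release` triple per cycle, and the
  run seed is recorded in it.

What passing tests on this generator do **not** show about real data: the
generator has no imaging pipeline (detection artifacts, occlusions), no
arrival kinetics (throughput depends on the attempt-period parameter, so it
is reported, never targeted), no viscoelastic spectrum beyond a single
$\tau$, and no dependence of capture probability on flow or cell size.

## Strain estimation and its bias

The definitional strain rule takes the minimum detected length as $L_0$ and
the maximum as the stretched length:
$\varepsilon = (L_{max} - L_0)/L_0$. It is order-free, scale-invariant, and
exactly recovers the truth for noise-free traces. Under additive frame
noise it is **positively biased**: the maximum over ~500 noisy frames
overshoots the plateau by roughly $s\sqrt{2\ln N}$ (noise sd $s$, $N$
frames near the plateau) and the minimum undershoots $L_0$ similarly. At
the default noise (0.05 µm on a 16 µm cell) the recovery harness measures a
bias of about +0.010 strain (+12% relative at a true mean of 0.0864), with
a first-order counterpart: the finite response time leaves a relative
shortfall of $e^{-T/\tau}$ (≈0.7% at $T = 10$ s, $\tau = 2$ s).

Because the min/max estimator cannot converge to the truth under fixed
noise, the package also provides a model-based estimator:
`fit_stretch_response()` fits the saturating response by linear least
squares in $(L_0, L_0\varepsilon)$ profiled over $\tau$ (golden-section
search on $\log\tau$). It is unbiased under the generator's noise model:
the recovery harness recovers group means within sampling error (standard
error ≈1% relative at $n = 1000$ per group with strain CV 0.35), against a
5% acceptance tolerance.
`analyze_traces(..., estimator = "minmax")` stays the default because it is
the definitional device rule; `end_to_end_recovery()` reports both side by
side so the bias is visible rather than hidden.

Quality control: traces collapsing below half (configurable) of their first
sample are flagged broken; zero/negative strains are flagged unmeasurable;
both are excluded from group statistics but itemized.

## Stress provenance and reporting conventions

Per-cell stress is not observable. Two modes are supported:

* **calibration mode (default):** $\sigma = E_{ref}\,\varepsilon_{ref}$
  from a reference (modulus, strain) pair. The two untreated reference
  populations give products agreeing to four significant figures
  (17.59968 Pa vs 17.59932 Pa), consistent with one shared device-level
  stress — which is why a single global stress, rather than a per-cell
  radius-dependent one, is applied to every cell.
* **physics mode:** $\sigma$ from `dep_stress()` with a solver-derived $n$,
  for what-if studies of electrode geometry and operating point.

Population reporting uses the mean, median, and the central 75% interval,
interpreted as the (12.5th, 87.5th) percentile band (`quantile()` type 7) —
an interpretation of the "75% confidence interval" box convention used in
deformability charts, documented as such. Interval-proportion histograms use
half-open bins of width 0.03 up to 0.18 plus an overflow bin. Reported
moduli are rounded to one decimal in Pa at the presentation layer only;
files carry full precision. Group comparisons are descriptive (deltas,
intervals, proportions); no significance test is bundled, since the choice
of test belongs to the analyst.

## Problem sizes and numerical settings

Defaults used by the shipped analysis scripts and test suite, chosen to
keep every stage interactive on a single CPU: field solves up to
roughly 320 × 160 nodes (direct sparse solve, residual tolerance
$10^{-8}$ relative); hydraulic networks of ~45 nodes solved densely with
Kirchhoff residuals below $10^{-10}$ of the inlet flow; simulation
campaigns of 30 cycles per group (~500 cells each); recovery studies at
$n = 1000$ per group; CM-factor sweeps of $10^5$–$2 \times 10^5$ random
parameter sets. The zero-crossing tolerance for regime classification is
$10^{-12}$ on $\mathrm{Re}(f_{cm})$; all stochastic components take a
single seed and restore the caller's RNG state.

## Known limitations

Sphere-only dielectric model; 2D field solve (no fringing in the channel
height); lumped hydraulics (no streamlines, no particle trajectories); a
single relaxation time in the synthetic stretch response; capture
probabilities independent of flow rate and occupancy history; release
efficiency as a parameter rather than a flow-rate model. These mirror the
boundaries of what the shipped data can constrain.
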