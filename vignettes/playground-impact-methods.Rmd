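---
title: "Methods: head-injury metrics and surrogate drop modelling for playground falls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: head-injury metrics and surrogate drop modelling for playground falls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(playfall)
```

# What the package computes

Playground impact-attenuation standards rate a surfacing material by
dropping an instrumented hemispherical headform onto it and requiring the
Head Injury Criterion (HIC) of the recorded acceleration to stay below
1000 (alongside a 200 g peak-acceleration cap). This package implements
the computational chain around that criterion for analysing head-first
falls of children:

1. **Signal conditioning and HIC** — zero-phase Butterworth filtering and
   exact windowed HIC maximisation of acceleration records.
2. **A reduced-order drop model** — a single-degree-of-freedom headform
   indenting a hysteretic rubber surfacing layer, with critical-fall-height
   search and family calibration.
3. **Tissue metrics** — the 95th-percentile peak principal Green-Lagrange
   brain strain (MPS) and peak von-Mises skull stress summaries of
   finite-element fields, with a 0.3-strain mild-TBI flag.
4. **Cross-age statistics** — direction aggregation, linear/exponential
   age regressions, the HIC-vs-MPS correlation and its inversion, and
   inverse-tissue-ratio scaling of HIC thresholds across ages.
5. **Synthetic data** — seeded generators reproducing the statistical
   structure of a fall-simulation campaign so the full chain is testable
   without finite-element inputs.

# Signal metrics

## Zero-phase filtering

Impact-test practice prescribes a 2-pole low-pass Butterworth filter run
once forwards and once backwards so the pass-band has zero phase lag: a
2077.5 Hz cutoff precedes HIC evaluation and a 180 Hz cutoff precedes
peak-kinematics extraction. `butterworth_filtfilt()` designs the biquad by
bilinear transform with frequency prewarping at the record's own sampling
rate, so a single pass is exactly −3 dB at the cutoff and the double pass
attenuates a cutoff-frequency sinusoid to half amplitude.

Rather than reproducing any particular reference coefficient listing, the
implementation is verified by its defining properties: unit DC gain (a
constant record passes through bit-exactly), half-amplitude at the cutoff,
and argmax preservation on symmetric pulses. Edge handling: the record is
extended by an odd (point-symmetric) reflection of `3 * order` samples at
each end and the filter state is initialised at the steady state of the
first extended sample, which suppresses startup transients on short impact
records; the extension is cropped before returning.

## HIC

For an acceleration record $a(t)$ in g,

$$\mathrm{HIC} = \max_{t_1 < t_2} \; (t_2 - t_1)
  \left[ \frac{1}{t_2 - t_1} \int_{t_1}^{t_2} a(t)\,dt \right]^{2.5},$$

with the window $t_2 - t_1$ capped at 15 ms (HIC15), 36 ms (HIC36) or
uncapped ("HIC unlimited", the playground standard's choice). `hic()`
evaluates the integral by the trapezoidal rule on a cumulative sum and
scans every admissible ordered sample pair on the stored grid — no
resampling, no heuristic pruning, so the maximisation is exact for the
stored samples. Numerical conventions:

* **Tie-break.** If several windows agree within $10^{-12}$ relative, the
  shortest window wins, and among equal lengths the earliest. An all-zero
  record therefore reports value 0 on the first single-step window.
* **Negative excursions** contribute to the windowed mean as-is; a window
  whose mean is negative scores 0 (fractional powers of negative means are
  undefined and such windows cannot be maxima of a true impact record).
* **Cost.** The pair scan is $O(n^2)$ vectorised over window lengths;
  traces fed to it are kept at ~20 kHz (see the drop model), where records
  of a few thousand samples evaluate in well under a second.

Because the HIC integrand is non-negative, widening a window cap can only
help: HIC15 ≤ HIC36 ≤ HIC unlimited, with equality whenever the achieving
window is shorter than the cap — which is why the three variants coincide
for stiff and baseline surfacing (window ≈ 3–8 ms) and separate only for
soft surfacing (≈ 14 ms).

# The reduced-order drop model

## Contact force

The full fall simulations this package post-processes use a
finite-element solver; the package's own drop model deliberately reduces
the headform test to one degree of freedom, which preserves the
quantities the standard cares about (acceleration history, HIC, critical
height orderings) at a cost of ignoring 3-D contact, friction and rate
dependence. The headform (mass $m$, default 4.6 kg as in the testing
standard; hemisphere radius $R$, default 0.08 m) indents the layer by $x$:

* layer strain $\varepsilon = x / \mathrm{thickness}$, stress
  $\sigma(\varepsilon)$ linearly interpolated on the material's loading
  table (linear extrapolation of the last segment beyond it);
* spherical-cap plan contact area
  $A(x) = \min\{\pi(2Rx - x^2),\ A_{\mathrm{cap}}\}$, clamped at the
  hemisphere equator for $x > R$ (the raw cap formula would shrink there);
* loading force $F = s\,\sigma(\varepsilon)\,A(x)$ with the family scale
  factor $s$.

Unloading of rubber/foam surfacing is hysteretic. It is governed by two
dimensionless parameters with solver-tradition names: the hysteretic
unloading factor `hu` (fraction of the loading force retained at full
unload; 0.5 by default) and the `shape` exponent (curvature of the
hysteresis loop; 2.0 by default). The exact unloading law of commercial
solvers is not published, so the package uses an energy-based form with
the same documented semantics: on unloading the loading force is
multiplied by

$$s_{\mathrm{unl}} = 1 - (1 - \mathrm{hu})\,(1 - W/W_{\max})^{\mathrm{shape}},$$

where $W(x)$ is the strain energy stored along the loading curve and
$W_{\max}$ its running maximum since first contact. The factor is 1 at the
unloading onset (force continuity) and tends to `hu` as the stored energy
drains. Reloading before separation follows the same factor until $W$
re-attains $W_{\max}$, keeping the force continuous and bounded. Because
the factor depends on $x$ only (through $W$), each contact cycle traces a
closed hysteresis loop whose enclosed area is the dissipated energy;
`hu = 1` recovers a perfectly elastic contact.

## Integration and audits

`simulate_drop()` integrates $m\ddot{x} = mg - F$ with classical
fixed-step 4th-order Runge-Kutta (default `dt` 1 µs; the hysteresis
memory $W_{\max}$ is frozen within a step) from first contact at the
free-fall velocity until the indentation returns to zero with upward
velocity. Degenerate inputs are handled explicitly: a zero impact
velocity returns the quasi-static rest state (contact force balancing
weight, zero net acceleration); indentation reaching the layer thickness
raises a classed "bottoming-out" error rather than extrapolating into a
regime the model does not represent; absence of separation within 200 ms
is a divergence error.

The reported acceleration is the net deceleration $(F - mg)/m$ in g —
zero at static equilibrium and indistinguishable from the accelerometer
reading $F/m$ for real impacts (1 g against peaks of 100–300 g). Every
run carries an energy audit ($\tfrac12 m v_{\mathrm{in}}^2 =
\tfrac12 m v_{\mathrm{reb}}^2 + \oint F\,dx$ within integration
tolerance; gravity does no net work over a cycle that starts and ends at
zero indentation) and an impulse record for momentum-balance checks.
Halving the default step changes HIC by well under 0.1%.

For critical-height and calibration searches the acceleration trace is
resampled to 20 kHz before filtering and HIC evaluation: the information
above the 2077.5 Hz conditioning cutoff is discarded by the filter anyway,
and the exact $O(n^2)$ HIC scan stays fast.

## The baseline material family and its geometry

Published loading curves of playground rubber composites are typically
available only as figures, while testing reports do print the material's
*critical height* — the highest drop height at which HIC stays within
1000. The package therefore ships a parametric loading-curve family and
anchors absolute levels to the critical-height observable:

* **Curve.** $\sigma(\varepsilon) = e_1 \varepsilon + e_3 \varepsilon^3$
  (defaults $e_1 = 1.2\times10^6$ Pa, $e_3 = 6.0\times10^5$ Pa): linear
  small-strain response with mild cubic stiffening. A strongly convex
  curve would be an inefficient absorber — force concentrated late in the
  stroke — which both raises HIC per unit of absorbed energy and pushes
  soft variants into bottoming; the mild convexity keeps the whole
  5×/0.2× stiffness ladder workable in one layer geometry.
* **Geometry.** Layer thickness 0.10 m with plan-area cap $\pi R^2$:
  thick enough that the 1/5-stiffness soft variant stops the headform
  within the layer over the full height range its own critical-height
  search probes (up to ~5 m), while the baseline still calibrates to a
  realistic tile-like critical height.
* **Calibration.** `calibrate_scale()` bisects on the logarithm of the
  stress scale until a drop from the target height yields the target HIC
  (default 1000) within 0.5%. A probe that bottoms out is interpreted as
  "too soft" so the bisection recovers. With the default coefficients the
  baseline family's critical height is 1.585 m — effectively the 1.59 m
  critical height of a common in-service tile — and the 5× / 0.2× scaled
  variants land near 0.89 m and 2.97 m, preserving the stiff < baseline
  < soft ordering and approximate magnitudes of measured rubber tiles
  (≈0.8 / 1.6 / 3.3 m). Exact reproduction of any particular tile's
  stiff/soft critical heights would require its tabulated curve, which is
  the one input this reduced model cannot invent.

`find_critical_height()` expands an upper bracket geometrically from
0.5 m until HIC exceeds the target, verifies the response is increasing
across the bracket, and bisects to a 5 mm height tolerance; bisection is
preferred over secant-type updates because each evaluation is a full
simulation whose small integration noise secant methods amplify. All
height–HIC probe pairs are returned (and included in diagnostic errors).
Height and velocity conversions use $g = 9.81\ \mathrm{m/s^2}$
throughout, consistent with the 1.59 m ↔ 5.59 m/s pair.

# Tissue metrics

`mps_95()` implements the brain-injury summary used in place of the raw
element maximum (which a handful of degenerate elements can corrupt): the
95th percentile over elements of each element's peak 1st principal
Green-Lagrange strain. Conventions fixed for reproducibility, since
percentile definitions differ across tools: time-maximum first per
element, percentile second over elements; linear interpolation between
closest ranks (rank $1 + 0.95(n-1)$ on the sorted values, R's quantile
type 7); no element-volume weighting. On the field $1,\dots,100$ the rule
gives 95.05. `peak_stress()` is the plain field maximum used for skull
von-Mises stress, and `mtbi_risk_flag()` compares an MPS value against
the 0.3 strain associated with a 50% mild-TBI risk.

# Cross-age statistics

`direction_difference_pct()` is $100(\max - \min)/\max$ over the
per-direction values of one metric. `average_over_directions()` reports
the per-age arithmetic mean with min/max retained as range error bars —
the range is used because with three directions per age any dispersion
statistic is equally arbitrary, and the range is what bar-with-whisker
campaign plots can be read back into.

`fit_vs_age()` fits $y = a + b\,\mathrm{age}$ by OLS or
$y = a e^{b\,\mathrm{age}}$ by log-linear initialisation followed by
Levenberg-Marquardt refinement; $R^2$ is always computed on the original
scale as $1 - SS_{\mathrm{res}}/SS_{\mathrm{tot}}$ so the two models are
comparable. The offset-free exponential is the simplest two-parameter
decay and matches the near-perfect exponential decrease of peak skull
stress with age (suture ossification); adding an offset would be
unidentifiable from the handful of ages available.

`hic_at_mps()` direction-averages HIC and MPS within each age, fits
$\mathrm{HIC} = a + b\,\mathrm{MPS}$ by OLS and evaluates at a strain of
interest (default the 0.3 mild-TBI threshold) — the construction that
maps a tissue threshold back onto the standard's HIC scale.

`scale_thresholds()` implements the inverse-tissue-ratio rule
$\mathrm{thr}(\mathrm{age}) = \mathrm{HIC}_{\mathrm{ref}}\cdot
\mathrm{tissue}(\mathrm{age}_{\mathrm{ref}})/\mathrm{tissue}(\mathrm{age})$:
equal tissue response across ages keeps the reference threshold, and an
age with twice the reference's response gets half the threshold. Published
age-dependent HIC values derived from skull-stress scaling do not come
with their exact arithmetic, so the rule here is the transparent ratio
form and the published numbers are context, not a reproduction target.

# Synthetic data: what it does and does not emulate

The generators provide seeded, bit-reproducible fixtures with the
*statistical structure* the analysis assumes:

* `generate_pulse()` — smooth unimodal impact pulses
  ($a(t) = \mathrm{peak}\cdot\sin^2(\pi t/\mathrm{duration})$ by default,
  10 ms at 20 kHz) with angular channels scaled by a direction rotation
  factor (low for front impacts, high for back/side) and optional
  Gaussian noise.
* `generate_table()` — per-age, per-direction campaign tables following
  $\mathrm{metric} = (\mathrm{intercept} + \mathrm{slope}\cdot
  \mathrm{age})\cdot\mathrm{offset}(\mathrm{direction}) + \mathrm{noise}$
  over ages 1.5–18. The default HIC and peak-acceleration lines are
  anchored so the zero-noise table reproduces the campaign extremes
  exactly (HIC 975.3 at 1.5-years back impact, 610.9 at 18-years side);
  a single-number `noise_sd` is relative (0.01 ≈ the tight scatter of
  near-linear campaign data — note the peak-acceleration trend is shallow,
  so this statistic is the most scatter-sensitive of the four).
* `generate_strain_field()` — lognormal element strains rescaled so
  `mps_95()` hits a requested target exactly.

What passing tests on these fixtures shows is that the *pipeline* is
correct: filters, maximisations, fits and searches recover known
generating parameters. What it cannot show is fidelity to real
finite-element fall data — actual waveform shapes, the nonlinear
age-dependence of real skull stress, volume effects in strain fields, or
any anatomy. Absolute tissue values and the published age-specific
threshold numbers require the full-body finite-element model and are out
of scope here.

# Problem sizes and budgets

The shipped test suite and the acceptance script run the drop model at
the default 1 µs step for end-to-end checks and at 5 µs for the
property-ladder unit tests (height and stiffness monotonicity,
calibration round-trips), with 20 kHz output traces throughout; synthetic
campaign tables use the default 7 ages × 3 directions. These sizes were
chosen so the full chain — including three critical-height searches —
completes in about a minute on a single core while every check retains
comfortable numerical margin (the 1 µs vs 0.5 µs HIC difference is below
0.1%).

# Known limitations

* One degree of freedom: no body coupling, no rotation, no friction —
  the drop model stands in for the headform *test*, not for a child's
  fall; rotational kinematics enter only through tables and fixtures.
* Rate-independent contact: viscoelasticity is not modelled; `hu` and
  `shape` capture dissipation only through the unloading path.
* The parametric loading curve is a family, not a measured material;
  absolute critical heights are meaningful only after calibration against
  a known anchor.
* `mps_95()` assumes the per-element time maxima are already computed;
  the package does not process displacement fields.
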