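# playfall

Head-injury metrics and surrogate headform drop modelling for playground
fall analysis.

## The problem

Playground surfacing is certified by dropping an instrumented
hemispherical metal headform (4.6 kg in the testing standard) onto the
material and requiring the Head Injury Criterion of the recorded
acceleration to stay below 1000, with peak resultant acceleration below
200 g, when dropped from the surface's *critical height*. Whether those
automotive-era thresholds actually protect a child's brain — and whether
one threshold can serve all ages — is an open question in pediatric
injury biomechanics. Answering it requires the computational chain this
package implements for researchers and test engineers:

* **Signal conditioning & HIC** — zero-phase 2-pole Butterworth
  filtering (2077.5 Hz before HIC, 180 Hz before peak kinematics) and
  exact windowed HIC maximisation,

  HIC = max over t1 < t2 of (t2 − t1) · [ (1/(t2−t1)) ∫ a(t) dt ]^2.5,

  with HIC15 / HIC36 / unlimited window variants, on acceleration in g.
* **Reduced-order drop model** — a single-degree-of-freedom headform
  indenting a hysteretic rubber layer (loading curve σ(ε), spherical-cap
  contact area, energy-based hysteretic unloading with `hu`/`shape`
  parameters 0.5/2.0), integrated by fixed-step RK4, with critical-height
  bisection and calibration of a material family to a target critical
  height.
* **Tissue metrics** — MPS (95th-percentile peak 1st principal
  Green-Lagrange brain strain, closest-ranks interpolation), peak
  von-Mises skull stress, and the 0.3-strain mild-TBI flag.
* **Cross-age statistics** — direction aggregation and difference
  percentages, linear/exponential age regressions with original-scale
  R², HIC-vs-MPS inversion, and inverse-tissue-ratio scaling of HIC
  thresholds across ages.
* **Synthetic data** — seeded generators for impact pulses, per-age
  campaign tables (anchored to HIC 975.3 at 1.5 years/back and 610.9 at
  18 years/side at zero noise) and strain fields, so the whole pipeline
  is testable without finite-element inputs.

See `vignettes/playground-impact-methods.Rmd` for the model details and
design rationale.

## Worked example

Drop the standard headform onto the baseline rubber-composite surfacing
from 1.59 m, condition the trace, and score it:

```r
library(playfall)

base  <- baseline_material()   # hu = 0.5, shape = 2.0, calibrated family
head  <- headform()            # 4.6 kg, R = 0.08 m
layer <- surface_layer()       # 0.10 m thick tile

r <- simulate_drop(head, layer, base, drop_height = 1.59, output_dt = 5e-5)
r
#> <drop_result> impact 5.59 m/s -> rebound 5.09 m/s, peak 133.2 g, max indentation 34.8 mm, contact 17.95 ms
#>   energy: in 71.75 J = returned 59.53 J + dissipated 12.22 J

hic(butterworth_filtfilt(r$accel, 2077.5))
#> <hic_result> HIC (unlimited) = 1006 over [0.00445, 0.0126] s (8.15 ms window)

find_critical_height(base, head, layer)
#> <critical_height_result> 1.585 m (HIC 1000.5 there; 13 evaluations; bracket [1.583, 1.586] m)
```

Reading the numbers: a 1.59 m fall impacts at 5.59 m/s (= sqrt(2·9.81·h))
carrying 71.75 J; the tile returns 59.5 J (rebound 5.09 m/s) and
dissipates the rest in its hysteresis loop. The 8.15 ms HIC window scores
1006 — right at the HIC = 1000 criterion, so 1.59 m is this material's
critical height (the bisection confirms 1.585 m) — while the 133 g peak
sits far below the 200 g cap: HIC is the binding criterion. Scaling the
stress curve ×5 (stiffer) or ×0.2 (softer) with `scale_material()` moves
the critical height to ≈0.89 m and ≈2.97 m respectively.

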