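# rtmscoil

Desk-scale design and validation toolkit for **miniaturized rTMS coils
for rodents**. Human-sized transcranial magnetic stimulation coils are a
poor match for a mouse head; designing a small coil means trading off
field strength, focality and Joule heating, and validating the design
means comparing simulated fields against measured ones. `rtmscoil`
implements that whole computational workflow in plain R, with tests:

* **Closed-form design stage** — Wheeler flat-spiral inductance
  `L = N²A²/(30A − 11Dᵢ)` (inch convention, µH), the spiral radius
  parameter `A = (Dᵢ + N(W+S))/2`, and the coil-centre flux density
  estimate `B = µ₀NI/(2R)`.
* **Magnetostatic solver** — exact circular-loop fields (complete
  elliptic integrals, AGM-computed) for circular and figure-8 loop
  stacks; plane field maps, distance sweeps, near-conductor clamping,
  and an independent segment-discretized Biot–Savart cross-check.
* **Focality metrics** — prominence-based peak counting and
  half-maximum (FWHM) area on observation planes.
* **Neumann partial-inductance** cross-check of the Wheeler estimate.
* **Layered murine head phantom** (scalp/skull/dura/arachnoid/brain)
  with the quasi-static induced field `E_φ = ω·A_φ` and an effective
  drive-frequency calibration.
* **Lumped thermal estimate** (DC resistance, duty cycle, convective
  steady state) for coil-safety orderings.
* **Synthetic Tesla-meter measurements** and the **one-way ANOVA
  panel** comparing human coil, mouse coil, simulation and measurement
  per stand-off distance.

## Worked example

```r
library(rtmscoil)

spec <- coil_spec()          # 7-turn murine spiral, Di 20 mm, 1000 A
design_report(spec)
#> <design_estimates>
#>   A = 21.2 mm, L = 2.084 uH, B = 0.4398 T (inner_radius)

w <- build_winding(spec)
neumann_self_inductance(w)   # independent partial-inductance route
#> [1] 1.931261

distance_sweep(w, c(0, 2, 5, 8, 10))
#>   distance_mm  peak_B_T
#> 1           0 0.4802020
#> 2           2 0.3106672
#> 3           5 0.2195269
#> 4           8 0.1722444
#> 5          10 0.1499716

comp <- compare_coils(spec, distance_mm = 5)
comp$circular$focality
#> <focality_report> 1 peak(s), max 0.2193 T at (-4, -8) mm, FWHM area 2484 mm^2
comp$figure8$focality
#> <focality_report> 2 peak(s), max 0.2279 T at (22, 0) mm, FWHM area 5004 mm^2

ph <- default_head_phantom()           # cortex 1.875 mm under the scalp
omega <- calibrate_drive(w, ph, 136.1452)
omega / (2 * pi * 1000)                # effective drive frequency, kHz
#> [1] 10.24131
induced_efield(w, ph, omega, depths_mm = 1.875)$E_V_per_m
#> [1] 136.1452

synth <- synthetic_validation_data(seed = 1)
distance_panel(synth$sets)
#> <comparison_panel>
#>    0 mm: omnibus p = 2.7e-19; human vs mouse p = 3.52e-10 *; sim vs meas p = 0.746 (n.s.)
#>    2 mm: omnibus p = 1.98e-26; human vs mouse p = 4.44e-14 *; sim vs meas p = 0.303 (n.s.)
#>    5 mm: omnibus p = 1.34e-17; human vs mouse p = 2.7e-09 *; sim vs meas p = 0.24 (n.s.)
#>    8 mm: omnibus p = 3.46e-18; human vs mouse p = 1.38e-09 *; sim vs meas p = 0.742 (n.s.)
```

Reading the numbers: the 7-turn spiral stores ~2 µH, produces ~0.44 T at
its centre and ~0.48 T at the wire surface, decaying to 31% of that at
10 mm. At a 5 mm plane it keeps a single focal spot while the figure-8
variant splits into two spots with twice the half-maximum footprint.
Calibrating the effective pulse frequency to the reference cortical
field (136.1452 V/m at 1.875 mm depth) lands at ~10 kHz — TMS pulse
content, not the 20 Hz repetition rate. The validation panel shows the
synthetic human coil dominating the mouse coil everywhere (p < 0.01)
while simulation and noisy measurement are statistically
indistinguishable (n.s. at every distance).

The end-to-end bundle (design report, maps, sweep, E-field profile,
measurements, statistics panel, `summary.json`) is produced by

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "rtms_out"))
```

or from a shell via the CLI launcher:

```sh
Rscript inst/cli/rtms.R run-all --seed 1 --out-dir rtms_out
Rscript inst/cli/rtms.R design --coil inst/extdata/mouse_coil.json
```

## Not in scope

MRI segmentation and anatomically realistic FEM meshes, commercial FEM
solvers, transient/FEM thermal simulation, pulse-circuit (capacitor
bank) modelling, and any real clinical device's internals (the "human
coil" is an explicitly synthetic generic figure-8 stand-in).
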