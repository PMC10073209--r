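---
title: "Methods: desk-scale modelling of a miniaturized murine rTMS coil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale modelling of a miniaturized murine rTMS coil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtmscoil)
```

## The problem

Repetitive transcranial magnetic stimulation (rTMS) coils built for human
heads are badly mismatched to mice: the head-to-coil size ratio is wrong,
the field is everything but focal on a ~1 cm brain, and a miniaturized
coil runs into resistance and Joule-heating limits. `rtmscoil` implements
the computational side of designing such a miniaturized coil — closed-form
design estimates, a magnetostatic field solver, focality metrics, a
layered murine head phantom for the induced electric field, a lumped
thermal estimate, and the statistical comparison of simulated against
(synthetic) measured fields — as a desk-scale, fully testable replacement
for the commercial FEM toolchain such a project would normally lean on.

The default coil is a 7-turn flat spiral: bore diameter $D_i = 20$ mm,
rectangular wire $W \times h = 3 \times 2$ mm, turn gap $S = 0.2$ mm,
outer diameter 65 mm, driven at $I = 1000$ A peak, 500 V, 20 Hz
repetition rate.

## Closed-form design stage

Three textbook quantities guide the design before any field is computed.

**Wheeler inductance.** For a flat spiral the empirical Harold Wheeler
formula is

$$L = \frac{N^2 A^2}{30A - 11 D_i}, \qquad
  A = \frac{D_i + N(W+S)}{2},$$

which yields microhenries when lengths are in inches. The formula's unit
convention is easy to get wrong; the package converts mm to inches
internally, because that is the only convention under which the result
(2.084 uH for the default coil) lands in the physically sensible range —
mm or cm units are off by orders of magnitude. Note $A \ge D_i/2$ by
construction, so the denominator $30A - 11D_i \ge 4D_i > 0$ for every
spiral that actually grows outward; the "non-physical geometry" error is
reachable only for degenerate negative-pitch inputs.

**Centre field.** The loop-stack estimate $B = \mu_0 N I / (2R)$ needs a
radius convention, since a spiral has no single radius. The package
defaults to the *inner* radius ($R = D_i/2 = 10$ mm, giving 0.4398 T for
the default coil): with the outer radius the estimate would be 3.25 times
smaller and inconsistent with the solver's near-field maximum. The
convention is recorded in every design report and selectable.

**Resistance/heating.** See the thermal section below.

## Field solver

Each turn is idealized as one filamentary circular loop at its centerline
radius $D_i/2 + W/2 + k(W+S)$; the rectangular cross-section survives
only through the geometric-mean-distance equivalent wire radius
$r_w = 0.2235\,(W+h)$ (used by the inductance formulas and the near-field
clamp). The field of a loop is evaluated with the exact off-axis solution
in complete elliptic integrals $K(m)$, $E(m)$; a straight-segment
Biot–Savart route is kept in the package as an independent cross-check
(the two agree to $10^{-4}$ relative in the tests). $K$ and $E$ are
computed by the arithmetic–geometric mean, because no elliptic-integral
package is available in the target environment; the AGM values are pinned
against `scipy.special` references to 14 digits.

Numerical choices:

* **Near-conductor clamp.** Filament fields diverge on the centerline;
  evaluation points closer than $r_w$ are projected radially onto the
  wire surface and counted in an `n_clamped` attribute. Consequently the
  solver's "surface maximum" at 0 mm stand-off is a wire-surface value,
  not an in-conductor FEM value.
* **Figure-8 geometry.** The figure-8 variant is two copies of the
  spiral with opposite current sign, laterally offset so the physical
  winding envelopes are exactly tangent (separation $2(a_{max} + W/2)$ =
  64.4 mm for the default lobe). The crossover region of a really wound
  figure-8 is not modelled.
* **Coordinates and units.** Coil plane $z = 0$, subject side $+z$; mm
  in every interface, tesla in every output.

### Focality metrics

The observation-plane comparison needs a peak count ("one focal spot or
two?") and a half-maximum area. A naive count of strict 8-neighbour grid
maxima above 50% of the global maximum fails here for a structural
reason: at a 5 mm plane the flat spiral's $|B|$ has a *shallow annular
maximum* (about 8% proud of the centre value), and a discretized annulus
yields a dozen strict grid maxima that are all the same physical focal
spot. The package therefore counts peaks by topographic prominence
(persistence): maxima above the 50% threshold are merged when the saddle
connecting them stays above 75% of the weaker maximum. The annulus
(saddle $\approx$ 99% of peak) merges to one spot; the two lobes of the
figure-8 map (saddle $\approx$ 60% of peak at the junction) stay
separate. The 25% relative-prominence threshold is the one free
parameter; any value between roughly 5% and 35% gives identical counts
for these maps.

`fwhm_area_mm2` is simply $\mathrm{spacing}^2 \cdot \#\{|B| \ge
\max/2\}$, with no smoothing.

### A known, deliberate red result

The filament model reproduces the qualitative coil comparison *except*
for one claim: that the circular coil's peak value exceeds the
figure-8's. In the filament idealization the opposite lobe's return flux
is strictly additive at the near lobe's maximum (outside a loop the
axial field reverses sign, and the lobes' polarities are opposite, so
the contribution aligns), which pushes the figure-8 peak a few percent
*above* the single spiral's — +3.9% at the 5 mm plane with tangent
lobes, decaying toward zero from above as the lobes separate, never
changing sign. The FEM-based claim plausibly reflects volumetric
conductors or an unstated drive difference. The acceptance test asserts
the claim as stated and is expected to fail; the regular suite documents
the model's actual behaviour (ratio in (1, 1.1]). Everything else in the
comparison — one focal spot vs two, and the much larger figure-8
half-maximum area — holds.

## Inductance cross-check

An FEM inductance extraction is emulated by partial inductances on the
same loop stack: per-loop self terms $\mu_0 a (\ln(8a/r_w) - 2)$ plus
all Neumann mutual terms for coplanar concentric loop pairs
(elliptic-integral closed form). For the default coil this gives
1.9313 uH — 1.3% below the reference FEM extraction (1.956 uH) and 7%
below Wheeler, comfortably inside the 15% band the acceptance criterion
allows for the method difference.

## Head phantom and induced electric field

The murine head is a 1-D stack of five quantified layers (thickness,
relative permittivity, conductivity): scalp 500 um, skull 1000 um, dura
300 um, arachnoid 75 um, brain 890 um, so the cortical surface sits
1.875 mm below the scalp. The published anatomical descriptions also
name subarachnoid space and pia; only the five quantified layers are
modelled, and the stack is user-extensible.

The computation uses the standard low-frequency TMS dosimetry regime:
tissue conductivities are far too small to perturb the coil field
(quasi-static), so $\mathbf B$ is the vacuum Biot–Savart field, and for
an axisymmetric coil the induced field is purely azimuthal with no
charge-accumulation term,

$$E_\varphi(\rho, z) = \omega\, A_\varphi(\rho, z),$$

with $A_\varphi$ the loop-stack vector potential (elliptic closed form)
and $\omega$ an *effective* angular frequency describing the pulse's
spectral content. Tangential-field continuity across layer boundaries is
automatic. The permittivities and conductivities are carried in the data
model (and validated) but do not enter this primary-field estimate —
zeroing them changes nothing, and the tests assert exactly that. At each
depth the magnitude is reported on the ring of maximal $|A_\varphi|$
(near $\rho \approx 21$ mm for the default coil), recorded in the
output.

**Why calibration instead of a default $\omega$.** The stimulation
repetition rate (20 Hz) cannot produce ~136 V/m at the murine cortex
with this coil — it is off by roughly three orders of magnitude — so the
effective source spectrum of the reference FEM run is unrecoverable from
its inputs. `calibrate_drive()` therefore solves the one-parameter
inverse problem $\omega = E_{target} / \max_\rho|A_\varphi|$; with the
reference cortical value 136.1452 V/m this lands at
$\omega \approx 6.4\times 10^4$ rad/s, i.e. an effective ~10 kHz —
squarely in the spectral band of real TMS pulses (~100 us rise times)
and a physically coherent resolution of the 20 Hz / 136 V/m tension.
The round trip (calibrate, then forward-evaluate) is exact by
construction and asserted to 4 significant figures.

## Thermal estimate

A deliberately lumped model: DC resistance from copper resistivity,
total loop circumference and the wire cross-section; $I_{rms} = I
\sqrt{duty}$; steady temperature $T = T_{amb} + P/(hA)$ with default
ambient 25 C, film coefficient 25 W/(m^2 K) and dissipation area
6e-3 m^2, both documented as *uncalibrated*. The published FEM
temperature pair (about 40 C at 500 A and 65 C at 1000 A over a 25 C
ambient) is mutually inconsistent with any purely quadratic rise
(15:40 vs 1:4), so the lumped model asserts orderings and scaling laws
only — $\Delta T \propto I^2$, figure-8 power $\ge 1.9\times$ circular
at equal drive — never absolute FEM temperatures.

## Synthetic measurements and statistics

The in vivo validation is emulated so the statistics stage is testable
without animal data. For each stand-off distance in {0, 2, 5, 8} mm
four groups are generated:

* `human_coil` — noisy readings around the field of a *synthetic*
  clinical stand-in (figure-8, two 70 mm lobes, 9 turns of 1.5 mm wire,
  5 kA; no real device's internals are modelled, and every output labels
  it synthetic);
* `mouse_coil` — noisy readings around the murine coil's plane peak;
* `simulation` — the model prediction itself (replicated, zero noise);
* `measurement` — noisy readings whose truth equals the simulation
  prediction.

Readings follow `truth * (1 + N(0, rel_sd)) + N(0, abs_sd)` with stated
defaults rel_sd = 5%, abs_sd = 1 mT, n = 5 replicates, all seeded and
bit-reproducible. These defaults are assumptions of the synthetic world
(the real replicate count and probe noise are unpublished), chosen once:
5% is a plausible gaussmeter-plus-positioning error, 1 mT a plausible
probe floor. What a green test establishes is therefore that the
*pipeline* reproduces the published significance pattern under a
realistic noise model — not that it reproduces the unpublished raw data;
exact in vivo p-values are out of reach by construction.

The ANOVA stage is the classical fixed-effects one-way decomposition
(explicit sums of squares, F and p from the F distribution; means
reported with standard errors), checked against `stats::aov` and the
$t^2 = F$ identity, with its type-I error calibrated by 2000 null
simulations. Degenerate all-identical input is defined as F = 0, p = 1.
The per-distance panel adds two uncorrected pairwise contrasts
(human-vs-mouse, simulation-vs-measurement) — no post-hoc correction was
specified for the original comparison, and the output flags the choice.
Under the defaults the panel reproduces the published pattern: human
vs mouse significant at every distance (the stand-in carries ~6x the
ampere-turns), simulation vs measurement non-significant at every
distance, and the non-significance is a stable property (>= 90% of 500
seeded repetitions), not a lucky seed.

## Pipeline, configs, CLI

`run_pipeline()` chains design → coil comparison → sweep → E-field →
synthetic measurements → statistics, writing CSV/JSON artifacts whose
headers carry the package version, an md5 of the config and the seed;
reruns with the same seed are byte-identical. JSON configs mirror the
interfaces (`inner_diameter_mm`, `conductivity_S_per_m`, ... — units
embedded in key names on purpose). `rtms_main()` exposes the
subcommands (`design`, `simulate-field`, `sweep`, `compare-coils`,
`induce-efield`, `thermal`, `synth-measure`, `compare-stats`,
`run-all`); `inst/cli/rtms.R` is a thin Rscript launcher.

## Known limitations

* Filamentary conductors: no volumetric current distribution, so
  in-conductor and wire-surface fields differ from FEM; the 0 mm
  stand-off "surface maximum" depends on the clamp convention.
* The induced-field closed form applies to axisymmetric windings only;
  figure-8 coils are deliberately routed to the map-based tools (a full
  non-axisymmetric E-field would need the charge-accumulation term).
* The thermal model is single-node steady state; no transients, no
  airflow.
* FEM-specific absolute values (in-tissue field tables, absolute
  temperatures) are not reproduced, only their trends, ratios and
  orderings — that boundary is asserted explicitly in the acceptance
  tests.
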