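# dtitherm

Finite-element bioheat modelling of heel deep tissue injury (DTI) for
dynamic infrared thermography.

Deep tissue injuries are pressure-induced lesions that start in muscle and
fat under intact skin, and become visible on the surface only at an advanced
stage. Because the early lesion is either ischemic (reduced perfusion and
metabolism — a cold anomaly) or inflamed (raised perfusion and metabolism —
a warm anomaly), its thermal footprint reaches the skin and can be imaged
with an infrared camera. `dtitherm` is for researchers in bioheat transfer
and thermographic diagnostics who want a reproducible forward model of that
footprint: it predicts how large the skin-surface temperature differences
are, where along the heel they appear, and how a short cooling stress
amplifies them.

## Model

The package solves the Pennes bioheat equation

$$\rho c \,\partial T/\partial t = \nabla\!\cdot k\nabla T +
\omega_b \rho_b c_b (T_b - T) + q$$

on a two-dimensional semi-elliptical heel cross-section with five soft
tissue layers (epidermis, papillary dermis, reticular dermis, fat, muscle;
0.46/1.67/1.67/5/2.5 mm) above a 37 °C muscle–bone interface. An elliptical
lesion (15 × 2.5 mm) is embedded at a configurable depth and carries
stage-dependent properties:

* **ischemia** — k = 0.1 W/m·K, ω_b = 0.405·10⁻³ s⁻¹, q = 342.1 W/m³, T_b = 35 °C;
* **inflammation** — k = 0.558 W/m·K, ω_b = 6.95·10⁻³ s⁻¹, q = 5262.5 W/m³;
* **multilayer** — ischemic core inside a 1.25 mm inflammation shell
  (mild), optionally extending to the skin surface (severe).

The simulated protocol mirrors dynamic IR thermography: (i) steady state
with convective exchange (h∞ = 12 W/m²K, T∞ = 22 °C) at the skin, (ii) 60 s
of 15 °C surface cooling, (iii) convective thermal recovery. Diagnostic
observables are the recovery curve at the sub-lesion skin point P, the
temperature profile along the heel periphery, and the lesion-minus-healthy
differences ΔT_isc and ΔT_inf.

The discretisation is linear (P1) triangular finite elements on a
deterministic boundary-fitted mesh (layer interfaces and the lesion outline
resolved by element edges), with sparse direct solves and backward-Euler
time stepping (Δt = 0.1 s during cooling and the first 5 min of recovery,
1 s after). See the methods vignette (`vignettes/heel-dti-thermography.Rmd`)
for the numerical choices and their verification.

## Worked example

```r
library(dtitherm)

pair <- run_scenario("ischemia", depth_mm = 8, cfg = protocol_config(t_end = 300))
pair$dti
#> recovery_result: stage=ischemia depth=8 mm, steady skin 31.82-32.34 C
#>   721 skin snapshots on t in [-60, 300] s (recovery clock)

d <- delta_series(pair$dti, pair$healthy, at = "P")
d$delta_C[d$t_s == 300]
#> [1] -0.5221075

ex <- profile_extremum(delta_series(pair$dti, pair$healthy, at = 210))
sprintf("largest signature at 3.5 min: %.3f C at l = %.1f mm", ex$delta_C, ex$l_mm)
#> [1] "largest signature at 3.5 min: -0.428 C at l = 44.8 mm"
```

Read: with an 8 mm deep ischemic lesion, the skin point below the lesion is
0.52 °C colder than healthy tissue five minutes after the cooling pack is
removed, and the strongest contrast at 3.5 min (−0.43 °C) sits at arc
coordinate 44.8 mm — directly beneath the lesion, inside the 35–55 mm
window a camera would monitor. Positive ΔT of similar build-up appears for
inflammation, so the sign of the anomaly separates the two stages.

A thin command-line tool is installed with the package
(`system.file("cli", "dtitherm", package = "dtitherm")`):

```sh
dtitherm simulate --stage ischemia --depth-mm 8 --out results/
dtitherm suite --config cfg.yaml
dtitherm show-config
```

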