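---
title: "Modelling heel deep tissue injury for dynamic infrared thermography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heel deep tissue injury for dynamic infrared thermography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dtitherm` computes skin-surface thermal signatures of deep tissue injury
(DTI) in the heel. Heat transport in perfused tissue is described by the
Pennes bioheat equation

$$\rho c \frac{\partial T}{\partial t} = \nabla\cdot k \nabla T +
\omega_b \rho_b c_b (T_b - T) + q,$$

in which conduction competes with a perfusion exchange term (blood enters at
arterial temperature $T_b$ and equilibrates with tissue) and a metabolic
source $q$. The equation is solved piecewise on a layered domain: each
tissue region is homogeneous with uniform thickness, properties are
temperature-independent, and temperature and normal conductive flux are
continuous across interfaces (automatic in our conforming single-field
discretisation).

The domain is a two-dimensional cross-section of the posterior heel: a
semi-ellipse cut by a flat top edge. Only the soft-tissue shell is
simulated — the five layers from epidermis to muscle, 11.3 mm in total. The
talus bone below is excluded and replaced by a fixed 37 °C condition on the
muscle–bone interface curve. This follows the boundary-condition reading of
the problem: with the core temperature pinned at that interface the bone
interior cannot influence the solution, so simulating it would only add
unknowns. The flat top edge carries a zero-flux condition (the lesion is
far from it and the dominant flux is radial); the skin arc exchanges heat
with ambient air by convection, $q'' = h_\infty (T - T_\infty)$.

A DTI lesion is an ellipse centred on the symmetry axis, major axis 15 mm
tangential to the skin, minor axis 2.5 mm. `depth_mm` is the depth of the
lesion *centre* below the skin surface: under the default layer
thicknesses this is the only reading for which the 8, 6 and 3.8 mm
scenarios intersect muscle+fat, fat alone, and fat+reticular dermis
respectively, which is how the scenarios are defined
(`classify_lesion_layers()` checks this). Stages:

* `healthy` — the lesion region inherits the enclosing layer's properties,
  making it thermally invisible. This is how matched baselines are built on
  the *same mesh* as the lesion run, so that reported ΔT values contain no
  mesh-difference noise.
* `ischemia` — degenerated tissue: low conductivity and density, reduced
  perfusion and metabolism, arterial supply at 35 °C.
* `inflammation` — hyperaemic tissue: raised conductivity, perfusion and
  metabolic heat generation.
* `multilayer_mild` — ischemic core surrounded by an inflammation shell of
  constant 1.25 mm thickness. The shell is the exact offset band of the
  core ellipse (points within 1.25 mm of the core boundary), not an
  enlarged ellipse, so its thickness is uniform as stated.
* `multilayer_severe` — as mild, with the inflamed region additionally
  spanning the normal-projection band from the core outline to the skin
  surface.

Blood density and specific heat do not appear in the published property
tables; we use $\rho_b = 1060$ kg/m³ and $c_b = 3770$ J/(kg·K), the
standard values in Pennes-equation modelling of skin, exposed under
`tissue:` in the configuration.

## Outer geometry

The outer heel dimensions are not part of the published parameter set. The
defaults, semi-axes $a = 27$ mm (horizontal) and $b = 30$ mm (vertical),
are fixed by two documented features of the reference setup: an 8 mm deep
lesion centre must sit 2.2 cm below the flat top ($b - 8\,\mathrm{mm}$),
and the apex must lie at arc coordinate ≈ 45 mm so that the sub-lesion
signature falls in the 35–55 mm periphery window. Both are configuration
parameters (`geometry:`), and the acceptance tolerances reflect this
residual geometric uncertainty.

## The protocol

`run_protocol()` performs the three steps of dynamic thermography:

1. steady state with the skin exposed to ambient conditions
   ($h_\infty = 12$ W/m²K, $T_\infty = 22$ °C);
2. cooling: the skin arc is held at 15 °C for 60 s (strong Dirichlet — a
   gel pack in a clinic), initialised from the steady field;
3. recovery: the convective condition is restored and the tissue rewarms,
   initialised from the end-of-cooling field.

The recovery clock puts $t=0$ at cooling removal; cooling snapshots are
stored at negative times. Skin-node temperatures are retained every 0.5 s
for the first five minutes and every 10 s afterwards — the observables are
minute-scale, so per-step storage would be wasteful.

## Discretisation and numerical choices

**Mesh.** The shell is meshed in normal-offset coordinates: columns are
inward normal rays of the outer ellipse at equally spaced arc lengths, and
each column carries nodes at every layer-interface depth plus the exact
intersections of the ray with the lesion (and shell) outlines, refined to
the target spacing. Adjacent columns are joined by a merge triangulation
that stays conforming when neighbouring columns carry different node
counts (near the lesion tips). Consequences worth knowing:

* layer interfaces and the lesion outline are resolved by element edges
  (piecewise linearly);
* the mesh is fully deterministic — the configuration keeps a `seed` field
  for interface stability, but no randomness is consumed;
* grid spacing is half the region's maximum element size, so every edge
  (including hypotenuses) respects the bound: 1.3 mm in epidermis, fat,
  muscle and lesion regions, 2.4 mm in the dermis layers, ≈ 4.8·10³
  triangles at defaults — the same discretisation scale as the reference
  solution;
* on tie-broken diagonals the orientation flips at the apex, so the
  triangulation and hence the discrete solution are mirror-symmetric.

**Solver.** Linear (P1) elements with consistent mass matrices; a lumped
variant is available (`lump = TRUE`) mainly for verification. Sparse
direct factorisation (Cholesky) is used throughout — at ~2.5·10³ unknowns
an iterative solver would be slower and add a tolerance parameter. Each
transient phase has a constant step and boundary-condition set, so the
system matrix is factorised once per phase. Time integration is backward
Euler with the reference schedule Δt = 0.1 s (cooling and first 300 s of
recovery) and 1 s afterwards; the scheme is unconditionally stable and the
test suite verifies that halving Δt changes five-minute skin temperatures
by less than 0.01 °C, so first-order accuracy costs nothing at this
resolution.

**Verification.** Three independent references back the solver, all run in
the test suite: the closed-form steady multilayer perfusion slab
(cosh/sinh profiles matched at interfaces; the FEM on a pseudo-1D strip
agrees to < 0.01 °C), the similarity (erf) solution for step cooling of a
deep conducting strip (< 2 % of the step amplitude at early times), and
hand-assembled P1 element matrices on a reference triangle. Energy balance
(volumetric input + interface inflow = convective loss) closes to 10⁻⁸
relative, and all stored fields respect the bounds set by the boundary and
source data (14.9–45 °C).

**Degenerate inputs.** A zero-size lesion reproduces the lesion-free mesh
exactly; a lesion touching the skin surface or the bone interface is a
geometry error; tangential ray–ellipse grazes shorter than 20 µm are
dropped to avoid sliver elements; configuration files are validated
against the default schema with unknown keys rejected and mm/m confusions
flagged.

## What the defaults do and do not show

The defaults reproduce the published study conditions: property tables,
protocol parameters, mesh sizes and the ten-scenario suite
(`study_scenarios()`). Within those conditions the model reproduces the
qualitative structure of the published results everywhere the test suite
looks: ischemia cools and inflammation warms the sub-lesion skin at every
depth and time in the five-minute window, shallower lesions give stronger
inflammation signatures, the severe multilayer lesion dominates all
responses, and transient imaging more than doubles the steady multilayer
contrast.

Quantitatively, the acceptance suite shows agreement at the 0.03–0.07 °C
level for the 8 mm and 3.8 mm ischemia signatures, the steady 6 mm ischemia
and 3.8 mm multilayer values, and the refinement criterion, while a subset
of reported values is not matched at the ±0.1 °C tolerance: the 6 mm
inflammation and late 6 mm ischemia values and the early multilayer
extremes. Two observations are relevant. First, the published 6 mm figures
are internally inconsistent: the same 0.41/0.7 °C pair is printed for both
the 6 mm and the 8 mm lesion in different places, and the depth-resolved
ΔT figures give 1.0–1.6 °C for 6 mm inflammation where the profile figure
text gives 0.7 °C; our computed 6 mm values agree with the depth-resolved
ranges, not the smaller ones. Second, the outer heel geometry is not
published, and source-driven (inflammation) anomalies are more sensitive
to it than conduction-driven (ischemia) ones. We therefore report these
discrepancies rather than adjust any parameter to absorb them.

A related dynamic difference: with the published layer properties and
$h_\infty = 12$ W/m²K, complete recovery (skin within 0.05 °C of steady)
takes ~37 minutes in this model, slightly longer than the 20–30 minutes
reported; the residual at 30 minutes is below 0.2 °C and the suite asserts
relaxation to within 0.02 °C by 60 minutes.

## Limitations

* Planar 2D cross-section: the lesion is effectively an infinite cylinder,
  which overstates its influence relative to a 3D ellipsoid; results are
  comparisons against a baseline computed under the same assumption.
* Piecewise-constant, temperature-independent properties; no vascular
  (discrete-vessel) effects; no ambient exchange at the flat top edge.
* Layer interfaces as constant-thickness offsets truncated at the flat
  top; patient-specific geometry is out of scope.
* The inverse problem — estimating lesion depth, size or perfusion from
  surface data — is deliberately not addressed.
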