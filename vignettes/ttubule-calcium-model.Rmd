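---
title: "Modeling Ca2+ entry, buffering and diffusion around a cardiac t-tubule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Ca2+ entry, buffering and diffusion around a cardiac t-tubule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcasim)
```

## The model

`ttcasim` simulates depolarization-evoked Ca2+ signals in a small
compartment of a rat ventricular myocyte: a 2 x 2 x 5.96 um box of
cytosol under the external sarcolemma, pierced by one branched
transverse tubule (t-tubule) that carries the membrane potential
5.645 um into the cell. The sarcoplasmic reticulum is assumed
pharmacologically silenced (ryanodine + thapsigargin), so the only Ca2+
sources and sinks are sarcolemmal: the L-type Ca2+ current (LCC), the
Na+/Ca2+ exchanger (NCX) and a background leak. Inside the cytosol,
free Ca2+ reacts with four buffers and diffuses:

* d[Ca]/dt = D_Ca lap[Ca] - sum_i R_i + boundary fluxes,
* d[CaB_m]/dt = D_m lap[CaB_m] + R_m for each mobile buffer
  (Fluo-3, ATP, calmodulin),
* d[CaB_s]/dt = R_s for the stationary buffer (troponin C),

with mass-action kinetics R_i = k_on,i [Ca]([B_tot,i] - [CaB_i]) -
k_off,i [CaB_i] (no cooperativity) and zero-flux conditions on the box
faces that represent neighbouring sarcomeres. Because Ca-bound and free
mobile buffer are assumed to diffuse equally fast, each total buffer
field stays uniform and only the bound form needs to be tracked.
Troponin C is excluded from a 45-nm sub-sarcolemmal shell (midpoint of
the reported 40--50 nm exclusion depth).

Concentrations are in uM, time in ms, length in um throughout; membrane
flux densities are in uM um / ms (amount per membrane area per time,
referred to the uM-um^3 amount unit).

## Membrane fluxes

The voltage protocol is a clamp: hold at -50 mV, step to +10 mV for
70 ms, 400 ms total. The +10 mV value interprets the reported "10 mV
pulse" as a step near the LCC current maximum; it is a constructor argument
(`voltage_protocol()`) and can be changed.

Three flux models act on the membrane:

* **LCC.** The whole-cell current density follows a double-exponential
  activation/inactivation template
  `-A (1 - exp(-t/4ms)) exp(-t/70ms)` during the pulse, with fast
  deactivation (tau = 1 ms) at repolarization. The closed-form template
  peaks at `4 ln(18.5) = 11.67` ms. The amplitude `A` is a calibrated
  free parameter: `calibrate_lcc_amplitude()` bisects on the well-mixed
  model until the dye-present global Ca2+ peak equals the measured
  163 nM. (The underlying whole-cell current trace is published only as
  a figure, so the template + calibration reconstruct it.)
* **NCX.** The canonical electrochemical exchanger formulation with
  pump rate 38.5 uM/ms, eta = 0.35, K_Na = 87.5 mM, K_Ca = 1380 uM,
  k_sat = 0.1; [Na+]_i fixed at 10 mM. At rest (-50 mV, 0.1 uM Ca) it
  extrudes ~1.7e-3 uM/ms; during the pulse it reverses into entry mode.
* **Leak.** A phenomenological conductance `g_leak (E_Ca - V)`. The
  conductance is always recalibrated at initialization so the leak
  exactly cancels the resting NCX flux (`calibrate_rest_leak()`); with
  140 mM external Na+ this gives g_leak > 0, with 0 mM (NCX forward-mode
  inhibition) the exchanger becomes a pure entry pathway and g_leak
  turns negative, so the leak extrudes. The reference conductances
  (+3.4e-6 / -6.8e-6 uM/mV/ms) share these signs; their magnitudes
  imply a ~3x smaller resting NCX flux than the canonical formulation
  evaluated here, which the calibration absorbs.

Current densities (pA/pF) convert to volume-referred fluxes via the
capacitance-to-volume ratio 8.8 pF/pL: `J = -I * 8.8 / (2 * 96.5)`
uM/ms, so -1 pA/pF is +0.0456 uM/ms of Ca2+ entry.

### Spatial distribution scenarios

The whole-compartment flux of each component (flux times compartment
volume) is spread over the membrane facets by `build_boundary_flux()`
under three LCC scenarios: (1) *heterogeneous*: the t-tubular share of
the LCC flux follows a cubic polynomial in depth
`C (p1 x^3 + p2 x^2 + p3 x + p4)` (weight rising 1.67-fold from mouth
to terminus) while the tubule-vs-external budget stays at the 6:1
(by area) split of case 2 -- the polynomial redistributes the t-tubular
total without changing it; (2) *uniform 6x*: uniform densities, six
times higher on the t-tubule membrane; (3) *homogeneous*. NCX density
is 3x t-tubular in cases 1--2 and uniform in case 3; the leak is always
uniform. Every scenario preserves each component's compartment total at
matched uniform Ca2+; NCX and leak densities are evaluated with the
facet-local Ca2+.

An earlier reading of scenario (1) -- applying the polynomial to the
external membrane as well, which gives the external surface nearly the
same density as the tubule mouth -- contradicts both the 3--9x
t-tubular LCC concentration reported by immunolabeling and the stated
constraint that redistribution leaves the t-tubular total unchanged,
and it reverses the observed heterogeneity ordering; the budget-
preserving reading above is therefore used.

## Rapid-buffer effective diffusion

For small Ca2+ elevations the buffered diffusion collapses to a single
effective coefficient (computed by `effective_diffusion()` in the
Ca -> 0 linearization, beta_i = B_tot,i / K_d,i):

D_eff = (D_Ca + sum_mobile D_i beta_i) / (1 + sum_all beta_i).

With the default parameters this reproduces the four reference
estimates: ~8 um^2/s (calmodulin + troponin C at D_Ca = 390 um^2/s),
~5.9 at D_Ca = 223, ~10.4 adding ATP, and ~66 adding 100 uM Fluo-3 --
the dye is a major Ca2+ carrier. Evaluating beta at 0.1 uM instead
of 0 changes the values by well under the reporting precision; the
Ca -> 0 choice matches the reference values best and is used.

## Synthetic geometry

The imaging-derived mesh of the original compartment is not available,
so `generate_ttubule_mesh()` builds a synthetic stand-in calibrated to
the same morphometry: compartment volume ~23.31 um^3, membrane area
~9.00 um^2, 64% of it t-tubular, tubule depth 5.645 um, and tubule
diameters spanning the measured 0.19--0.469 um. (The measured range is
printed once as a "radius" and once as a "diameter"; only the diameter
reading is geometrically consistent with the printed area and volume --
radii that large would alone exceed the whole t-tubular area -- so the
default trunk radii are 0.095--0.155 um.) Reproducing an external
membrane of ~3.25 um^2 on a flat 2 x 2 um top face forces a mouth
opening of ~0.75 um^2, which the generator realizes as a funnel-shaped
mouth vestibule flaring to a 0.49-um radius at the surface; t-tubule
openings are indeed funnel-like, and the funnel wall carries the
t-tubule membrane label.

The tubule is a tree: a trunk wandering slightly about the depth axis
with linearly tapering radius, plus closed side branches (their end
caps carry the t-tubule label; their area is small). The cytosolic
domain (box minus lumen) is meshed by carving a structured box grid
(six tetrahedra per cube, conforming Kuhn decomposition) along the zero
level set of the tubule's distance function: vertices within 0.22 h of
the wall are projected onto it (vertices on box faces only move within
their face), crossed tetrahedra are subdivided marching-tetrahedra
style with neighbour-consistent diagonals, and boundary facets are
labeled external_membrane (top face), ttubule_membrane (carved wall,
caps included) or reflective (other box faces). The same spec and seed
give bit-identical meshes. Meshes are exchanged as Gmsh MSH 2.2 or
legacy VTK.

At the default resolution (h = 0.07 um) the shipped spec measures
volume ~23.4 um^3, membrane ~9.1 um^2 and t-tubular fraction ~64.3%;
between h and h/2 the statistics move by well under 2%. What this
generator does *not* emulate: the irregular cross-sections, local
dilations and multi-generation branching of real t-tubules, and any
realistic surface texture of the sarcolemma. Statistics tied to those
features (notably the magnitudes of spatial-heterogeneity fold changes
between flux scenarios) are therefore treated as directional, not
numeric, targets.

## Numerics

Space: P1 finite elements on the labeled tetrahedral mesh with a lumped
mass matrix (positivity-friendly); membrane fluxes enter as Neumann
loads (one third of the facet flux to each facet vertex). Time:
first-order operator splitting per step dt -- (i) implicit
(backward-Euler) diffusion for Ca2+ and each mobile complex, with one
sparse Cholesky factorization per species reused across all steps;
(ii) an implicit reaction substep solved per node: given the node's
conserved total, each complex's backward-Euler update is a rational
function of free Ca2+, so the coupled 5-species system reduces to one
monotone scalar equation solved by vectorized Newton iteration to
1e-13. The substep conserves free + bound Ca2+ per node exactly, and
the diffusion step adds exactly dt times the boundary load, so global
mass is conserved to solver precision (`check_conservation()` verifies
the wiring; observed drift ~1e-13 relative).

The default step is dt = 0.1 ms. The reference computation used 4-ms
output snapshots; reaction stiffness (ATP unbinding at 45 /ms) makes a
4-ms *integration* step inadequate, so 4 ms is treated as an output
stride, not a solver step. Halving dt from 1 to 0.5 ms changes the
global peak by well under 1% (tested). Stability is unconditional
(backward Euler); the explicit treatment of the Ca-dependent boundary
flux is benign at these flux magnitudes.

The 0-D reduction (`run_0d()`, stiff `lsoda`) integrates the volume-
averaged system; on a homogeneous-scenario cylinder mesh it matches
the 3-D volume average within 5% at every output time, which is the
cross-validation used for the LCC amplitude calibration.

A note on the global time-to-peak: in this model the free-Ca2+
transient peaks at 70 ms, the end of the depolarizing pulse (both in
0-D and in the 3-D branched run). The reason is kinetic: during the
rapid rise the buffers lag behind equilibrium and absorb Ca2+ at
almost the influx rate, so the moment the LCC tail decays (tau = 1 ms
deactivation) and NCX flips to efflux, d[Ca]/dt turns negative. The
reference computation, which stepped the solver at 4 ms, reports the
peak a few milliseconds later (~76 ms); a continuous-time integration
of the same equations does not reproduce that lag, and we report the
faithful 70-ms value rather than emulate the coarse-step artifact.

Degenerate inputs: the generator rejects grids that do not resolve the
minimum tubule radius (h > r_min), tubules that leave the box, and
meshes with degenerate elements; the scan-line extractor rejects lines
that exit the cytosol; SCH is undefined when the maximal value is zero.

## Analysis statistics

`extract_linescan()` samples a field along a straight line parallel to
the depth axis, offset 200 nm outward from the tubule at a chosen
azimuth (the reference line uses 120 degrees). Because the published
description of the scanned line is schematic, the construction is
parameterized; the line sits at (mouth radius + offset) from the tubule
axis, which keeps it at least the offset away from the wall at every
depth. Spatial Ca2+ heterogeneity is
`SCH(t) = (max - min) / max` over fixed reference spots (0.17, 3.09,
5.45 um) -- scale-free, in [0, 1]. `detect_front()` reports a
propagating front when first-crossing times increase monotonically over
at least 1 um of depth; the default threshold used in the scenario
comparisons is 0.2 uM, i.e. a 100% elevation over the 0.1-uM resting
level (the conventional wave criterion). The initiation verdicts are
insensitive to the exact threshold over 0.2--0.3 uM, where the
dye-loaded scenario never reaches threshold while the
immobilized-buffer and zero-Na+ scenarios initiate and falter.

## A worked comparison

```{r scenarios, eval = FALSE}
# coarse, fast variant of the compartment for a desk-scale comparison
mesh <- generate_ttubule_mesh(
  ttubule_spec(radius_min = 0.14, radius_max = 0.20,
               branch_radius = 0.16), 0.14)
amp <- calibrate_lcc_amplitude(0.163, simulation_config())
ov <- list(dt = 1, output_every = 10, duration = 250,
           lcc_amplitude = amp)
het <- run_scenario("fig4_heterogeneous", overrides = ov, mesh = mesh)
hom <- run_scenario("fig4_homogeneous", overrides = ov, mesh = mesh)
subset(het$sch, epoch == "t_ca_peak")$sch  # ~0.10
subset(hom$sch, epoch == "t_ca_peak")$sch  # ~0.30
```

With 100 uM Fluo-3 the heterogeneous distribution yields the flattest
profiles (SCH at the Ca2+ peak ~0.10 on this coarse mesh), uniform-6x
is intermediate and fully homogeneous distribution the most
heterogeneous -- the ordering found with the imaging-derived geometry.
Removing the dye raises SCH severalfold; immobilizing CaATP/CaCal or
removing external Na+ steepens sub-sarcolemmal gradients enough to
initiate a (faltering) Ca2+ wave at the outer edge.

## Problem sizes used by the shipped checks

Geometry calibration and the reported morphometry use the default spec
at h = 0.07 um (~90k elements; seconds). The scenario property
comparisons run on a thickened coarse branched variant (h = 0.14,
dt = 1 ms, 250 ms) and a coarse cylinder (h = 0.18), chosen as the
smallest problems on which the directional effects are stable; the
calibration and transient targets use the 0-D reduction, where the
spatial distribution is irrelevant.

## Known limitations

* Flux pathways are continuous densities; discrete LCC clusters in
  dyadic clefts (and any SR release) are out of scope, as in the
  reference model.
* [Na+]_i is constant; sub-sarcolemmal Na+ gradients would modulate
  NCX.
* The synthetic tree reproduces aggregate morphometry, not the true
  branch topology; SCH fold magnitudes are geometry-dependent.
* The dye is modeled purely as a buffer (CaFluo as fluorescence proxy);
  no photophysics or point-spread-function convolution.
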