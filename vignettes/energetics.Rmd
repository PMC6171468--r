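---
title: "Methods: the NGV energy-metabolism model and mesh morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NGV energy-metabolism model and mesh morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and philosophy

`gliaflux` couples two things that are usually studied apart: a
*compartmental reaction model* of brain energy metabolism in the
neuro-glio-vascular (NGV) unit, and a *geometric quantification suite* for
the reconstructed ultrastructure (meshes of neurites, astrocytes,
organelles; glycogen granule point sets) in which that metabolism happens.
The package is deliberately self-contained: a synthetic-data module
generates every input the analysis modules consume, so the full pipeline is
testable offline and all quantitative claims in the test suite are
recomputed, never quoted.

The model is a lumped architecture, not a calibrated replica of any
measured tissue: it reproduces a described *structure* (compartments,
species, transporters, signaling links) with canonical rate-law forms and
one documented, physiologically plausible default parameter file.  No
default is asserted as biological truth; every parameter is named,
unit-tagged and overridable from TOML.

## The metabolic unit

### Compartments and state

Four well-mixed compartments share a tissue volume: neuron (`v_n` = 0.45),
astrocyte (`v_a` = 0.25), extracellular space (`v_e` = 0.20) and capillary
(`v_c` = 0.10).  Each cell type x tracks `Na_x`, `GLC_x`, `G6P_x`, `PYR_x`,
`LAC_x`, cytosolic and mitochondrial NADH, `ATP_x`, `PCr_x`, `O2_x`; the
astrocyte adds glycogen (`GLY_a`, glucosyl units) and `cAMP_a` (µM); the
ECS carries `GLU_e`, `GLC_e`, `LAC_e`; the capillary `GLC_c`, `LAC_c`,
`O2_c`.  Units are mM and seconds throughout (cAMP in µM); lengths are µm.

Four moiety pools are conserved *by construction*: ADP, cytosolic and
mitochondrial NAD⁺, and creatine are derived (`A_tot − ATP`,
`N_tot − NADH`, `C_tot − PCr`), never integrated.  A drift in these pools
is therefore impossible rather than merely small — the conservation report
asserts the stored half stays inside `[0, total]`, which is the substantive
numerical check.

### Rate laws

* **Reversible carriers** (GLUT glucose, MCT lactate) use the symmetric
  saturable form `T (S1/(S1+K) − S2/(S2+K))`, which is exactly zero at zero
  gradient and odd under exchange of the two sides.
* **Hexokinase–PFK lump**: linear in saturated glucose, Hill-inhibited by
  ATP (`K_I_atp` = 1 mM, `n_H` = 4) with a small ATP substrate term so the
  rate vanishes when ATP does.  The strong Hill feedback is the model's main
  homeostat: an ATP dip disinhibits glycolysis within seconds.
* **Lower glycolysis**: `G6P → 2 PYR` with +2 ATP and +2 cytosolic NADH,
  saturable in ADP and NAD⁺.  Together with the 1-ATP hexokinase cost the
  glycolytic lump yields a net +1 ATP per glucose and +2 per glucosyl unit
  entering from glycogen — the glycogen shortcut is what makes the reserve
  worth paying for.
* **LDH** and **creatine kinase** are mass-action reversible; the
  neuron/astrocyte asymmetry is purely parametric: the astrocyte's
  forward/backward ratio (20 000) leans toward lactate production, the
  neuron's (1 667) toward lactate consumption, per the design decision that
  cell differences live in parameters, not structure.
* **Mitochondria** are two lumped fluxes.  The *pyruvate lump* burns 1 PYR
  with 3 O2-equivalents and yields `n_atp_ox` = 14.8 ATP, saturating in
  PYR, O2, ADP and mitochondrial NAD⁺ (the TCA electron acceptor); the NADH
  it generates internally is consumed internally.  A separate
  *electron-transport term* re-oxidizes the mitochondrial NADH delivered by
  the cytosolic shuttle (2.5 ATP and ½ O2 per NADH).  The split is a
  deliberate repair of a latent inconsistency: if a single lump both rises
  with NAD⁺ and consumes shuttle NADH 1:1 with pyruvate, the pyruvate,
  cytosolic-redox and mitochondrial-redox balances cannot vanish
  simultaneously except on the `NADHm → 0` boundary, and no interior
  resting state exists (we observed exactly this failure mode numerically:
  runaway pyruvate and a singular Newton Jacobian).  With the split, the
  resting state is an isolated, well-conditioned fixed point and the
  contracts "rate has an NAD⁺ factor", "mitochondria re-oxidize NADHm" and
  "J_mito = 0 when O2 = 0 or PYR = 0" all still hold.
* **Na/K ATPase** consumes 1 ATP per 3 Na (`k_pump · ATP · Na`), balancing
  a linear Na leak, AMPA-gated Na influx in the neuron (proportional to
  extracellular glutamate) and the 3-Na-per-glutamate EAAT load in the
  astrocyte.  This is the chain that converts synaptic activity into energy
  demand.
* **Glycogen**: synthase is saturable in G6P and capacity-limited by
  `(1 − GLY/GLY_max)`; phosphorylase is activated by cAMP, which is driven
  by noradrenaline and degraded first-order.  The capacity factor and a
  small basal cAMP production are additions to the stated rate laws: without
  them glycogen has no resting steady state at all (synthase on,
  phosphorylase off, unbounded growth).  Both are ordinary, documented
  parameters.
* **Capillary** species relax toward arterial values at rate `CBF · F_0`;
  cerebral blood flow enters only as this dimensionless multiplier — there
  is no neurovascular coupling mechanism, by design.
* **Glutamate** in the ECS gains the release drive, loses EAAT uptake
  (reduced by the recycling fraction `f_glu_recycle` = 0.5, standing in for
  the glutamate–glutamine loop we do not model) and a first-order decay.

Every trans-membrane flux is expressed in the receiving compartment's
volume frame and converted with `v_B/v_A` factors at the donor; the frame
table lives in one place (the header of `R/metabolism.R`).

### Rate-law positivity

Every unidirectional term carries a factor that vanishes with its
substrate (including small-K saturable factors on ATP where ATP is
consumed), so species cannot cross zero under exact integration.
Numerically, the integrator raises an error — it never clamps — if a
species falls below `−atol`; silent clamping would hide exactly the
stiffness bugs this design wants to surface.

### Default parameters

The defaults target resting-tissue plausibility at the order-of-magnitude
level: resting glycolytic flux ≈ 0.005 mM/s per cell, neuronal ATP turnover
≈ 0.2 mM/s dominated by the pump, lactate around 1 mM with the gradient
astrocyte > ECS > neuron, glycogen near 8 mM glucosyl against a 12 mM
capacity, resting ECS glutamate tens of nM.  The resting state itself is
*solved*, not assumed: parameters are fixed first, then the 28-dimensional
root is found.  Both the documented initial guess and the solved state are
persisted in `inst/extdata/default_params.toml`, and a test re-verifies the
persisted state against the current model.

## Electrical activity

The activity module is the classic squid-axon Hodgkin–Huxley membrane
(120/36/0.3 mS/cm² conductances) with one twist: `E_Na` is recomputed every
step from intracellular Na through the Nernst equation, so a metabolic
state with Na loading depolarizes the sodium reversal.  `E_K` is a constant
by default — extracellular K is not a tracked species — with a flag to
derive it from fixed K concentrations instead; tracking only what the state
vector houses avoids inventing dynamics for untracked pools.  Spikes
(upward 0 mV crossings) are converted to glutamate release by a normalized
exponential kernel (`q` per spike, `tau_rel` = 2 ms), the simplest
transient whose integral is exactly `q`; transients superpose.  Forward
Euler at `dt ≤ 0.025` ms is the standard discretization at this step size,
and the suite checks spike times against an independent RK4 oracle.

## Voxelized simulation

Release events `(t, x, y, z, q)` are binned into half-open cubic cells
(`floor((pos − origin)/h)`, boundary to the higher cell) — a true
partition, so quanta are conserved exactly by construction.  Each voxel
then runs an *independent* metabolic unit; nothing is exchanged between
voxels by default because the tiled description this emulates states no
exchange.  A flag enables an exploratory explicit-Euler diffusion pass for
ECS species between face neighbors (stability-guarded at `D·dt/h² ≤ 1/6`),
covering the plausible intent without changing the default's letter.
Voxel independence makes the grid result bit-identical to running the
units separately, which the acceptance suite asserts literally
(`identical()` on a 2×2×2 grid vs 8 unit runs).  Snapshots default to
10 ms; volumes export as ASCII-encoded NRRD with a JSON sidecar (species,
times, normalization, parameter hash).

## GLAM and morphometrics

Glycogen granules are treated as isotropic emitters with
volume-proportional power `P = k (4/3) π r³` (the power law is a modeling
choice; `k` is configurable).  The analytic map deposits
`P cosθ / (4π d²)` per vertex with an optional binary ray-cast visibility
against a configurable occluder set — by default everything except the
granules' host membrane, since granules are intracellular and their
"light" must exit the host.  The Monte Carlo mode emits isotropic photons,
deposits each at the nearest vertex of its first hit and divides by the
barycentric one-ring vertex area; its expectation is the unoccluded
analytic irradiance, and per-vertex standard errors come with the map.

A statistical note that the test suite encodes: with ~360 vertices checked
simultaneously, demanding *every* Monte Carlo z-score inside 3 SE would
fail a perfectly correct sampler in most runs (0.997³⁶⁰ ≈ 0.34).  The
acceptance check therefore requires ≥ 98% of vertices within 3 SE *and*
the region total within 3 SE — the multiple-comparison-aware reading of
"agrees within 3 standard errors", not a loosened one.

Morphometrics are exact Euclidean point/segment/triangle computations, not
geodesics: granule tallies assign each granule to the mesh of minimum
point-to-surface distance (ties to the lower object id); contact area sums
triangles of mesh A whose centroid lies within ε of mesh B (asymmetric by
convention, monotone in ε, and matched against an exhaustive no-pruning
scan in the tests); minimum surface distance refines a vertex-stage bound
with exact triangle–triangle distances on bounding-box-screened pairs;
cross sections chain triangle–plane segments into closed loops (watertight
input required) and report area and perimeter.  Loop areas are summed as
absolute values per loop, which is correct for disjoint lobes and convex
organelles but would overcount a nested (annular) section — a known
limitation.

## Synthetic data: what it does and does not emulate

`make_neuropil()` builds a miniature neuropil: axons and dendrites as
capped tubes, boutons and spines as spheres attached to parent tube
surfaces, and an astrocyte as a multi-component mesh of disjoint spheres.
(A true union of *overlapping* spheres would need a boolean/marching-cubes
kernel; disjoint components keep every mesh watertight with none of that
machinery.)  All generators draw from private seeded RNG streams — global
RNG state is saved and restored around every draw — so scenes are
byte-reproducible and never perturb a caller's randomness.

`scatter_granules()` *plants* a nearest-class distribution: with
probability `p_bouton` a granule is rejection-sampled until it lies
strictly nearest a bouton, otherwise nearest a uniformly chosen other
class, and the planted truth table is returned.  Because placement verifies
the exact nearest-mesh condition, the tally recovers the plant by
construction; what the green test establishes is therefore that the
*analysis* (distance kernels, tie-breaks, tallying) is faithful — not that
real glycogen is polarized.  The generators emulate geometry and sampling
statistics only: no biophysically realistic morphologies, no EM noise, no
segmentation artifacts, and mesh interpenetration between distinct objects
is not prevented (each mesh is individually clean).

Default granule radii (0.01–0.04 µm) are a plausible β-granule scale,
configurable and not asserted as biological truth.

## Numerical choices

* **Integrator**: Dormand–Prince 5(4), embedded error with *max-norm*
  control (`rtol` 1e-6, `atol` 1e-9), PI-free step adaptation with safety
  0.9, exact landing on the output grid (no dense-output interpolation), so
  trajectories are bit-reproducible and schedule-independent.  The model's
  fastest default time constants are ~1 ms (glutamate clearance, LDH), well
  inside explicit-method territory; no implicit solver is shipped.  The
  suite holds the adaptive result to within 1e-4 (scale-relative, per
  species) of a fixed-step RK4 oracle at dt = 1e-4 s over a stimulus run.
  Linear invariants (total carbon in closed runs) are conserved to
  round-off by any Runge–Kutta method, which the conservation criterion
  exploits.
* **Resting state**: damped Newton on the full 28-species derivative with a
  forward-difference Jacobian, positivity/cap-respecting line search,
  residual target 1e-11 mM/s (well under the 1e-8 contract).  The tight
  residual matters: a state off the fixed point by `|f|/λ` drifts visibly
  over a 100 s run for slow modes, so solving to 1e-8 alone would not hold
  the 1e-6 relative constancy the acceptance suite demands.
* **Ray casting**: Möller–Trumbore, vectorized across rays per triangle in
  Monte Carlo mode and across triangles per ray in visibility mode;
  degenerate determinants are treated as misses.
* **Cross sections**: vertices exactly on the cutting plane are nudged by
  1e-9 of the coordinate scale to avoid degenerate chains; intersection
  parameters themselves are computed exactly, which is why the axis-aligned
  cube section is exact `(4, 8)`.
* **Hot path**: the integrator uses a positional right-hand side with all
  parameters bound to locals; a property test asserts it equals the
  reference `ngv_derivatives()` to 1e-12 on randomized states, so the fast
  and readable implementations cannot drift apart silently.

## Known limitations

* The parameterization is plausible, not fitted; quantitative outputs are
  illustrative of the architecture's behavior, and nothing in the tests
  claims agreement with measured transients.
* Explicit integration only; pathological parameter choices (sub-ms time
  constants) would make runs slow before they make them wrong.
* No pentose-phosphate pathway, glutamine cycle, neurovascular coupling,
  or inter-voxel transport by default; H2O, G-protein and β2 receptor are
  not explicit states.
* Cross sections overcount nested loops; contact area uses whole-triangle
  centroid inclusion (resolution-matched, oracle-friendly) rather than
  clipped partial areas.
* The CLI's `simulate-unit` protocol library covers rest, a glutamate
  pulse, a noradrenaline pulse and a CBF step; arbitrary drives are
  available programmatically via `ngv_drive()`.
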