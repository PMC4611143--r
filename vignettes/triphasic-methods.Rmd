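---
title: "Methods: triphasic finite-element simulation of a cardiomyocyte segment"
author: "tricellfem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triphasic finite-element simulation of a cardiomyocyte segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`tricellfem` simulates excitation–contraction coupling in a segment of a
cardiac ventricular myocyte using triphasic mixture theory: at every
material point a cytoskeletal **solid** phase, a cytosolic **fluid** phase
and an **ionic** phase (nine solutes: Na⁺, K⁺, Ca²⁺, Cl⁻, ATP, ADP,
creatine, creatine phosphate, inorganic phosphate) coexist.  The governing
system couples

* the quasi-static mixture momentum balance, ∇·**Π** = 0, where the first
  Piola–Kirchhoff stress contains the passive solid stress (compressible
  neo-Hookean), the fluid pressure, and the Ca²⁺-driven active tension
  along the fiber (z) axis;
* the solid compressibility condition J − 1 + P_S/κ_S = 0 (κ_S = 25 kPa),
  satisfied identically by the constitutive choice P_S = −κ_S (J − 1);
* the fluid momentum balance ∇P_w + RT(1 − φ)∇C_total + K⁻¹W − C^F∇Ψ = 0
  (Darcy friction, osmotic driving with osmotic coefficient φ, and the
  electrical body force on the fixed charge C^F), with permeability
  K = 700 μm⁴/mN/ms;
* mixture incompressibility J − 1 + ∇·Q^w = 0 with Q^w = ∫W dt, relaxed by
  the t-tubule wall compliance where a lumen is hosted;
* the electroneutral ion balance
  Φ^w Ċ^α + W·∇C^α − ∇·[D^α(∇C^α + z^α F/(RT)·C^α ∇Ψ)] − f^α_subcell = 0
  per species, closed by the nodal electroneutrality condition
  Σ_α z^α Ċ^α + Ċ^F = 0 that determines the potential Ψ implicitly.

The sarcolemma is a zero-thickness interface with duplicated
intra/extracellular potential degrees of freedom per membrane node
(capacitance approximation, V_m = Ψ_i − Ψ_e, C_m = 1 μF/cm²), carrying a
reduced six-current ionic model (I_Na, I_CaL, I_K, I_K1, I_NaCa, I_NaK)
and the −100 A/F, 0.5 ms pacing stimulus (carried by K⁺ so the
electroneutrality system stays solvable).  T-tubules are one-dimensional
triphasic truss elements on the z-line plane: lumen flow between nodes i
and j is W_{j→i} = G(p_j − p_i) with G = 1 μm³/MPa/ms, walls dilate with
compliance C = 100 × lumen volume per MPa, mouths exchange with the bath,
and intra-lumen diffusion is restricted to 0.08 of the cytosolic
coefficient for every species (the value fitted to solution-switch
experiments; 0.08 × 900 μm²/s ≈ 72 μm²/s for K⁺).

### Units

Internally: μm, ms, mM (≡ amol/μm³), mV, kPa, A/F.  RT/F = 26.73 mV at
310 K.  Diffusion coefficients are entered per second (D^K = 980,
D^Na = 665, D^Cl = 1015 μm²/s, half of free solution) and used on the ms
scale; the parameter table they derive from prints "μm²/ms", but its own
fitted t-tubular value (72 μm²/s = 0.08 × cytosolic) is only consistent
with the per-second reading, which this package adopts throughout.

## Discretization

* **Mesh** — a structured, axis-aligned hexahedral grid (element edge
  0.5 μm by default) over a quarter cross-section of half-sarcomere length,
  with a one-element extracellular shell beyond the sarcolemma.  Elements
  carry compartment labels filled to the intracellular volume ratio
  myofibril : mitochondria : cytosol : JSR : NSR = 54 : 35 : 8 : 0.03 : 3;
  myofibril bundles sit on a lattice (25 bundles on a 2 μm pitch by
  default), NSR sheathes the bundles, mitochondria are placed by a seeded
  shuffle of the remaining "street" columns (optionally excluded from the
  sub-sarcolemmal layer), and the remainder is cytosol.  T-tubule polylines
  run along the street node-lines with alternating penetration depth, so
  every segment borders non-myofibril tissue.  JSR release units tile the
  z-line plane every 0.4 μm (snapped to mesh nodes); a small number of
  elements near membrane-facing units carry the volumetric JSR label, while
  each unit holds an equal share of the JSR volume scaled by a
  calsequestrin capacity factor (40), so the 2 %-absolute composition
  tolerance and the release physiology are met simultaneously.
* **Fields** — trilinear (Q1) interpolation for displacement,
  concentrations and potential; element-constant fluid and solid pressure
  (the stabilised mixed pair uses a finite-volume two-point flux coupling
  for the Darcy term between neighbouring elements).
* **Membrane** — surface membrane nodes are grid nodes shared by
  intracellular and shell elements, with paired DOFs and nodal areas lumped
  from the adjacent faces; t-tubular membrane nodes pair the grid node with
  an appended lumen DOF (area 2πr × adjacent half-lengths, default radius
  0.125 μm); mouths share the shell DOF so lumen and bath are diffusively
  continuous.
* **Convection** — central differences with a runtime Péclet assertion
  (Pe < 2); justified a posteriori because convection stays orders of
  magnitude below diffusion.

## Time stepping

Multirate operator splitting with defaults dt_mech = 1 ms,
dt_elec = 10⁻² ms, chemistry adaptive in [10⁻⁵, 10⁻²] ms.  Each coarse
step runs the electrical/chemical inner loop with frozen geometry and
fluid velocities, then the mechanics/fluid solve with the updated active
stress and osmotic/electrical loads (the split order is this package's
choice; the originating formulation states the separation but not the
ordering).

Within an electrical step the membrane ionic currents are evaluated
explicitly; the electroneutrality condition is then solved *implicitly*
for Ψ on all intra- and extracellular DOFs — a sparse SPD system
Σ_α z_α A_mig,α(C̄) plus the capacitive pair coupling a·C_m/(F dt) — and
species are advanced by forward Euler with diffusion, convection and the
migration flux computed from the fresh potential.  Because the species
update and the Ψ equation use the *same* operators, the discrete nodal
charge balance holds to linear-solver accuracy at every step (verified to
10⁻⁶ in the conservation suite).  Forward-Euler transport deviates from a
fully implicit treatment but is unconditionally stable here: at h = 0.5 μm
the stability bound is ≈ 0.04 ms against dt_elec = 0.01 ms.  Gates use the
Rush–Larsen exponential update (bounded in [0, 1] for any step).  The
operator coefficients (element-mean concentrations in the migration
operators, fluid velocities in the convection operator) are lagged and
refreshed on the mechanics cadence; single-rate reference runs keep the
same refresh interval so that splitting comparisons isolate the multirate
error.

Chemistry (RyR gating, SR fluxes, mitochondrial exchange) is advanced by
an embedded Euler/Heun pair with a proportional controller (safety 0.9,
rejection halves the step).  Cytosolic Ca²⁺ is integrated as *total*
(free + rapid-buffer-bound) concentration with a closed-form inversion of
the rapid-buffer relation, which makes the calcium inventory conserve
exactly rather than to the linearisation error of the buffering factor.

Mechanics solves the monolithic saddle system over displacement, element
pressures and truss lumen pressures with a modified Newton iteration: the
exact compressible neo-Hookean residual against the constant small-strain
tangent (factored once), with backtracking that rejects element-inverting
steps.  At twitch strains (about 1 %) one or two iterations reach
round-off.

## Reduced subcellular surrogates

The full ionic/metabolic reaction network of the lineage this model
extends lives behind the `f^α_subcell` interface and is replaced by
reduced surrogates sized to give a diastolic free [Ca²⁺] of ~0.1 μM,
local twitch peaks of order 1 μM, and a guinea-pig-like action potential
(rest −86.6 mV, peak +51 mV, APD ≈ 190 ms at 1 Hz):

* **CICR** — per-unit RyR gating with a Hill(4) trigger
  (K = 0.7 μM), opening 1 ms⁻¹, closure 0.12 ms⁻¹ into a refractory pool
  recovering at 0.004 ms⁻¹; release flux proportional to the JSR–cytosol
  difference (store-load dependent, zero from an empty store).  Junctional
  units (those directly facing a membrane) sense the bulk Ca plus an
  L-type microdomain elevation of 1 μM per A/F of local inward I_CaL — a
  standard local-control surrogate for sub-grid dyadic coupling.  The
  trigger kinetics were calibrated so that facing units release within a
  few ms while the regenerative spread to remote units takes tens of ms,
  reproducing the reported release-delay-versus-distance relation; a
  faster trigger collapses all delays to ~10 ms and destroys the
  correlation.
* **SR** — Hill(2) SERCA uptake (V_max = 6×10⁻⁴ mM/ms, K = 0.28 μM) into a
  well-mixed NSR pool, first-order NSR→JSR refill (0.08 ms⁻¹), and a
  concentration-driven leak balancing uptake at diastole.
* **Buffering** — a single rapid cytosolic buffer (B_max = 0.1 mM,
  K_d = 0.6 μM).
* **Mitochondria** — uniporter influx (Hill(2), K = 10 μM) and
  Na⁺/Ca²⁺-exchanger efflux per mitochondrial element, damping local
  transients and raising resting Ca near mitochondria.
* **Crossbridges** — first-order activation of a Hill(3) function of local
  free Ca (K = 0.6 μM, τ_on = 25 ms, τ_off = 45 ms), tension
  T = T_max × activation along z.  T_max defaults to 10 kPa: the source
  reports normalized force only, and this scale keeps heterogeneous-
  activation shear strains within the validity of trilinear kinematics on
  0.5 μm elements.
* **Stimulus charge carrier** — K⁺ (the originating description does not
  state the species).

Metabolites are transported but chemically inert (their reaction network
is out of scope) and charge-inert by default (valences 0, charges absorbed
into C^F, which is initialised nodally from electroneutrality of the
initial state because its magnitude is never stated).

## What the synthetic meshes do and do not emulate

The generator reproduces the architecture that drives the reported
phenomena: compartment volume ratios, z-line t-tubules avoiding
myofibrils with restricted lumen diffusion and compliant walls, JSR units
every 0.4 μm with membrane-distance spread, seeded-random mitochondria
including the sub-sarcolemmal contrast, symmetry/periodicity boundary
planes, and a bath shell with fixed concentrations and grounded potential.
It does **not** reproduce anatomically reconstructed, branching t-tubules,
unstructured anatomical meshes, or the full-scale geometries (the
headline runs of the source used 10⁵-node meshes and ~150 h per simulated
second; this package targets ~10³ elements and minutes).  Passing tests
therefore demonstrate the governing equations and couplings at reduced
scale, not quantitative agreement with any particular cell's anatomy.

## Numerical choices and degenerate inputs

* Explicit transport requires dt_elec below the diffusion stability bound;
  the defaults satisfy it with a 4× margin at h = 0.5 μm.
* With no bath the potential system is singular up to a constant; one
  reference node is pinned (consistent because the closed-system charge
  compatibility holds identically).
* Donnan/dialysis-style problems are well-posed through the same
  machinery: fixed charge enters only the electroneutrality right-hand
  side and the fluid body force.
* All-neutral species degenerate the potential equation; the gauge pin
  then fixes Ψ ≡ reference.
* Meshes whose lattice cannot host the requested myofibril fraction raise
  an explicit error naming the worst-off compartment, as do element
  inversions (with the element id) and chemistry steps rejected at the
  minimum step size.
* Observable problem sizes: the bundled analyses run the default
  ~10³-element quarter-section mesh for 300 ms paced windows and a
  3 ms depolarization-onset window; the multirate-consistency check uses a
  3 × 3 μm quarter section with both runs at a 0.02 ms electrical step
  (single-rate = mechanics at the same 0.02 ms).  These sizes were chosen
  so a complete verification pass stays within desk-scale minutes.

## Known limitations

* Transport operators are assembled on the reference configuration
  (small-strain transport); large-deformation remeshing is out of scope.
* The t-tubule lumen is radially unresolved by construction of the truss
  idealisation, and tubule length changes under stretch are not modelled.
* The reaction surrogates reproduce qualitative physiology (thresholds,
  lags, store dependence), not any fitted parameter set; every surrogate
  sits behind the subcellular-source interface so a full reaction network
  can be substituted.
* The deep-versus-surface Na-current difference and the t-tubular
  potential spread depend on tubule length and channel-density ratios
  (default Na⁺ 2:1 t-tubular:surface); at the reduced scale they agree
  with the reported values in order of magnitude.
* At this reduced geometry the t-tubular membrane carries roughly
  three-quarters of the total membrane area, so lumen concentration
  polarization feeds back on the local reversal potentials more strongly
  than in a full-scale anatomy.  One visible consequence: the
  dual-potential and lumped-potential formulations repolarize a few
  milliseconds apart, which dominates the pointwise-in-time comparison of
  their Ca²⁺ traces around the downstroke even though the traces agree to
  a fraction of a percent elsewhere.
* For the abundant monovalent ions, the cycle-integrated electromigration
  transport is of the same order as diffusion — electroneutrality couples
  their fluxes to every charge rearrangement — so the few-percent
  "electrical contribution" headline is meaningful for Ca²⁺, the ion whose
  intracellular concentration actually changes during the beat; the
  decomposition table reports every species.
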