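---
title: "steerbd: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{steerbd: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steerbd)
```

## What the package models

`steerbd` is about the *control logic* of accelerated ligand-binding
protocols, separated from any particular dynamics engine. Three protocols
are implemented:

* **Gated constant-force steering** (`steering_config()`,
  `steering_decision()`): a force of constant magnitude `f0` directed
  from the ligand's target bead towards a fixed reference atom, applied
  only while the bead is inside an extracellular selection cone *and*
  farther than a cut-off distance from the reference. The decision is
  re-evaluated from the instantaneous inter-atom vector at every
  application (an update period of 2 steps is also supported).
* **Flat-bottom harmonic containment** (`flatbottom_config()`,
  `flat_bottom()`): zero potential within the cut-off radius, harmonic
  beyond it, continuous and once-differentiable at the boundary. A linear
  (constant-force) wall variant is available for comparison but is not
  propagated by the engine.
* **High-concentration unbiased sampling**: many independent ligands
  placed uniformly in the extracellular slab
  (`place_ligands_uniform()`), relying on numbers rather than force.

The shared guarantee — and the property the test suite leans on hardest —
is *zero-bias purity*: on every recorded frame in which the ligand is
within the cut-off (steering) or inside the flat region (containment),
the bias force is exactly the zero vector. Binding itself is always
sampled unbiased.

## The selection cone

The steering region is `z > 0` together with `x² + y² < (z + a)²`,
`a = 15` Å: a cone of 45° half-opening whose apex sits at `z = −a` on the
pore axis. The quadratic form is the only dimensionally consistent
reading of the region (a squared length must be compared with a squared
length), and it matches the drawn funnel geometry this construction is
known by. Both the apex offset and the exponent are exposed in
`cone_region()` for users who want a different funnel.

## Units of the bias parameters

Two parameter conventions deserve a note:

* The steering strength is implemented as a constant **force magnitude**,
  `f0 = 5` kcal·mol⁻¹·Å⁻¹. Steering of this family is sometimes quoted
  with a stiffness-like unit, but the protocol itself is a
  constant-strength push along a recomputed direction, which is what the
  implementation does.
* The containment restraint is implemented as a true **harmonic**
  flat-bottom with `k = 0.1` kcal·mol⁻¹·Å⁻², i.e. energy
  `½ k (d − d_c)²` and restoring force `k (d − d_c)`. Cut-offs of 7, 10
  and 12 Å are the documented choices; 12 Å is the default.

Steering distances are deliberately *unwrapped* (no minimum image): a
pulling force that acted across a periodic boundary would be physically
meaningless, so the protocol is only defined in the extracellular
half-space and the cone gate keeps it there.

## The Brownian-dynamics engine

The propagator is overdamped Langevin (Euler–Maruyama):

    x' = x + (D / kBT) · F · Δt + sqrt(2 D Δt) · ξ

per coordinate, with `ξ` a standard-normal draw. Defaults: `Δt = 0.01`
ps, `D = 0.6` Å²·ps⁻¹, `T = 300` K with `kB = 0.0019872`
kcal·mol⁻¹·K⁻¹ (so `kBT = 0.59616` kcal/mol), a 120 × 120 × 100 Å box
periodic in x and y, reflective walls at `z = 0` (the membrane surface)
and `z = Lz`. The binding site is a rigid attractive Gaussian well of
depth 5 kcal/mol (≈ 8.4 kBT, deep enough that a captured ligand stays
for the remainder of a typical run) and width 2 Å centred on the
reference atom; its force is evaluated analytically. The time unit is a
toy picosecond: the engine reproduces the *statistics implied by the
protocol logic* (ordering of first-passage times, purity, equilibrium
distributions), not molecular kinetics.

Reproducibility is bit-exact for a fixed configuration and seed: a
single random stream drives the run, with a fixed draw order (per step,
per particle, per axis), and each recorded frame stores the bias
decision evaluated at that frame's own coordinates, so the purity
invariant can be audited from the output alone. If the deterministic
drift of any step exceeds the well width the run warns that `Δt` is too
large.

Each ligand is propagated as a single interaction bead — the "CA" bead
the bias targets. Four-bead ligand geometry (C, CA, CB, CG) is exercised
through the fixture generator and the scheduled dihedral trajectories,
which is what the conformer analyses consume; rigid multi-bead dynamics
would add nothing to the binding-pathway statistics the engine is for.
Ligand–ligand interactions default to off (ideal, independent binders);
a soft-sphere repulsion is available.

## Observables

* **Distance series** between any two endpoints (static receptor atoms
  resolved by selectors such as `"ARG:397:CZ"`, or mobile particle
  labels), minimum-image on the box's periodic axes.
* **RDF and cumulative RDF** within `r_max = 10` Å of a reference atom,
  bin width 0.1 Å. `g(r)` is normalised by the *mean density within the
  analysis sphere*, not a bulk density: the analysis region is the
  near-reference neighbourhood itself, and a bulk normalisation would
  depend on an arbitrary far-field volume. The choice is recorded in the
  result's attributes; `N(r)` is normalisation-free.
* **Conformer occupancy** from the C–CA–CB–CG dihedral, IUPAC sign,
  range (−180°, 180°]. The syn/anti boundary is `|χ| = 120°`, the
  midpoint between the two reported modes (~70° syn, ~180° anti); a
  three-state mode labels only ±30° windows around the modes and calls
  the rest "other". Degenerate frames are excluded from the fractions
  and logged.
* **Binding events** with hysteresis: an event opens after `dwell = 10`
  consecutive recorded frames below 7 Å and closes above 9 Å. The event
  definition (7/9/10) is this package's own: contact-peak positions at
  5–6.5 Å motivate the 7 Å bound-state threshold, and the hysteresis gap
  plus dwell keep boundary noise from fragmenting events. All three
  numbers are parameters.
* **Bias-time fraction**: the mean of the per-frame bias-active flags.

## The synthetic fixture

`build_synthetic_system()` emits a minimal binding site: anchors
ARG397 CZ/CG, SER277 CA, PRO356 CA and the ASP390/ASP394 carboxylate
carbons, all within 5 Å of the membrane surface, plus a bound four-bead
aspartate ligand whose CA bead sits exactly 5.6 Å from the reference —
the occluded-state geometry (the gate pair SER277 CA ↔ PRO356 CA is
also placed at 5.6 Å). The coordinates are synthetic, not copied from
any deposited structure; `import_reference_anchors()` extracts the same
anchor set from a locally supplied real structure when one is available,
and the crystal-geometry checks use it preferentially. Free ligands
start 18 Å above the reference by default (23 and 27 Å are the
documented alternative starting distances; the sources quote both 23 and
27 for the farther position, so all three are exposed and 18 — the value
both agree on — is the default).

What the fixture does *not* emulate: receptor flexibility (the HP2 gate
never opens or closes here), solvent and ion effects, and competing
binding poses. Passing tests therefore demonstrate the correctness of
the protocol logic and the analysis chain, not the biology of any real
transporter.

## Statistical checks and their problem sizes

The suite's empirical checks run at sizes chosen to give comfortable
statistical margins while keeping a full run in tens of seconds:

* **Free diffusion**: 10⁴ particles × 10³ steps; the ensemble MSD slope
  must match `6D` within 3 %.
* **Flat-bottom equilibrium**: a restraint-only particle, 10⁷ steps
  recorded every 10 (10⁶ samples). In 3D the equilibrium radial density
  is `p(d) ∝ d² e^{−U(d)/kBT}`; the Boltzmann statement "excursions
  beyond the cut-off are half-Gaussian with variance kBT/k" applies to
  the potential-of-mean-force density `p(d)/d²`. The check therefore
  uses 1/d²-weighted moments (the standard shell correction) and asks
  for agreement within 5 %; the uncorrected second moment at
  `d_c = 12` Å would sit ~30 % high for purely geometric reasons.
  Inside the cut-off the same correction predicts `P(d < r) = (r/d_c)³`,
  tested on decorrelated subsamples.
* **Purity**: 50 steered + 50 contained runs of 10⁵ steps each; the
  violation count must be exactly zero.
* **Acceleration ordering**: 50 seeded replicates per protocol, 10⁵
  steps each; medians must order steer ≤ flat-bottom(7) ≤
  flat-bottom(12) ≤ unbiased, with one-sided paired rank tests at
  α = 0.05. Unbound replicates are censored at the simulated duration.
* **Concentration effect**: 30 seeds × (76 vs 1) uniformly placed
  unbiased ligands, 2 × 10⁴ steps; one-sided Fisher test on the
  fraction of seeds with at least one binding event.

`scripts/acceptance.R` recomputes all of these from scratch under a
caller-supplied seed.

## Numerical details worth knowing

* Minimum-image displacement uses `round(d/L)`, i.e. full modular
  reduction, valid for arbitrarily distant points; the box is
  orthorhombic only.
* Dihedral angles use `atan2((n₁ × n₂) · b̂₂, n₁ · n₂)`; planar-cis is
  0°, planar-trans +180°, and rotating the far atom about the central
  bond by δ changes the angle by exactly δ. Collinear triples raise a
  distinct error.
* Superposition RMSD uses the SVD construction with the determinant
  correction (no reflections); degenerate (collinear) point sets are
  rejected. The test oracle is an independent Euler-angle grid search
  with simplex refinement.
* PDB reading and writing go through bio3d; the package layer adds the
  validation contract (no-atom and duplicate-key errors, altLoc
  filtering to blank/"A", non-finite coordinate detection) and keeps
  author residue numbering untouched.
* The trajectory format is extended XYZ with `time=… flags=…` comment
  lines — text, diffable, lossless at 10⁻⁶ Å.
* Wrapped axes are centred (`[−L/2, L/2]`), so the binding site at the
  origin never sits on a wrap seam.

## Known limitations

Rigid receptor; no gate dynamics (gate distance is an analysis-side
observable only); no electrostatics, solvent or ions; orthorhombic boxes
only; single reference atom per controller (trimeric receptors would run
one controller per subunit-ligand pair); the engine's time scale is not
physical. These are scope decisions, not accidents: every one marks the
boundary between the protocol logic this package owns and the physics an
MD engine would supply.
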