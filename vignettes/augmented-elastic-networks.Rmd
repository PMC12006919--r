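---
title: "Augmented elastic networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmented elastic networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aenm)
```

## The model

`aenm` simulates a macromolecule as an *augmented elastic network*: beads
connected by Hookean springs, with additional energy terms layered on top.
The elastic part encodes shape memory — every pair of beads closer than a
cutoff in the input structure is joined by a spring whose rest length is
that initial distance, so the input conformation is the exact minimum of
the spring energy

$$V = \sum_{i<j} K\,(d_{ij} - d^0_{ij})^2 .$$

Two conventions deserve emphasis. First, there is **no ½ prefactor**: many
elastic-network codes write ½k(d−d₀)², so a force constant K here equals
k/2 there. Second, rest lengths come from the *input coordinates*, never
from a force field, which is why beads are placed on a single
representative atom (Cα, or P for nucleotides) rather than a residue
centroid: the spring geometry is then reproducible from the structure file
alone.

The augmentation terms give the network chemistry the springs cannot
express: steric exclusion and electrostatics (non-bonded), external
precomputed fields, an implicit membrane, and surface-burial scoring. All
share one contract — a *force term* maps coordinates to
`(energy, per-particle forces)` — and the engine sums any combination of
them. Disabled terms contribute exactly zero.

### Units

Lengths in Å, energies in kcal/mol, charges in e, masses in amu, times in
fs. The Coulomb constant is 332.0637 kcal·Å/(mol·e²) and accelerations use
the conversion 4.184·10⁻⁴ Å/fs² per (kcal/mol/Å)/amu. These constants live
in one place (`unit_constants()`) and every closed-form check in the test
suite is exact in these units. Particle indices are 1-based everywhere,
matching both R convention and PDB serial numbers.

## The terms and their parameters

**Springs.** `cutoff` (default 9 Å, within the 7–15 Å range in common
use — shorter cutoffs emphasize local stiffness, longer ones add global
shape memory) and a single uniform `stiffness` K (default
0.6 kcal/mol/Å²). Multiple layers with different cutoffs/stiffnesses can
be merged; a duplicate pair keeps the entry of the earliest layer
(*first-layer-wins*), so a stiff backbone layer declared first is
protected. The alternative, summing stiffnesses, was rejected because it
silently changes a layer the user explicitly declared. Pairs at exactly
the cutoff are included (≤, not <).

**Non-bonded.** Lennard-Jones in the (R_min, ε) convention,
E(d) = ε[(R/d)¹² − 2(R/d)⁶] with R = r_i + r_j and ε = √(ε_i ε_j): the
energy minimum sits exactly at the sum of the bead radii, which makes
radii interpretable as size exclusion. Coulomb is k_e q_i q_j/(ε_r d).
Both are truncated and *energy-shifted* to zero at their cutoffs
(defaults 12 and 16 Å) — a shift, not a switch, because damped dynamics
only needs continuous energies, not continuous second derivatives.
Spring-bonded pairs are excluded from both terms: spring neighbours
typically sit closer than R and would otherwise ride the r⁻¹² wall. The
relative dielectric defaults to 1 for use alongside a Poisson–Boltzmann
grid (the grid already embodies solvent screening); without such a grid a
screened value of ~10 is the physically sensible choice for aqueous
systems, and the mechanical-deformation demo uses exactly that.
Neighbours come from a cell grid (cell size = the largest cutoff, 27-cell
scan); on systems under a few hundred beads the engine simply uses the
all-pairs path, which is faster in R at that size — the cell grid is
verified against brute force either way.

**Grid fields.** OpenDX scalar grids ("regular positions, regular
connections", the dialect Poisson–Boltzmann solvers write) are
interpolated trilinearly. In potential mode the coupling is the bead
charge (E = qφ, F = −q∇φ); in density mode the energy is the linear pull
−wρ, the simplest functional that generates forces toward high density —
a deliberate, documented choice, since nothing in a density map dictates a
fitting functional. Points outside the grid hull are clamped to the
boundary value with zero force: interactive pulls routinely drag beads
off-grid, and a hard edge or extrapolation would explode the dynamics.
The gradient at a cell face takes the lower cell's value (a measure-zero
tie-break).

**Implicit membrane.** Each bead carries a transfer energy (kcal/mol,
negative = hydrophobic) and the membrane term scales it by a logistic
insertion profile f(z) = 1/(1 + exp((|z − z₀| − h)/w)): 1 deep in the
slab, ½ exactly at the interface, 0 in water. The logistic was chosen as
the stand-in analytic profile because it is smooth, has an analytic
derivative, and has two interpretable parameters — half-thickness h
(engine default 15 Å, i.e. a ~30 Å slab) and interface width w (default
1.5 Å). A second bilayer combines by per-bead *maximum* of the two
profiles — a bead cannot be "doubly inside"; summing could exceed 1.
Membranes are planar with the normal fixed to +z; inputs are assumed
pre-oriented. Forces act along z only, so lateral motion is exactly
energy-neutral.

**Surface burial.** Shrake–Rupley SASA with a golden-spiral (Fibonacci)
point lattice — deterministic by construction, so areas are
bit-reproducible across runs and platforms; that reproducibility is worth
more than the marginal isotropy a random point set would buy at the
default n = 256. A sample point is accessible iff *strictly* outside every
other expanded sphere (boundary-touching counts as buried). The burial
term is reference-anchored, E = Σ w_i (A_i − A_i^ref) with reference areas
from the isolated molecules, so it is exactly zero before contact: it
drives association, it is not a folding potential. Default weights are
−0.01·(transfer energy) per Å², giving hydrophobic beads positive weights
so burying them lowers the energy. The term is score-only by default
(an observable with an exactly-zero force); finite-difference forces
(central, step 0.05 Å, computed only for beads with a contact partner in
reach) are opt-in, reflecting its experimental status.

## Dynamics, steering and stability

Two deterministic integrators:

* `damped-verlet` (default): v ← (1 − γ)(v + (F/m)·c·dt), x ← x + v·dt.
  γ ∈ (0, 1] is the per-step velocity loss; the guideline
  dt ≤ 0.5·√(m_min/(2 K_max c)) keeps the stiffest spring stable.
* `overdamped`: x ← x + μ F dt, no inertia. This mode exists because it
  makes relaxation behaviour *exactly* solvable — a single spring decays
  as x(t) = x₀ + Δ·exp(−2Kμt), which the tests verify at 1% — and because
  its effective mobility can be set orders of magnitude above the damped
  integrator's (1−γ)/γ·c·dt/m, which matters for slow collective modes
  like a domain swinging back after release.

There is deliberately **no thermal noise**. The engine's signature
behaviours — relaxation to the reference state, metastable states escaped
only when the user supplies the activation energy — are reproducible only
without a thermostat, and determinism (bit-identical observables from
identical configs) is a tested contract. Langevin dynamics would be a
natural extension, not a default.

Steering is an elastic pull between the geometric centre of a selected
group and a target point: F = k(target − centre), capped at `max_force`
(default 500 kcal/mol/Å — excessive forces are the classic way to
destabilize an interactive run), then divided *equally* over the group
(matching the geometric-centre formulation; mass-weighting would
contradict it). The force depends only on the current coordinates and the
current target, so how often a client re-sends the target cannot change
the dynamics — the tests assert bit-identical trajectories across resend
strides. A global per-step displacement cap (default 0.5 Å) is the second
stability guard. Static particles (the "static set") exert forces but are
never integrated; their coordinates are bit-identical across a run.

The steepest-descent minimizer halves its step whenever the energy would
rise (the accepted energy sequence is monotone non-increasing) and grows
it by 1.2 after success; it stops at a force tolerance or step budget.

## Configuration, observables, interaction protocol

Experiments are single YAML files with blocks `system`, `springs` (a list
of layers), `nonbonded`, `field`, `membrane`, `sasa`, `dynamics`,
`steering`, `output`; relative paths resolve against the config's
directory. Validation materializes every default, rejects unknown keys
with a nearest-key suggestion (typo safety), reports all violations at
once, and warns — without refusing — when a spring cutoff leaves the
commonly used 7–15 Å range. Observables stream as one TSV row per frame:
step, per-term energies, total, then depth/tilt (membrane runs), total
SASA and steering-force magnitude where applicable. The score-only SASA
observable is recomputed every `sasa.stride` frames (default 10) for cost
control.

The interactive wire protocol (`SELECT`, `TARGET`, `K`,
`PARAM damping|membrane.scale|steer.k`, `GET ENERGY|DEPTH|SASA`) is
implemented as a pure function from (session, line) to (session, reply),
so it can be served over any line-based transport; the package ships the
protocol core, not a socket server, because the protocol semantics are
the testable part.

## The generated demonstration systems

All test inputs are generated by code — nothing is downloaded — and each
generator is deterministic (fixed constants, no random draws), so fixture
files are bit-reproducible.

* **linear-chain**: n beads at fixed spacing; the unit-test substrate.
* **two-lobe**: two 30-bead lobes (golden-spiral shells, radius 5.5 Å)
  joined by a 5-bead hinge into a U-shape, residue names cycled through a
  mixed charged/hydrophobic set. The hinge is *static*: it pins the
  rigid-body zero modes of the network, so a released deformation relaxes
  back to the unmoved reference — which is also why the package's RMSD
  deliberately performs no least-squares superposition (the comparison is
  against the same anchored frame, and a fitted RMSD would mask genuine
  drift).
* **dock-field**: a static ring of 12 negatively charged beads, a
  flexible 10-bead positively charged ligand chain, and an OpenDX grid
  holding a Gaussian potential well (depth 30 kcal/mol/e, width 5 Å)
  whose global node minimum *is* the annotated binding pose. The pose is
  annotated where the bound ligand actually rests — the self-consistent
  equilibrium of Coulomb attraction and steric contact — mirroring how a
  guide field derived from a known complex marks the true bound position.
* **membrane-barrel**: a 7-ring, 70-bead cylinder (radius 8 Å, 30 Å
  long), hydrophobic belt (|z| ≤ 10 Å) between polar caps, paired with a
  demo membrane of half-thickness 12 Å and interface width 3 Å — a
  realistic hydrophobic-core thickness with a soft headgroup-scale
  interface. The geometry is chosen so that even a fully horizontal
  (lying) barrel keeps part of its surface inside the interface gradient;
  with a much thicker slab a lying barrel would be fully submerged on an
  energy plateau with no usable gradient. The five standard starting
  poses (vertical, 30°, 60°, horizontal, depth-displaced) each carry a
  fixed 2.5° rotation about the skew axis (1,1,1) plus a sub-Å depth
  offset: the perturbation that keeps no pose exactly on a symmetry
  saddle, applied about an axis that is never parallel to the barrel
  axis at any nominal tilt.

What the fixtures emulate is the *mechanics* of the three demo
experiments: elastic restoration after deformation, field-guided docking,
and membrane-orientation recovery. What they do not emulate is real
structural data: no side-chain packing, no sequence-specific contacts, no
experimental noise, and bead parameters from the packaged table — a
synthetic stand-in whose radii, well depths and masses are residue-level
effective values and whose transfer energies follow a standard
hydrophobicity ordering, not any published force field. Passing tests
therefore demonstrate that the engine's physics and contracts are
correct, not that any particular protein will behave quantitatively as
these toys do.

## Verification protocols and problem sizes

The acceptance computations (also packaged as `scripts/acceptance.R`) use
desk-scale sizes chosen to finish in about a minute while still exercising
every code path: 20 random 10-bead configurations per force term for
gradient checks, 50 random 100-bead clouds × 3 cutoffs for the
neighbour-search oracle, 10 checkpoints over 2000 overdamped steps for the
closed-form relaxation, a 1000-step settle + pull-to-5 Å + 5000-step
release for the two-lobe restoration, 4000 relaxation steps for the
docking demo, and up to 128 000 overdamped steps per barrel pose (the
fully horizontal start needs ~104 000 steps to rotate through the weakly
driven region near 90°; the other poses converge in well under half
that). The membrane oracle is an exhaustive (depth × tilt) scan at
0.25 Å × 1° resolution of the rigid-body membrane energy.

Numerical notes: force/gradient agreement is measured as a max-norm
relative error against central differences (step 10⁻⁵ Å, or 10⁻⁶ for the
interpolated and membrane terms whose higher curvature rewards a smaller
step); Newton's-third-law checks are relative to the force scale, since
random clouds can contain deep steric overlaps with very large pair
forces; SASA oracle agreement is measured per bead relative to the bead's
isolated-sphere area (a near-zero buried area makes a per-bead relative
error meaningless).

## Known limitations

* Aperiodic only — no periodic boundaries, no Ewald; the engine targets
  single assemblies, not condensed phases.
* Planar membranes with a +z normal; curved or arbitrarily shaped
  bilayers are out of scope.
* No thermal sampling: results are relaxation paths and minima, not
  ensembles.
* The minimizer and the damped integrators find *nearby* minima; neither
  is a global search, and the engine offers no systematic or Monte-Carlo
  conformational search.
* SASA forces are finite-difference and quantized by the point lattice;
  they are adequate for driving association in demos, not for precise
  surface thermodynamics.
* Single-threaded by design; determinism and simplicity were preferred
  over parallel speed at the system sizes the engine targets.
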