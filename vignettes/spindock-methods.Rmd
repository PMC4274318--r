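---
title: "Docking rigid bodies with spin-label distance restraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking rigid bodies with spin-label distance restraints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Pulsed electron-electron resonance (PELDOR, also called DEER) measures
nanometre-range distances between pairs of nitroxide spin labels attached to
engineered cysteines. When the structures of two protein bodies are known
but their assembly is not — the motivating case is a homodimer that
self-associates into a dimer-of-dimers — a handful of inter-label distances,
together with the symmetry of the assembly and simple sterics, can be enough
to dock the bodies. `spindock` implements that pipeline: label-ensemble
modelling, ensemble-averaged square-well distance restraints,
non-crystallographic-symmetry (NCS) restraints, a scalable soft repulsion,
staged rigid-body minimisation, and a final relaxation of interface
side-chain torsions.

# Spin-label ensembles

A label is never a point: the R1 side chain (MTSL bound to a cysteine) has
five rotatable linker dihedrals, and the measured distance is an average
over its conformations. `search_r1_conformers()` therefore rebuilds the
side chain from idealised internal coordinates, draws the five dihedrals
uniformly, and rejects conformers whose atoms (from the second sulfur
outward; the CB and SG sit against the attachment backbone) approach any
protein heavy atom closer than a scaled sum of element radii. The scale is
0.9 for the `tight` setting and 0.75 for `loose` — the two customary
accessible-volume modes name the idea but not the numbers, so these are the
package's own calibration, chosen so that a surface site on a toy helix
passes roughly a third of uniform draws. Sampling stops at `max_conformers`
(default 200, the usual accessible-volume cap) or when the trial budget
(`thoroughness`, default 1000) is exhausted; zero survivors is an error that
advises raising the budget or loosening the clash test. All draws come from
a locally seeded RNG, so ensembles are bitwise reproducible and the caller's
RNG stream is untouched.

The restraint endpoint is the nitroxide nitrogen (N1). `extract_n1_ensemble()`
keeps the first `min(n, 190)` N1 positions in sampling order — 190 because
downstream fixed-format machinery limits a residue to 190 atoms, and the cap
is conventionally applied head-first, which makes the surviving subset
order-dependent by construction — and names them `N001`…`N190`. Ensembles
are written as `SPIN` pseudo-residues: one ATOM record per conformer, a
shared residue number that increases by one per ensemble, and a segment id
(columns 73–76) that supersedes the chain letter everywhere selections are
evaluated.

The Rx2 label bridges *two* cysteines and is pseudo-cyclic, so a dihedral
(rotamer-style) search is the wrong model. The underlying placement
protocol for such labels is molecular dynamics, whose details are not
reproducible here; `generate_rx2_ensemble()` instead samples nitroxide
positions geometrically from the intersection of two spherical shells, one
per anchor CB, with the linker band set to 5.5–7.0 Å and clash rejection as
for R1. This is a documented surrogate: it reproduces the two-anchor
constraint and the (testably) narrower ensemble breadth relative to R1 at
the same site, not any force-field-specific population. Anchors farther
apart than the configurable reach (default 12 Å) are rejected.

# Distance restraints

Two ensembles `A`, `B` are compared to a measured distance through
R⁻³ averaging,

$$ r_\mathrm{eff} = \Big( \tfrac{1}{|A||B|} \sum_{i \in A, j \in B}
   r_{ij}^{-3} \Big)^{-1/3}, $$

which weights short cross-pairs more strongly than the centroid distance
and reduces to the plain distance for singleton ensembles. Whether the
reference convention uses the mean or the sum over pairs is not documented;
the mean is adopted precisely so that the singleton limit behaves as an
ordinary distance. The energy is a square well: zero on
`[target − minus, target + plus]`, outside it

$$ E = \mathrm{scale} \cdot \min(\mathrm{ceiling},\;
   \mathrm{sqconstant} \cdot v^{\mathrm{sqexponent}}), $$

with defaults sqconstant 1, sqexponent 2, ceiling 50, scale 10. Two
conventions need care:

* **Ceiling scope.** The cap applies to the *unscaled* well term. A
  violation of 2.937 Å under the defaults scores 10 × 2.937² ≈ 86.26
  kcal/mol — above 50, which is only the cap on the unscaled term — while
  arbitrarily large violations saturate at scale × ceiling = 500 kcal/mol.
* **Signed delta.** `delta` is reported as (nearest violated bound) −
  r_eff, so overlong distances print negative deltas.

A capped well has zero force on its plateau, yet the docking protocol
deliberately starts with the bodies ~100 Å apart, far beyond the cap point
(√ceiling ≈ 7.07 Å of violation). The package resolves this by keeping two
readings of the same restraint: reported energies are always capped, while
the minimisation objective continues past the cap linearly with the slope
at the cap point (C1-continuous). Minimisation therefore always feels a
restoring force, and no reported per-restraint energy ever exceeds 500
kcal/mol. Restraint-set summaries report the RMS of deltas over *all* rows
(an option restricts it to violated rows) and the violation count.

# NCS restraints

Symmetric assemblies are restrained through equivalence groups: lists of
equal-length, correspondingly ordered atom selections, conventionally the
CA atoms of residues shared between chains — and, importantly,
*cross-body* composites (chain A of body 1 together with chain D of body 2,
versus B with C), so that the restraint constrains the relative pose rather
than the internal geometry of either rigid body. No formula is published
for the reference implementation's NCS mode; `spindock` adopts the
generalized-Procrustes form: every copy is least-squares superposed onto
the running copy-average, iterated to a fixed point, and the energy is
`weight_ncs × Σ |y_i − mean_i|²` summed over copies and atoms. Iterating to
the fixed point (rather than a single pass) makes the energy a well-defined
function of the coordinates and — via Danskin's theorem — makes the
analytic gradient `2 w Rᵀ (y − mean)` exact, which the test suite verifies
against finite differences at 1e-4 relative tolerance. The form is
validated against its own closed-form two-copy oracle
(`E = w/2 · n · RMSD²`), not against any external numeric convention.
`sigb` is parsed and stored for config compatibility but unused: no
B factors are refined. Degenerate (collinear) copies are rejected, as is
any cardinality mismatch.

# Non-bonded terms

A deliberately small stand-in for a full force field (`forcefield_lite`):
heavy atoms only, per-element radii and well depths from a built-in table,
simplified partial charges on backbone N/CA/C/O, electrostatic constant
332.06 kcal·Å·mol⁻¹·e⁻². SPIN pseudo-atoms are excluded from all
non-bonded terms: an ensemble represents a population, and scoring its
sterics would overestimate the footprint of any single label. Two modes:

* `repel > 0`: quartic soft repulsion
  `E = k Σ max(0, (repel·(r_A+r_B))² − r²)²` with k = 4.0 kcal/(mol Å⁴).
  `repel = 1e-9` makes the term numerically zero for separated atoms (the
  "pass through each other" stage); 0.7 restores soft sterics.
* `repel = 0`: 12-6 Lennard-Jones (Lorentz–Berthelot combination) switched
  over the 6.0–6.5 Å window, plus Coulomb electrostatics damped by the
  shift function `(1 − (r/ctofnb)²)²` and truncated at 6.5 Å, with the
  short pair-list cutoff of 7.5 Å.

Because hydrogens, bonded terms and real partial charges are absent,
absolute VDW/ELEC magnitudes are *not* comparable to a full CHARMM-style
evaluation; what the pipeline relies on — and what is tested — is the
qualitative staging behaviour (tiny repel ≈ 0; energy monotone in `repel`;
physical terms for the final evaluation).

# Staged rigid-body minimisation

Each rigid group (a body plus the ensembles riding on it) carries six
degrees of freedom: a unit quaternion and a translation about the group's
input centroid. Energy gradients are assembled per atom and mapped to the
pose by the chain rule — translation force as the sum of atom forces, the
rotational gradient as the torque `Σ (x_i − centroid) × f_i` applied as a
rotation-vector increment, which is the exact equivalent of the quaternion
chain rule and avoids normalisation bookkeeping. The minimiser is gradient
descent with a backtracking line search; the derivative-free structure of
the reference minimiser is not published, so the package makes its own
choice and keeps the documented step-size heuristic: the first trial step
is sized so the expected first-step decrease is about `drop` kcal/mol
(α₀ = drop/|g|²). Accepted steps never increase the stage objective;
iteration stops at `nstep`, when no decreasing step exists, or when the
objective changes by less than 1e-6 kcal/mol over five consecutive steps.

The standard protocol is four stages: (1) restraints only, repel 1e-9,
nstep 100 — the bodies may pass through each other; (2) restraints + NCS,
repel 1e-9, nstep 200; (3) adding soft repulsion at repel 0.7, nstep 100;
(4) torsion refinement with repel 0 (LJ + Coulomb). Intermediate structures
are written after each stage (`RES/noe.pdb`, `noencs.pdb`, `noencsvdw.pdb`,
`noencsvdwdynint.pdb`).

Stage 4 relaxes the chi angles of side chains in configured interface
ranges by coordinate descent (a 30° grid scan per angle, refined locally by
bisection, accepting only decreasing moves), under an evaluation budget
(`nstep`, default 2000) and a per-sweep improvement threshold (`depred`,
default 1 kcal/mol). This is minimisation in torsion space, not
thermostatted dynamics — the reference usage is itself energy minimisation,
so the semantic simplification is deliberate and documented. Backbone
atoms never move; ring moieties of PHE/HIS/TYR/TRP move only as rigid
units (no intra-ring torsion is ever sampled, so ring geometry is preserved
to machine precision) and PRO is fully rigid. Intra-body side-chain pairs
are scored with their electrostatics weight set to zero so that the Coulomb
term cannot dominate packing, mirroring the interaction-weight convention
for this stage.

# Synthetic fixtures: what they emulate, and what they do not

All tests run on generated data. Chains are idealised helices (rise 1.5 Å,
100° twist, full N/CA/C/O backbones, CB on non-glycine residues,
poly-alanine with PHE/LEU/TYR side chains at interface positions for the
torsion tests). The planted assembly is exactly D2-symmetric — the dimer's
internal 2-fold about z and the planted tetramer 2-fold about x — because
the cross-body NCS equivalence groups ((A∪D)/(B∪C) and (A∪C)/(B∪D)) are
exactly satisfiable only when the two 2-folds commute; this makes the
ground truth a true zero of the NCS energy. The docking start point
separates the second body by 100 Å (plus an optional random rotation of up
to 10°), and restraint tables are computed from the truth pose with
Gaussian noise (bounds set to `max(noise_sd, 0.1)` Å).

Passing on these fixtures demonstrates the correctness of the energetics,
the gradients, rigidity, and the protocol's ability to recover a planted
pose from sparse exact restraints. It does not demonstrate docking accuracy
on real proteins: real bodies have imperfect internal symmetry, labels on
real surfaces have multimodal ensembles, measured distance distributions
carry systematic width, and the simplified non-bonded treatment cannot rank
near-degenerate interfaces. Fixture sizes are kept small on purpose (30
residues per chain, 15-conformer ensembles, 16 restraints; the recovery
study uses 20 seeds), which keeps the full suite fast while leaving every
code path exercised.

# Numerical choices and degenerate inputs

* Coordinates are Å throughout; PDB emission uses 3 decimals; energies are
  kcal/mol.
* Rotations must be proper orthonormal to 1e-8 or they are rejected;
  superposition of collinear point sets is an error, not a silent fallback.
* Coincident atoms across two ensembles make the R⁻³ average singular and
  raise an error.
* Alternate-location indicators and insertion codes are rejected on read:
  the workflow never produces them, and silently collapsing them would
  corrupt ensemble bookkeeping. HETATM records are dropped by default with
  a flag to retain. Residue renumbering exists only as an explicit
  operation, never an implicit one.
* The per-residue emission cap keeps the *first* 190 conformers in
  sampling order (a documented order-dependence, matching head-first
  truncation); ties in the torsion grid scan resolve to the current angle
  (no move).
* `maxe` is treated as an evaluation budget per torsion sweep, and `drop`/
  `depred` as step-size and sweep-improvement heuristics, since their
  precise internal semantics in the reference implementation are not
  published.

# Known limitations

* No bonded force field: bodies are rigid and BOND/ANGL/DIHE/IMPR report
  as zero rather than values inherited from the input coordinates.
* R1 conformers are unweighted (no rotamer-library populations); Rx2 is a
  geometric surrogate.
* Single-solution minimisation: no simulated annealing or multi-start
  ensemble docking; convergence from a given start is deterministic.
* The NCS functional form is this package's own (validated against its own
  oracle), so NCS magnitudes are not comparable across implementations.
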