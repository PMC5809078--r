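---
title: "Measuring protein-induced DNA kinks: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein-induced DNA kinks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `dnakink`: the geometric model
behind every reported number, the parameters that matter and their
defaults, what the synthetic generator does and does not emulate, the
numerical choices, and the known limitations. It states no empirical
result that the package's tests and acceptance script do not themselves
compute.

## The observable: roll at a base-pair step

A base-pair step is the dinucleotide unit formed by two consecutive base
pairs. Its relative geometry is described by six rigid-body parameters:
three translations (shift, slide, rise, in Å) and three rotations (tilt,
roll, twist, in degrees). Sharp protein-induced kinks concentrate the
deformation in the roll of a single step — the rotation about the step's
long in-plane axis — so the package's central quantity is the per-step
roll profile. A step with roll above a threshold (default 35°) is called
a kink, and the largest roll in a complex is reported as its kink angle.
Screening at 35° separates sharply kinked complexes from the gradual
bends that spread over several steps.

## Base frames, pair frames, step frames

**Base frames.** Each nucleotide base carries the standard nucleic-acid
reference frame: origin on the pseudo-dyad, x toward the major groove, y
toward the strand-I backbone, z normal to the base plane along strand I
5'→3'. The frame is obtained by least-squares (Kabsch) superposition of
an embedded idealised base (A, C, G, T coordinate tables; ring atoms
only drive the fit) onto the observed ring atoms; at least 6 matched
ring atoms are required, and a proper rotation (det = +1) is enforced so
mirror-image coordinates cannot produce a left-handed frame. The fit
RMSD is reported; it is 0 for idealised bases and grows with thermal
noise and modelling error.

**Pair frames.** The strand-II base frame is flipped 180° about its own
x-axis (y and z negated) so both triads share the strand-I sense, and
the pair frame is the half-way rotation between the two triads, origin
at the midpoint of origins. A relative rotation above 90° after the flip
signals non-Watson-Crick geometry and is refused.

**Step parameters (mid-step-frame scheme).** For consecutive pair frames
i and j: the bending angle Γ is the angle between the two z-axes; the
hinge is z_i × z_j; both triads are rotated halfway about the hinge onto
a common z; twist is the signed angle between the symmetrised x-axes;
the mid frame lies at half-twist; the phase φ of the hinge against the
mid-frame y-axis decomposes the bend into roll = Γ·cos φ and tilt =
Γ·sin φ; and (shift, slide, rise) are the origin difference expressed in
mid-frame coordinates. Positive roll opens the step toward the minor
groove. This scheme is exactly invertible, which the generator exploits
(see below). It is *not* the curvilinear-axis convention of Curves+;
for crystal-structure comparisons against values derived with Curves+ a
±3° allowance covers the convention gap, which is well below the 15–20°
contrasts of interest between wildtype and mutant complexes.

Intra-pair parameters (buckle, propeller, etc.) enter only through the
pair-frame construction and are not reported: kink analysis uses roll
only.

## Duplex detection and curation

Pair detection is geometric: complementary identities (A:T, G:C only; no
wobble or Hoogsteen pairs), C1'–C1' distance 8.0–12.5 Å, at least two
canonical donor–acceptor contacts (A N1:T N3, A N6:T O4; G N1:C N3,
G N2:C O2, G O6:C N4) within 3.6 Å, base-plane angle ≤ 65°. Conflicts
are resolved greedily by hydrogen-bond count, then smaller C1'–C1'
distance. The thresholds were chosen so steps kinked up to ~55° roll
still pair while stacked non-pairs do not; on generated duplexes with
kinks in that range, recovery of the planted pairing is exact (a tested
property). Under *unphysical* deformations — simultaneous large negative
roll and large tilt that crush the minor groove — a cross-step contact
can out-compete a true pair on the distance tie-break; the pairing
guarantee is therefore stated for the physical kink range, and
measurement round trips at extreme prescribed deformations use the
generator's own pairing.

Curation mirrors how kinked-complex catalogues must be cleaned:

* **Dangling ends.** Unpaired terminal nucleotides shift the pairing
  register of automated helical analysis. They are counted into
  `trimmed_5p`/`trimmed_3p` and excluded from step indexing — step 1 is
  always the first *paired* dinucleotide. Trimming, not re-alignment, is
  the implemented correction.
* **Base flip-outs.** A base rotated out of the helix breaks its pair
  and produces spurious large rolls that are not kinks. Positions are
  flagged when a nominal pair has fewer than two hydrogen bonds, when a
  paired base's ring centroid strays more than 4 Å from the local axis
  (the piecewise path through the three neighbouring pair origins — a
  chord would cut the corner of a genuine sharp kink and misflag it),
  or when an unpaired nucleotide sits in an interior break with pairing
  continuing beyond it. Kink calls adjacent to a flagged position carry
  a `flip_adjacent` annotation rather than being silently dropped.
* **Multiple helices.** Separate double strands in one model (a common
  failure mode for automated helical analysis) become separate duplexes
  and are analyzed independently.

## Intercalation geometry

At a kinked step, sidechain heavy atoms (CB and beyond; CA and backbone
excluded, so glycine can never intercalate) are tested against the step
slab: between the two base-pair mean planes (signed distances of
opposite sign, each ≤ 4.5 Å) and within 7 Å of the mid-step origin.
Insertion depth is measured past the step's C1'–C1' line toward the
helix axis. A residue with at least half its sidechain atoms inside the
slab and depth ≥ 1.5 Å is classified *full*, anything less *partial*.
The 50 %/1.5 Å rule is this package's quantitative surrogate for what is
otherwise a visual judgement; it is calibrated so planted deep wedges
classify full and grazing contacts partial, and both cut-offs are
exposed as arguments. Borderline residues near either cut-off may
legitimately classify differently than a human inspector would decide.

## Trajectory statistics

Snapshot ensembles (multi-model PDB is the canonical format) are reduced
to n equidistant snapshots with the deterministic rule
`floor(k·M/n) + 1`, k = 0..n−1 (default n = 2000, the per-trajectory
budget used throughout). The snapshot × step roll matrix yields the
average profile (column means, with per-snapshot fitting failures stored
as missing and excluded per column), per-step histograms fit by
nonlinear least squares to `y = a·exp(b·(x−c)²)` with b constrained
negative and moments as starting values (2° bins over [−20°, 80°],
widened to cover the data), and the stability classification:

* per snapshot, the argmax-roll step within ±1 of the reference step;
* `unstable` if a neighbour carries the maximum in ≥ 30 % of snapshots
  (the kink has shifted or wanders);
* otherwise `stable_large_kink` if the mean roll at the reference step
  is ≥ 35°, else `stable_reduced_kink`.

The 30 % occupancy and 35° cuts are surrogate operationalisations of
qualitative groups (small effect / stable reduced kink / instability);
both are configurable, and both per-step means and occupancies are
reported so that a shifted kink remains visible rather than being
averaged away.

## The synthetic generator: what it emulates, what it does not

`build_duplex()` places ideal Watson–Crick pairs (standard base
geometries, zero intra-pair deformation, ring + WC exocyclic atoms +
C1', no phosphate backbone) into pair frames generated by running the
mid-step construction in reverse from prescribed step parameters; fiber
B-DNA defaults are rise 3.38 Å, twist 36°, all else zero. Because the
generator is the exact inverse of the measurement, `measure(build(p)) = p`
to numerical precision for any profile with |roll|, |tilt| ≤ 60°, twist
20–45°, rise 2.5–4.5 Å — the package's defining tested property (500
random profiles, observed error < 1e-9 in every component, reported by
the acceptance script).

`simulate_roll_ensemble()` draws each step's roll independently and
normally about a mean profile (other parameters fixed), seeded and
reproducible. This emulates the near-Gaussian per-step roll fluctuation
of equilibrium trajectories around a stable kink. It does **not**
emulate: correlated fluctuations between neighbouring steps, elastic
coupling between roll and the other five parameters,
sequence-dependent stiffness, kink migration dynamics, backbone or
solvent degrees of freedom, or crystallographic disorder. Passing the
trajectory-recovery tests therefore demonstrates that the measurement
and statistics chain is correct and unbiased, not that real MD
ensembles obey the independence assumptions.

Planted fixtures (`plant_intercalator()`, `add_overhang()`,
`flip_base()`) produce geometrically faithful but chemically schematic
features: the wedge sidechain marches into the slab in the mid plane at
1.3 Å spacing rather than with rotamer geometry, and placements that
would overlap DNA atoms (< 1.5 Å) are refused — note that at a sharply
kinked step the closed major-groove side genuinely leaves no room
beyond ~2.5 Å insertion, so over-deep plants fail by design.

## Numerical choices

* Bending angle Γ uses `atan2(|z_i × z_j|, z_i·z_j)`: the `acos` form
  loses ~√ε precision near parallel z-axes and would leak ~1e-6° of
  spurious roll into straight steps.
* Near-zero Γ (< 1e-9°): the hinge is undefined; roll = tilt = 0 and
  the hinge rotations are skipped.
* Kabsch superposition uses SVD with a sign correction that forbids
  reflections.
* Alternate locations: the highest-occupancy conformer is kept (ties:
  first in file); hydrogens are dropped on read; heavy-atom,
  single-conformer geometry is what all downstream stages assume.
* Residues with unknown names and no base-like ring default to `other`
  and never enter duplexes.
* Files without an experiment method in the header are *accepted with a
  warning* by the screening filter (generated fixtures have no header);
  a header that names a non-diffraction method excludes the entry.
* Greedy pair assignment: hydrogen-bond count first, then C1'–C1'
  distance; deterministic for reproducible catalogues.
* Step failures (missing ring atoms, degenerate pairing) mark the
  affected steps as missing rather than aborting a profile or a
  trajectory column.

## Problem sizes

The tested configurations are: 11-bp duplexes (5–10 bp in randomised
property tests), 500 random profiles for the round-trip sweep, 100
random rigid motions and strand reversals, and 2000-snapshot ensembles
for trajectory recovery (smaller ensembles in unit tests, where the
3·SD/√n sampling bound is asserted instead of a fixed tolerance). These
sizes make every property check exact or statistically sharp while
keeping the full suite fast.

## Known limitations

* Roll values are mid-step-frame values; agreement with curvilinear-axis
  analyses is bounded (±3° in practice for sharp kinks), not exact.
* Pair detection is tuned for B-DNA with Watson–Crick pairing; triplexes,
  quadruplexes, Hoogsteen pairs and wobble pairs are out of scope.
* The full/partial intercalation rule is a quantitative surrogate for a
  visual criterion; borderline insertions may classify differently.
* Crystal-structure re-analysis requires user-supplied coordinate files;
  the package neither downloads nor redistributes PDB entries.
* Curation implements the two documented correction cases (dangling-end
  trimming, flip-out flagging); manual editing beyond those is not
  automated.
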