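# dnakink

Coordinate-level detection and analysis of protein-induced DNA kinks.

Many DNA-binding proteins — chromatin compactors such as Sac7d and TFAM,
transcription factors such as TBP, Sox-family HMG boxes, or CcpA — bend
their target DNA sharply at a single base-pair step, frequently by
intercalating hydrophobic sidechains (Leu, Met, Val, Phe) between the two
base pairs of that step. The natural observable for such a kink is the
**roll** angle of the base-pair step: the rotation of one base pair
relative to the next about the step's long in-plane (y) axis, with
positive roll opening the step toward the minor groove. A step whose roll
exceeds **35°** is called a kink, and the largest roll in a complex is its
**kink angle**.

`dnakink` is an R package, in the spirit of bio3d, for structural
biologists who want to run this analysis on crystal structures and
trajectory snapshot ensembles:

* **Duplex curation** — Watson–Crick base-pair detection by geometric
  criteria, assembly of antiparallel duplexes (several independent
  helices per model are handled), trimming of dangling single-stranded
  ends that would shift the pairing register, and flagging of flipped-out
  bases whose spurious large rolls must not be reported as kinks.
* **Step parameters** — least-squares fitting of the standard reference
  frame to each base (Kabsch superposition onto embedded idealised base
  geometries), pair frames, and the six rigid-body step parameters
  (shift, slide, rise, tilt, roll, twist) by the mid-step-frame scheme.
* **Kink and intercalation calls** — roll > threshold kink calling, and a
  slab test that finds sidechain heavy atoms inserted between the two
  base-pair planes of a kinked step, classified *full* or *partial* by
  inserted-atom fraction and insertion depth.
* **Mutant building** — in-silico truncation of intercalating sidechains
  to alanine or glycine (`truncate_sidechain()`), the starting point for
  comparative wildtype/mutant simulations.
* **Trajectory statistics** — equidistant snapshot selection (2000 per
  trajectory by default), snapshot × step roll matrices, average roll
  profiles, Gaussian fits `y = a·exp(b·(x−c)²)` to per-step roll
  histograms, and a three-way stability classification
  (`stable_large_kink` / `stable_reduced_kink` / `unstable`, the last
  detecting kinks that wander to an adjacent step).
* **Synthetic B-DNA generator** — `build_duplex()` constructs coordinates
  from a prescribed step-parameter profile as the *exact inverse* of the
  measurement, plus seeded snapshot ensembles, planted intercalators,
  overhangs and base flip-outs, so the whole pipeline is verifiable by
  round-trip recovery without any deposited structure.

## Worked example

Build an 11-bp duplex with a 50° kink at step 5, plant a leucine wedge at
the kinked step, and analyze it:

```r
library(dnakink)
prof  <- step_profile("ACGTACGTACG", roll = c(0, 0, 0, 0, 50, 0, 0, 0, 0, 0))
model <- build_duplex(prof)
wedge <- plant_intercalator(model, step_index = 5, "LEU", depth = 2.2)
ana   <- analyze_structure(wedge)
ana$kinks
#>   step_index roll dinucleotide threshold_used flip_adjacent duplex
#> 1          5   50           AC             35         FALSE      1
ana$intercalations
#>   chain resno resid step_index n_inserted_atoms n_sidechain_atoms
#> 1     P     1   LEU          5                4                 4
#>   insertion_depth classification duplex
#> 1             2.2           full      1
```

The one step with roll above 35° is called as the kink (50°, at the AC
dinucleotide), and the planted leucine is recovered with all four
sidechain heavy atoms inside the step slab at 2.2 Å insertion depth —
a *full* intercalation.

A synthetic "trajectory" fluctuating about a 54° kink (per-step roll SD
8°) is summarised the same way an MD snapshot ensemble would be:

```r
prof54 <- step_profile("ACGTACGTACG", roll = c(0, 0, 0, 0, 54, 0, 0, 0, 0, 0))
ens    <- simulate_roll_ensemble(prof54, roll_sd = 8, n_snapshots = 500, seed = 1)
res    <- analyze_trajectory(ens, config = kink_config(n_snapshots = 500))
round(res$average_profile, 2)
#>    AC    CG    GT    TA    AC    CG    GT    TA    AC    CG
#> -0.19  0.40  0.36 -0.08 54.16 -0.43 -0.26  0.44 -0.62 -0.03
res$histogram_fit
#> gaussian histogram fit: a=52.26, b=-0.0091, c=54.53 deg (sd 7.42), rss=575.45
res$stability
#> stability: stable_large_kink (ref step 5, occupancy 1.00, mean kink 54.2 deg)
```

The average profile peaks at the planted step, the Gaussian fit recovers
the planted center and spread within sampling error, and the step is
classified as a stable large kink (the kink never migrates to a
neighbouring step).

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "dnakink", package = "dnakink")`:

```sh
dnakink screen  complex1.pdb complex2.cif --threshold 35 --tsv report.tsv
dnakink analyze complex.pdb --steps steps.tsv
dnakink traj    snapshots.pdb --n-snapshots 2000
dnakink simulate ACGTACGTACG --kink-step 5 --roll 50 --out kinked.pdb
```

`screen` emits one catalogue row per input file with its outcome
(`analyzed`, or the first matching exclusion: RNA content, modified
nucleotides, no assemblable duplex, non-crystallographic method), kink
calls and intercalating residues.

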