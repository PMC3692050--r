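---
title: "Models and methods behind remfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind remfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remfold)
```

`remfold` is a desk-scale toolkit for template-based ("consensus") and
template-free ("de novo") protein structure modeling on a coarse-grained
Cα trace. This vignette is the package's own account of the science: the
representation and its surrogate energy, the restraint model, the sampler,
the model-selection rules, the numerical choices behind each, and what the
synthetic test bed does and does not demonstrate.

## Representation: the Cα trace

A conformation is one 3-vector per residue, the Cα position in Ångström.
Consecutive beads are connected by virtual bonds whose equilibrium length
is 3.8 Å; the audited geometric envelope is a bond window of [3.4, 4.2] Å
and a hard-clash distance of 4.0 Å between non-adjacent beads (standard
Cα-trace statistics; both configurable). Everything downstream — restraint
distances, RMSD, GDT_TS, radius of gyration, end-to-end distance — is
defined on this trace, so no information is lost between stages.

This is a deliberate reduction. Production coarse-grained force fields add
Cβ/side-chain centers, lattice discretization and knowledge-based
statistical potentials; those are outside the scope of this package. The
internal energy used here is a transparent **surrogate**:

* **bonds** — harmonic, `k_bond (d − 3.8)²` with `k_bond = 10` model units
  Å⁻²;
* **pseudo-angle bias** — for residues assigned helix (H) or extended (E)
  secondary structure, `k_angle (θ − θ₀)²` on the Cα pseudo-bond angle,
  with θ₀ = 91° (H) and 120° (E) and `k_angle = 5` rad⁻²; coil (C) carries
  no bias, so when in doubt the caller should under- rather than
  over-assign regular structure;
* **excluded volume** — soft-core `k_rep (4.0 − d)²` for non-adjacent
  pairs closer than 4.0 Å, `k_rep = 10`.

Energies are dimensionless "model units" and only relative values are
meaningful; temperatures are likewise dimensionless. The absolute scale
was fixed once so that at the cold end of the default ladders (T = 1.0)
bond fluctuations are a few tenths of an Ångström and the chain is nearly
frozen, while at T = 3.5 most local moves are accepted.

## Consensus distance restraints

Templates are partial Cα traces whose residue numbers are the alignment to
the query (numbering beyond the query length is rejected; insertion codes
are rejected; residue identity is deliberately *not* checked, only
numbering). Restraint generation has three regimes:

1. **min/max** — when the minimum pairwise template GDT_TS is ≥ 0.3, each
   eligible pair (i, j) is restrained to the interval
   [min observed dᵢⱼ, max observed dᵢⱼ]. Every template must cover the
   pair: taking a min/max over a partial subset would silently narrow the
   range.
2. **distribution** — when any template pair scores GDT_TS < 0.3, the
   observed distances are summarized as mean ± one standard deviation;
   pairs covered by at least two templates qualify. The σ convention is
   the population σ (divide by n), switchable to sample σ. No σ multiplier
   or additive padding is applied; the lower bound is floored at 3.0 Å to
   avoid unphysical ranges.
3. **single template** — the template geometry is enforced on covered
   pairs as [d − τ, d + τ] with τ = 1.0 Å by default; uncovered residues
   get no restraints and fold de novo (this is also how loop modeling
   arises: a single template with missing fragments).

Pair eligibility in all regimes: sequence separation |i − j| ≥ 5 (local
geometry is the chain model's job) and mean distance ≤ 25 Å (very long
distances carry little signal); both configurable. Restraint energy is a
flat-bottom harmonic: zero inside the range, `weight · dev²` outside,
which is continuous and vanishes exactly on the satisfaction region.
Default weight 1.0; the directive language (`A i j dmin dmax`,
`D r1,r2,a–b`) lets users add or remove restraints, with deletions applied
before additions.

## GDT_TS and superposition

Superposition is the closed-form Kabsch least-squares fit over the common
residue set (at least three shared residues). GDT_TS is the mean over the
1/2/4/8 Å thresholds of the maximal fraction of common residues
superposable within the threshold, reported as a fraction in [0, 1] to
match the 0.3 regime gate. The maximization is the standard iterative
seed-extension heuristic: superpose on a seed subset, re-include all
residues within the threshold, re-superpose to a fixed point, take the
best over seeds. Seeds are all contiguous 3-, 5- and 7-residue windows
plus the full set; for tiny instances (≤ 8 common residues) the seeds are
instead *all* residue subsets of size ≥ 3, which makes the search
provably equivalent to exhaustive subset superposition at negligible cost
and anchors the test suite's oracle-equality checks.

## Replica-exchange Monte Carlo

Sampling uses three reversible local moves with fixed probabilities
(single-bead displacement ≤ 0.7 Å, 60%; two-bead crankshaft about the
flanking chord, ±30°, 30%; terminal-bead pivot, ±30°, 10%), each proposal
accepted by the Metropolis rule `min(1, exp(−ΔE/T))`. One cycle is one
sweep (chain-length proposals) per replica followed by one exchange phase:
adjacent pairs, alternating even/odd pairing by cycle parity, swap with
probability `min(1, exp((1/T_a − 1/T_b)(E_a − E_b)))`.

The ladder defaults to 20 replicas spanning 3.5→1.0 (de novo) or 2.0→1.0
(consensus), geometrically spaced — the uniform-acceptance heuristic; the
endpoints are exact and a flat ladder (e.g. 2.0–2.0) degenerates to
independent chains with always-accepted swaps, useful for studying
transient conformers. "Lowest-energy replica snapshots" are resolved per
recording point: at each one, the replica currently holding the minimum
total energy contributes the snapshot and its observables (energy, radius
of gyration, end-to-end distance). Recorded energies are recomputed from
scratch at each recording point, so incremental-update drift cannot
accumulate into the record; the test suite verifies recorded energies
against an independent full recomputation.

The production sweep runs in compiled code with one dedicated RNG stream
per replica (plus one for exchange decisions),
all derived from the master seed. Consequences worth stating: runs are
bit-reproducible for a given seed and configuration, and changing the
replica count does not silently reshuffle the randomness of the remaining
replicas. The default cycle budget (2000 cycles, i.e. roughly
2000·n proposals per replica for an n-residue chain) is a desk-scale
choice; serious sampling should raise it.

## Clustering and model selection

Snapshots are embedded as vectors of inter-residue distances over pairs
with |i − j| ≥ 3 — a rotation/translation-invariant featurization — and
partitioned by K-means (Lloyd's algorithm, k-means++ seeding, fixed seed;
K = 10 by default with the top 5 clusters reported). Clusters emptied
during iteration are repaired by splitting the largest cluster. The
implementation is in-package so the repair rule is deterministic;
`stats::kmeans` serves as an independent cross-check in the tests.

Clusters are ranked by **density**, defined here as
`members / (1 + average intra-cluster RMSD)` — occupancy per tightness;
ties break by size, then mean snapshot energy. The average intra-cluster
RMSD is the mean over all member pairs of superposed RMSD (exact up to 200
members, fixed-seed subsampled above). The representative rule: if the
average intra-cluster RMSD exceeds **2.15 Å** the medoid is returned (the
member minimizing summed dissimilarity); otherwise the coordinate-average
structure, built after superposing every member onto the medoid. Averages
of tight clusters are demonstrably more central than any single member,
but averaging can break chain geometry, so averaged traces (and written
medoids, which are raw Monte Carlo snapshots) are regularized by a short
local minimization of the bond and excluded-volume terms before being
written. Ranked models are cross-analyzed with pairwise RMSD and GDT_TS
matrices.

## The synthetic test bed

`generate_fixture()` builds ideal toy geometries — an α-helix (radius
2.3 Å, rise 1.5 Å, twist 99.1°, ≈ 3.8 Å bonds), a two-strand hairpin, or
a self-avoiding random coil — plus a matching sequence and secondary
structure, and emits templates as copies with independent Gaussian
coordinate noise and optional coverage masks. This emulates the essential
structure of real template sets: consistent-but-noisy observations,
partial coverage, and controllable mutual dissimilarity. It does **not**
emulate real alignment errors (which are systematic, not Gaussian),
register shifts, domain motions, or sequence-dependent energetics — so
passing the recovery tests shows the pipeline machinery is correct and
self-consistent, not that the surrogate energy predicts real protein
structures.

The test suite's problem sizes are deliberate desk-scale choices: toy
chains of 8–30 residues, hundreds to a few thousand Monte Carlo cycles,
10-seed replicates for stochastic claims, a 12-state enumerable toy for
the Boltzmann check, and ≤ 6-residue instances for exhaustive GDT_TS
oracles. Validation inputs follow the documented limits: a 900-residue
hard cap on query length and a ~120-residue recommendation for de novo
runs (longer de novo inputs only warn).

## Degenerate inputs and tie-breaks

* Absent secondary structure defaults to all-coil with a recorded warning.
* Empty restraint sets are legal everywhere; satisfaction is vacuously 1
  (with a warning).
* Distribution-regime ranges are clamped so dmin ≤ dmax after flooring.
* K-means assignment ties go to the lowest cluster index; ranking ties are
  fully ordered (density, size, mean energy, label), so outputs are
  deterministic.
* Coil bridges across template gaps are built by interpolation plus
  transverse jitter followed by Gauss–Seidel bond projection holding the
  anchors fixed; anchors farther apart than the bond window permits raise
  an explicit "unbridgeable gap" error rather than producing a stretched
  chain.
* A single bead has radius of gyration 0; end-to-end distance requires at
  least two beads and errors otherwise.

## Known limitations

The surrogate energy has no hydrogen bonding, no side-chain packing and no
knowledge-based statistics, so de novo runs compact the chain and satisfy
secondary-structure biases but should not be over-interpreted. GDT_TS uses
the common heuristic search, which is a lower bound on the true optimum at
realistic sizes (exact only on the tiny instances where seeding is
exhaustive). All-atom reconstruction and refinement of the Cα models are
out of scope, as are multi-chain inputs and mmCIF.
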