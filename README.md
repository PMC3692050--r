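# remfold

Restraint-guided coarse-grained protein structure modeling in R: consensus
distance restraints from aligned structural templates, replica-exchange
Monte Carlo (REMC) sampling of a Cα trace, and K-means model selection with
density-ranked representatives.

## The problem

Template-based protein structure prediction has to reconcile several
alternative, partially disagreeing structural templates with the physics of
a polypeptide chain; purely *de novo* prediction has to fold a chain with no
template at all. `remfold` implements a single pipeline that covers both
regimes at a desk scale, for method development, teaching and
prototyping. The chain is reduced to its Cα trace (one bead per residue,
virtual bonds near 3.8 Å), which keeps every stage — restraints, sampling,
clustering, scoring — in one consistent representation.

## The method

**Consensus restraints.** Templates are Cα traces aligned to the query by
residue numbering. Template similarity is assessed with GDT_TS (Global
Distance Test Total Score, on a 0–1 scale) between all template pairs. For
residue pair (i, j) with observed Cα–Cα distances d_ij across templates:

- if min pairwise GDT_TS ≥ 0.3 (mutually consistent templates), the
  restraint range is **[min d_ij, max d_ij]**;
- otherwise (at least one pair with GDT_TS < 0.3), the distance
  distribution is used: **[mean(d_ij) − σ(d_ij), mean(d_ij) + σ(d_ij)]**;
- a single template enforces its own geometry, **[d_ij − τ, d_ij + τ]**, on
  the covered fragment only; uncovered fragments are modeled *de novo*.

During simulation each restraint contributes a flat-bottom penalty: zero
inside its range, `weight · (deviation)²` beyond the nearest bound.
Restraints can be edited with a compact directive language
(`A 3 14 7.8 10.12` adds a 7.8–10.12 Å restraint between residues 3 and 14;
`D 55,58,120–160` deletes all generated restraints touching those residues).

**Sampling.** A Metropolis Monte Carlo chain of small local moves
(single-bead displacement, two-bead crankshaft, terminal pivot) runs at
each rung of a 20-replica temperature ladder (defaults 3.5→1.0 *de novo*,
2.0→1.0 consensus), with alternating adjacent-pair replica exchange at
probability `min(1, exp((1/T_a − 1/T_b)(E_a − E_b)))`. The internal energy
is a transparent surrogate coarse-grained field (harmonic virtual bonds,
secondary-structure-dependent pseudo-angle bias, soft-core excluded
volume); the trajectory records the lowest-energy replica's conformation,
energy, radius of gyration and end-to-end distance.

**Model selection.** Snapshots are embedded by their inter-residue distance
vectors, clustered with K-means, and clusters are ranked by density
(members / (1 + average intra-cluster RMSD)). Each cluster's representative
is the coordinate-average structure when the average intra-cluster RMSD is
≤ 2.15 Å and the medoid when it is larger (averages of diverse models can
be unphysical). Models are cross-analyzed with pairwise RMSD and GDT_TS
matrices.

## Worked example

Fold a 30-residue helical toy protein from three noisy templates:

```r
library(remfold)

fx  <- generate_fixture("helix", 30, perturbation = 0.5,
                        n_templates = 3, seed = 42)
rs  <- generate_consensus_restraints(fx$templates)
attr(rs, "regime")      # "minmax"  (min pairwise GDT_TS 0.875 >= 0.3)
nrow(rs)                # 232 restraints

cfg <- run_config("consensus", n_replicas = 8, n_cycles = 800,
                  record_every = 20, seed = 42)
rep <- run_pipeline(fx$sequence, cfg, ss = fx$ss,
                    templates = fx$templates, out_dir = "helix_run")
rep
#> <run_report> mode=consensus regime=minmax seed=42
#>   41 snapshot(s), 8 replica(s), final energy 37.63
#>   rank cluster size avg_rmsd    mode satisfaction
#> 1    1       5   10 1.937981 average    0.8706897
#> 2    2       4    7 1.738433 average    0.8232759
#> 3    3       7    7 2.274774  medoid    0.6250000
#> 4    4       8    4 1.295988 average    0.7974138
#> 5    5       1    4 1.871503 average    0.7413793
```

The model table lists the density-ranked clusters: `size` is the cluster
occupancy, `avg_rmsd` the mean pairwise member RMSD (clusters above 2.15 Å
fall back to the medoid rule, as cluster 7 does here), and `satisfaction`
the fraction of restraints the written model satisfies. The top model
recovers the underlying helix to 0.76 Å RMSD:

```r
m1 <- rep$model_set$models[[1]]
superpose(ca_trace(fx$ideal), ca_trace(m1))$rmsd
#> [1] 0.7604618
```

`run_pipeline` writes `trajectory.pdb` (multi-MODEL Cα trace),
`analysis.tsv` (per-snapshot energy, radius of gyration, end-to-end
distance), `swaps.tsv`, `restraints.tsv`, `models/model_<rank>.pdb`,
`clusters.json`, `matrices.tsv` and `report.json` under the output
directory.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/fold.R fixtures --kind helix --n 30 --perturb 0.5 \
    --templates 3 --seed 42 --out fx
Rscript inst/cli/fold.R run --mode consensus --seq fx/sequence.fasta \
    --ss fx/ss.txt --templates fx/template_1.pdb,fx/template_2.pdb \
    --seed 42 --out helix_run
Rscript inst/cli/fold.R analyze --traj helix_run/trajectory.pdb
```

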