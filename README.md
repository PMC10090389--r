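# limlinker

Analysis of the intrinsically disordered linker connecting tandem LIM
domains in CSRP-family proteins and their homologs.

CSRP proteins (including the muscle LIM protein CSRP3, a Z-disc stretch
sensor implicated in cardiomyopathies) consist of two ~57-residue
zinc-binding LIM domains joined by a flexible linker — 53 residues in human
CSRP3, but spanning a striking **trimodal** length distribution across
homologs: plants tend to carry short linkers, chordates a medium linker
near the human length, and nematodes long linkers. `limlinker` is for
sequence analysts and structural biologists studying this (or any similar
dual-domain-plus-linker) system: it curates homolog sets, quantifies linker
composition and length classes, summarises predicted PTM sites, and
computes geometric summaries of MD-style trajectories of the two-domain
approach.

## What it computes

**Curation.** Hit tables (BLAST-tabular-like TSV) are filtered at query
coverage > 75% and identity > 30% (strict); HMMER3 `--domtblout` tables are
parsed and each sequence classified as dual-LIM / multi-LIM / other /
sub-threshold; dual-LIM sequences are segmented into LIM1 / linker / LIM2
using the alignment coordinates, the linker being everything between the
two domain boundaries.

**Linker propensity.** For amino acid *i* pooled over *N* segmented
sequences with linkers *D<sub>j</sub>* and domains *L1<sub>j</sub>*,
*L2<sub>j</sub>*:

```
P_i = [ Σ_j count_i(D_j) / Σ_j |D_j| ] / [ Σ_j count_i(L1_j D_j L2_j) / Σ_j |L1_j D_j L2_j| ]
```

P = 1 means no enrichment; disorder-promoting residues (P, Q, S, N, T) rank
highest in CSRP linkers.

**Trimodal classification.** A 3-component 1-D Gaussian mixture fitted by
EM (deterministic quantile initialisation, sd floor 0.5 residues) with
posterior short/medium/long classification, plus fixed thresholds
(40/70 residues) as a simple alternative; per-taxon class frequency tables;
PTM-site counts at score cutoffs 0.8 and 0.9 restricted to linker spans.

**Trajectory summaries.** Multi-model PDB reading; Kabsch superposition
RMSD against the first frame; per-residue RMSF; radius of gyration;
an interdomain marker-atom distance (the Cys10–Phe176 CA proxy in human
CSRP3) with a time–distance density map and collapse detection; phi–psi
arrow maps between frames; and a dihedral-basin secondary-structure
timeline.

**Synthetic data.** Generators for every input — homolog sets with a
trimodal linker mixture and decoy architectures, scored PTM tables, and
two-rigid-domain collapse trajectories (120 Å → 35 Å by default) — each
with recorded ground truth and byte-deterministic output given a seed.

## Worked example

```r
library(limlinker)
library(dplyr)

set  <- simulate_homolog_set(synthetic_spec(300, seed = 42))
segs <- segment_sequences(set$sequences, set$domains)

prop <- compute_propensity(segs)
head(arrange(as_tibble(prop), desc(propensity)), 5)
#>   aa    propensity f_linker f_total
#> 1 P          1.66    0.104   0.0629
#> 2 T          1.66    0.100   0.0604
#> 3 N          1.64    0.0998  0.0607
#> 4 Q          1.64    0.0982  0.0598
#> 5 S          1.60    0.0978  0.0613

fit <- fit_length_mixture(segs$linker_length)
fit
#> <linker_mixture> k = 3, n = 270, converged after 11 EM iterations
#>   weights: 0.181, 0.63, 0.189
#>   means:   19.92, 51.83, 89.94
#>   sds:     2.8, 2.95, 2.6
#>   boundaries: 35.15, 72.3
```

The five enriched disorder-promoting residues top the propensity table
(values ~1.6 = 60% over-represented in linkers relative to the whole
two-domain region), and the mixture recovers the three length modes
(20/52/90 residues) with their weights. Trajectories work the same way:

```r
sim <- simulate_trajectory(50, collapse_frame = 25, seed = 42)
ds  <- interdomain_distance_series(sim$trajectory, 10, 149)
detect_collapse(ds, time_bins = 10)
#>   collapse_bin collapse_frame threshold
#> 1            6             26      77.6
```

The two domains approach from 120 Å to 35 Å; the detector reports the first
time bin whose mean distance drops below the midpoint (~77.6 Å), here bin 6
(frame 26), right after the programmed crossing at frame 25.

`run_sequence_pipeline()` and `run_trajectory_pipeline()` chain these
stages end-to-end, writing TSV outputs with provenance headers and a JSON
manifest; `inst/scripts/limlinker.R` exposes the same runs as shell
subcommands (`simulate`, `curate`, `linker-stats`, `traj`).

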