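---
title: "Methods: disordered-linker analysis for tandem LIM-domain proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disordered-linker analysis for tandem LIM-domain proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limlinker)
library(dplyr)
```

## The scientific problem

CSRP-family proteins (CSRP1/2/3) consist of two compact, zinc-binding LIM
domains joined by an intrinsically disordered linker. In human CSRP3 — the
muscle LIM protein of the sarcomeric Z-disc — that linker is 53 residues
long, while each LIM domain is close to 57 residues. Across homologs the
LIM domains are tightly length-constrained but the linker varies widely,
with a striking three-mode (trimodal) length distribution: plant homologs
tend to carry short linkers, most chordates a medium linker near the human
length, and nematodes long linkers. Because the linker mediates how the two
LIM domains approach each other, its length, composition and modification
sites bear directly on CSRP function.

`limlinker` packages the downstream computational analyses of this system:

1. **Curation** — parse homolog hit tables (BLAST-tabular-like TSV) and
   per-domain tables (HMMER3 `--domtblout`), filter on query coverage and
   identity, classify domain architectures, and cut each dual-LIM sequence
   into LIM1 / linker / LIM2.
2. **Linker statistics** — length histograms, a pooled amino-acid
   propensity statistic, trimodal Gaussian-mixture classification,
   per-taxon class frequencies, and PTM-site summaries at score cutoffs.
3. **Trajectory summaries** — geometric analyses of multi-model PDB
   trajectories: superposition RMSD, per-residue RMSF, radius of gyration,
   an interdomain marker distance with a time–distance density map and
   collapse detection, phi–psi arrow maps, and a dihedral-based
   secondary-structure timeline.
4. **Synthetic data** — generators for every input with recorded ground
   truth, so all stages are testable without database retrieval or MD runs.

Homolog retrieval itself (DELTA-BLAST, E-utilities), profile scanning
(hmmscan), homology modelling, the MD engine and the neural PTM predictor
are out of scope: the package consumes their tabular/structural outputs.

## Curation model

Hits are retained when query coverage exceeds 75% **and** percent identity
exceeds 30%, with strict inequalities — a hit at exactly 75% coverage is
dropped. The same coverage rule is re-applied after domain parsing, so
sequences that slipped past the first filter are still excluded.
Annotation status is keyword-based: descriptions containing "hypothetical"
or "unnamed" (case-insensitive, anywhere in the line) are flagged
hypothetical but still analysed.

Architecture labels are: `dual-LIM` (exactly two non-overlapping LIM hits,
nothing else), `multi-LIM` (three or more LIM hits), `other` (any non-LIM
domain present) and `sub-threshold` (no surviving hits). Two design
choices were genuinely open:

* **Coordinates.** HMMER reports both alignment (`ali`) and envelope
  (`env`) coordinate pairs; we use the `ali` pair, 1-based inclusive. The
  envelope is systematically wider and would shorten every linker by a few
  residues; either convention is defensible, but one must be fixed, and
  alignment coordinates are what the aligner actually asserts.
* **Overlapping LIM hits.** Resolved greedily by bit score (the stronger
  hit wins any residue overlap), mimicking standard domain tiling. This is
  never an error: profile scans of tandem repeats commonly produce
  overlapping hits.

The linker is defined purely by domain boundaries — residues
`lim1_end + 1 .. lim2_start − 1` — and may legitimately be empty when the
domains abut. No disorder predictor is involved. Terminal tails outside
LIM1..LIM2 belong to no segment and enter no statistic.

## The propensity statistic

For amino acid $i$ over $N$ segmented sequences with linkers $D_j$ and
domains $L1_j, L2_j$:

$$P_i \;=\; \frac{\sum_j \mathrm{count}_i(D_j) \,/\, \sum_j |D_j|}
                {\sum_j \mathrm{count}_i(L1_j D_j L2_j) \,/\, \sum_j |L1_j D_j L2_j|}$$

i.e. the pooled linker frequency of the residue divided by its pooled
frequency over the whole two-domain region. $P_i = 1$ means no enrichment.
Edge cases are explicit: $P_i = 0$ when the residue never occurs in any
linker but does occur in the region, and $P_i$ is reported missing (`NA`)
when the residue is absent from the region altogether — a 0/0 is not a
zero. The identity $\sum_i P_i f^{tot}_i = 1$ holds on every input and is
asserted in the tests. Pooling before dividing (rather than averaging
per-sequence ratios) matches the equation above; the two differ when
linker lengths vary.

## Trimodal classification

The trimodal structure is formalised as a 3-component 1-D Gaussian mixture
fitted by EM, authored in the package:

* **Initialisation** is deterministic — component means at the 1/6, 1/2,
  5/6 quantiles, equal weights, pooled standard deviation — so fits are
  reproducible without relying on random restarts; the seed only breaks
  ties when quantiles coincide.
* **Degeneracy guard:** component standard deviations are floored at 0.5
  residues. Linker lengths are integers, so without a floor a component
  can collapse onto a single repeated value and send the likelihood to
  infinity. 0.5 residues is half the measurement granularity.
* **Convergence:** relative log-likelihood change below `1e-8`, up to 500
  iterations; the trace is non-decreasing (an EM invariant we test).
* **Class boundaries** are the lengths where the posterior argmax switches
  between adjacent mean-sorted components, located on a fine grid
  (4000 points across the fitted range) — adequate because lengths are
  integers.

Classification is offered two ways: posterior argmax under the fitted
mixture (the principled route), or fixed thresholds. No numeric
short/medium/long boundaries are established in the literature for this
family, so the defaults — short `< 40`, medium `[40, 70)`, long `>= 70`
residues, half-open so a length of exactly 40 is medium — were chosen once
to separate the exemplars (Arabidopsis-like short linkers, the 53-residue
human linker, nematode-like long linkers) and are configurable.

Per-taxon class frequencies normalise within each taxon; sequences missing
from the lineage table are tallied under `Unclassified` rather than
dropped, so counts always reconcile.

PTM summaries count a predicted site at cutoff $c$ iff its score is
$\ge c$ — "cutoff" semantics of prediction servers are inclusive — and
only when its position falls inside the owning sequence's linker span.
Counts at 0.9 can therefore never exceed counts at 0.8, a monotonicity the
tests assert on every input.

## Trajectory summaries

All trajectory analyses are geometric re-implementations of standard
definitions, operating on multi-model PDB files (fixed-column parsing,
MODEL/ENDMDL framing; a file without MODEL records is one frame).

* **Superposition** is the Kabsch algorithm via SVD with a
  proper-rotation constraint (det +1): mirrored structures keep their
  residual RMSD instead of being "fixed" by a reflection. Degenerate
  inputs (fewer than 3 points, collinear sets) are errors. Tests compare
  against a brute-force rotation-grid + refinement oracle.
* **RMSD** is computed per frame after superposing onto the reference
  frame (the first frame by default) over the backbone selection
  (N, CA, C, O). The value at the reference frame is exactly 0.
* **RMSF** superposes every frame onto the reference over the backbone,
  then takes each residue's CA root-mean-square deviation about its mean
  position. Note that in a two-domain collapse the *distal* domain
  inherits large rigid-body motion from the linker, so its whole-body RMSF
  can rival the linker's; the anchored domain is the clean baseline.
* **Radius of gyration** uses unit masses by default — appropriate for CA
  or backbone selections, where mass weighting changes values by well
  under a percent; element masses can be supplied.
* **Interdomain distance** is the Euclidean distance between one named
  atom (CA by default) of two marker residues, without superposition —
  the analogue of the Cys10–Phe176 alpha-carbon proxy used for human
  CSRP3. The time–distance density map bins this series; collapse
  detection reports the first time bin whose mean distance falls below
  the midpoint of the start and end levels. The crossing frame sits at
  that midpoint by construction, so the detected bin is typically the bin
  *after* the one containing the crossing — a one-bin discretisation
  offset inherent to the definition.
* **Dihedrals** follow the IUPAC sign convention, wrapped to
  `[-180, 180)` (so a planar-trans 180 reports as −180), while dihedral
  *differences* wrap to `(-180, 180]` — the opposite half-openness keeps
  deltas symmetric and their magnitudes ≤ 180 (a drift from 170 to −170
  is +20). Chain-terminal phi/psi are undefined, as are residues missing
  backbone atoms.
* **Secondary structure** is assigned from dihedral basins — H for
  phi ∈ [−100, −30] and psi ∈ [−80, −5]; E for phi ∈ [−170, −70] and
  psi ∈ [90, 180) ∪ [−180, −170); else C — then smoothed by relabelling H
  runs shorter than 4 and E runs shorter than 3 as coil. This is a
  deliberate substitution for hydrogen-bond-based assignment (DSSP/STRIDE
  energies): the timeline is consumed only to distinguish intact domains
  from coil, for which dihedral basins suffice. It will disagree with
  STRIDE near helix caps and in borderline bridge regions.

Frame-to-time mapping is linear at 0.2 ns per frame by default, so a
1000-frame trajectory spans 200 ns; frames are indexed 1-based throughout
the package, as is idiomatic in R (the "0th frame" of MD convention is
frame 1 here).

## What the synthetic generators emulate

`simulate_homolog_set()` builds sequences as
`tail + LIM1 + linker + LIM2 + tail` with linker lengths drawn from the
trimodal mixture. Its defaults *are* the study conditions used throughout
the tests and the acceptance script: modes at 20, 52 and 90 residues with
standard deviation 3 and weights 0.2/0.6/0.2 — a dominant central mode at
the human-like length, flanked by well-separated short (plant-like) and
long (nematode-like) modes; 57-residue LIM segments; linkers enriched
threefold in the disorder-promoting residues P, Q, S, N, T. LIM segments
are random sequences carrying the consensus zinc-binding anchor pattern
(C..C...H..C twice); profile fidelity is unnecessary because domain
boundaries travel in the domain table rather than being rediscovered.
Decoy architectures (multi-LIM, other-domain, domain-free) are a
configurable 10% by default — no canonical decoy distribution exists, so
it is a parameter, not a constant. Hit-table coverage/identity values
deliberately straddle the 75/30 thresholds, and a small fraction of
sequences is omitted from the lineage table to exercise the
`Unclassified` path.

`simulate_trajectory()` builds two rigid backbone clusters (fixed internal
dihedrals, ideal bond geometry via sequential internal-coordinate chain
building) joined by a linker whose dihedrals are resampled each frame from
coil basins (PPII / beta / alpha). The marker distance follows a logistic
schedule between the start and end levels centred on the collapse frame,
with Gaussian noise of sd 1 Å clamped positive; the second domain is
rigidly translated along the marker axis to realise each frame's target,
so the recorded truth distance is exact by construction (and the default
120 Å → 35 Å collapse mirrors the documented human-CSRP3 behaviour). Two
things are deliberately *not* physical: the covalent junction between
linker and second domain stretches when the domain is translated, and
there are no forces, solvent or thermostats. The analyses under test are
purely geometric, so geometric plausibility is the design target;
conclusions about real MD energetics cannot be drawn from these fixtures.

`simulate_ptm_table()` draws typed, scored sites inside linker spans, with
a default type mix dominated by phosphorylation and glycosylation as
observed for disordered-region predictions, and tabulates truth counts at
the 0.8/0.9 cutoffs at generation time.

Every generator is byte-deterministic given its seed (RNG state is scoped
and restored), and each emits a truth table against which the downstream
modules are checked exactly — segmentation must recover every true linker
length, PTM summaries must match truth counts exactly, and the distance
series must match the scheduled truth within the noise bound.

What passing these tests does **not** show: real homolog sets carry
alignment uncertainty at domain boundaries, compositional biases beyond a
five-residue enrichment, and taxonomic structure far richer than the
three-class default; real trajectories have correlated dynamics the
per-frame-independent linker resampling lacks. The generators validate
the *machinery*, not biological conclusions.

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale, chosen so the
statistical checks are sharp without being wasteful: mixture recovery uses
20 replicates of n = 1000 lengths (binomial/CLT bounds at n = 1000 make
±0.04 on weights and ±1 residue on means comfortable margins at 3-sigma
mode separation); propensity oracle checks use 20 sets of up to 50
sequences; curation truth-recovery uses sets of 100-500 sequences; the
collapse fixture uses 50 frames of a 167-residue protein. The
`scripts/acceptance.R` entry point recomputes all headline quantities from
scratch with `--seed` controlling every RNG stream and writes them as
JSON.

## Known limitations

* The secondary-structure rule is dihedral-only (see above); do not
  compare its per-residue labels against hydrogen-bond-based tools.
* The EM fit assumes Gaussian components; strongly skewed length modes
  would bias boundaries. With fewer than ~9 observations per component
  the fit is refused.
* `read_multimodel_pdb()` requires a consistent atom table across models
  and reads ATOM records only (no HETATM, no altLoc handling).
* Fixed-threshold linker classes (40/70) are a convention; for datasets
  whose modes sit elsewhere, fit the mixture and use posterior
  classification instead.
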