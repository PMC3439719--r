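---
title: "Quantifying conformational flexibility and secondary-structure wobble in crystal-structure ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational flexibility and secondary-structure wobble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexwobble)
```

## The scientific question

Experimentally resolved protein structures, and the data derived from them
(secondary-structure strings, structure-based sequence alignments), are
routinely treated as a fixed gold standard for evaluating structure and
alignment prediction. Proteins, however, are dynamic: independently
deposited crystal structures of the *same* sequence differ, sometimes
substantially. `flexwobble` measures that variability at three levels:

1. **3D flexibility.** Within a *structural group* — a set of deposited
   chains whose sequences are at least 99% identical — every pair of
   structures is superposed (Kabsch least squares over backbone
   C&alpha; atoms) and scored by RMSD and TM-score. The distribution of the
   per-group maximum RMSD summarises how non-rigid "identical" proteins
   are.
2. **Secondary-structure wobble.** Each structure's DSSP-style 8-state
   assignment is reduced to three states (`E` &rarr; `E`; `H`,`G`,`I`
   &rarr; `H`; the rest &rarr; `C`). After aligning the group's sequences,
   an alignment column showing more than one 3-state label across the
   group is a *wobble site*. The wobble ratio is
   `Rw = Nw / Na * 100`, with `Nw` wobble sites out of `Na` observed
   sites; transition types are tallied as `C<=>E`, `C<=>H` and `H<=>E`.
   The group-level ratio ("wobble total") is regressed, through the
   origin, on the largest pairwise ratio ("wobble single"); a slope `s`
   above 1 means a fraction `(s - 1)/s` of wobble sites appears only in
   intermediate conformations, not between the two most different
   structures.
3. **Alignment variation and its cost.** Across two groups of the same
   family, every cross-pair of structures is aligned by structure. A
   residue aligned to the same partner in *all* comparisons is a *common
   site*; aligned to a gap in all comparisons, a *gap site*; anything
   else, a *multi site*. Counts are averaged over the two proteins and
   divided by the average protein length, so the three ratios sum to
   100%. Each group pair's best and worst comparison (minimum/maximum
   RMSD, or maximum/minimum TM-score) is scored by a BLOSUM62
   evolutionary distance
   `ED = (1 - 2 * sum M(x_i, y_i) / (sum M(x_i, x_i) + sum M(y_i, y_i))) * 100`
   over the columns where both rows carry a residue. The expectation is
   that the structurally better comparison has the lower ED; pairs
   violating it are *exceptions*, and their gap-opening/extension
   differences (after trimming terminal columns without an aligned
   partner) are censused by quadrant.

The package also relates wobble to data quality: every state observed at a
wobble site between two structures is attributed to each structure's
0.1-&Aring; resolution bin, and the per-bin coil fraction is correlated
with resolution.

## Superposition and the structure-based aligner

`kabsch_superpose()` is the closed-form least-squares rotation (SVD with a
determinant sign correction excluding reflections). TM-score uses
`d0 = 1.24 (L - 15)^{1/3} - 1.8`, clamped at 0.5 &Aring; (active for
`L <= 21`), normalised by the shorter chain by default (`norm =
"average"` is offered; published TM-align values depend on the same
choice).

For pairs at or above the grouping identity (0.99) the correspondence is
fixed by the sequence alignment, so within-group RMSD is the plain Kabsch
value over the 1:1 residue pairing — the dominant code path. Below that
identity, `structural_align()` iterates: superpose on the current pairs,
re-align by dynamic programming on the TM-score site similarity
`1/(1 + (d_ij/d0)^2)` with a linear gap penalty of 0.6 and free end gaps,
and stop when the pair set is stable or after 30 rounds, keeping the
iterate with the highest TM-score (earlier iterate on ties, for
determinism). Seeds are the sequence alignment and the best gapless
threading offset. This is a deliberate simplification of fragment-assembly
structure aligners: on near-identical ensembles, where it is used, the
seeds start essentially at the answer.

## Secondary structure without an external DSSP

When classic DSSP files are supplied they take precedence (the per-chain
residue count is validated, and provenance is recorded). Otherwise a
simplified Kabsch–Sander assigner is used: the amide hydrogen is imputed
1.01 &Aring; from N opposite the bisector of the C(i-1) and O(i-1)
directions; the hydrogen-bond energy is
`E = 0.084 (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332` kcal/mol with bonds
accepted below -0.5 kcal/mol (clashing distances clamp at 0.5 &Aring;);
helices come from runs of at least two consecutive n-turns (n = 4, 3, 5
for `H`, `G`, `I`), sheets from the parallel/antiparallel bridge patterns
with ladders of length &ge; 2 as `E` and isolated bridges as `B`; leftover
turn residues are `T`. Bends (`S`) are never emitted (they are accepted on
input and reduce to coil); proline is treated as a non-donor. Helix
assignment at termini is known to drift by a residue between DSSP
versions; the 3-state reduction absorbs most of that, and all wobble
statistics consume only the 3-state strings.

## The synthetic ensemble generator

Every stage is testable without downloads because `generate_dataset()`
builds families of structural groups with known ground truth. A group is
an ideal segment-layout backbone (helix &phi;/&psi; = -57&deg;/-47&deg;,
strand -120&deg;/120&deg;, coil sampled from an extended/PPII-like region;
all N, CA, C, O atoms placed with Engh–Huber covalent geometry by natural
extension). The default layout is 110 residues: two long rigid helices, a
hinge linker, and three short "wobble" helices.

Design choices worth making explicit:

* **Conformers, not noise, create wobble.** A structure either keeps the
  base conformation or (probability 0.6) adopts an alternative conformer
  in which 2 of the 3 wobble helices are melted to compact irregular
  loops. Because every alternative conformer leaves one wobble helix
  intact, no single structure pair exhibits all wobble sites — some exist
  only in intermediate conformers — which is exactly what pushes the
  wobble-total/maximum-wobble-single slope above 1 (about 1.3 under the
  defaults).
* **Ground truth is defined by the generator's own noise-free
  templates:** the true wobble sites of a group are the positions where
  the conformer templates' 3-state strings disagree; the *rigid core*
  (used for false-positive rates) is the interior of never-melting
  helices, at least two residues from each segment end — helix termini
  legitimately fray in any assigner and are excluded from both sets.
* **Heterogeneous flexibility.** Each group is flexible with probability
  0.5; the rest differ only by sub-&Aring;ngstr&ouml;m coordinate jitter
  (0.05 &Aring; in helices, 0.10 &Aring; in coil — refinement-level
  noise). This mirrors real ensembles, where most groups are nearly rigid
  and a minority are strongly flexible, and it gives cross-group
  comparisons both stable (common-site-rich) and unstable
  (multi-site-rich) pairs.
* **Hinges are dihedral perturbations** (Normal, 5&deg; s.d. by default)
  at the centre of a designated coil linker: a &phi;/&psi; change *is* a
  rigid rotation of the downstream domain about the bond axis and keeps
  covalent geometry exact.
* **Resolution is linear in coil content:**
  `resolution = 1.2 + 1.5 * coil_fraction + N(0, 0.15)` &Aring;, clipped
  to [0.8, 3.49]. The qualitative claim "more coil, worse resolution"
  thereby becomes a recoverable parameter: the sign of the fitted
  coil-ratio-versus-resolution slope.
* **Families and groups.** Two families of three groups, 10 structures
  per group (the selection rules require more than 4; real groups average
  a few dozen). Groups of one family differ by 3 substitutions plus an
  N-terminal deletion of up to 3 residues (so cross-group alignments have
  genuine gap sites); 45% of groups carry a point mutation in a third of
  their members. Proline and glycine are excluded from generated
  sequences (proline's missing amide proton makes it a non-donor in the
  hydrogen-bond model; glycine's backbone is atypical).
* One RNG stream, seeded once per dataset, drives every draw in a fixed
  order: identical configuration and seed reproduce the output exactly.

What the generator does **not** emulate: side chains, beta-sheet
topologies in the default layout, ligand-induced conformational change
(ligand flags exist but default to "free"), missing density, and the
amplitude statistics of real ensembles — melted helices move further than
typical crystal-to-crystal differences, so synthetic RMSDs and multi-site
ratios are larger than survey values. Passing the recovery tests therefore
shows that the statistics *detect what they are defined to detect* under
controlled conditions, not that real data would show effects of the same
size.

## Numerical and convention choices

* Sequence identity is matches divided by alignment length including gaps
  (one of several CD-HIT-compatible conventions; configurable through the
  clustering threshold interface). Alignments use BLOSUM62 with gap
  opening 10 / extension 1 in the Biostrings convention (a k-gap costs
  10 + k).
* Greedy clustering is longest-first with lexicographic id tie-breaks;
  the progressive group MSA anchors on the longest member. Both are
  deterministic for a given input set.
* The selection rules are strict as stated: resolution strictly below
  3.5 &Aring; (members with no recorded resolution are removed), strictly
  more than 4 structures per group, at least 3 surviving groups per
  family. When one deposition carries two resolution values, the first
  REMARK 2 value is used.
* Gap-facing columns are *not* mutation sites; mutations are
  substitutions only.
* A wobble column showing all three states increments all three
  transition tallies; in the state-distribution-by-class analysis a
  two-state site contributes 0.5 to each state and a three-state site 1/3
  to each (three-state sites are counted and flagged — the 1/3 rule is
  this package's extension).
* `Na` counts alignment columns with at least one observed state; for the
  identical-sequence groups the analysis targets, this equals the protein
  length.
* The chi-square for wobble enrichment at mutation sites compares
  mutation sites against *all* sites (mutation sites included) with the
  Yates continuity correction — the convention under which the published
  2&times;2 worked example gives 11.59.
* Evolutionary distances are computed on the untrimmed alignment; gap
  counting first deletes terminal columns whose gap run touches either
  end of either row. Zero ED difference between a pair's extremes is its
  own class, not an exception. A quadrant census classifies exceptions by
  the signs of (&Delta;openings, &Delta;extensions), with zero differences
  on an axis or at the origin.
* Degenerate inputs are explicit: singleton comparisons flag the site
  classification as degenerate; trimming that consumes an alignment
  returns zero gap counts with a flag; a group pair whose extremes
  coincide is reported with zero difference.

## Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
ensembles: the default dataset is 2 families &times; 3 groups &times; 10
structures of 110 residues (270 within-group and 600 cross-group
comparisons), the resolution-recovery experiment uses 20 replicates of 1
family &times; 3 groups &times; 8 structures, and property checks use
1,000 random aligned pairs, 50 random point sets against a
quaternion-search oracle, and 100 substitution-count simulations. These
sizes were chosen so a complete run takes a few minutes on one CPU while
every statistic is still estimated from hundreds of sites or comparisons.

## Known limitations

* The built-in assigner is a simplified Kabsch–Sander: no bend state, no
  &pi;-helix preference reordering, no chirality or ladder-merging rules.
  Supplied DSSP files always win over it.
* The structural aligner is rigid-body; hinge motion within a pair is
  averaged over, exactly as in the rigid aligners the analysis emulates.
* Identity clustering is O(n&sup2;) pairwise alignments without word
  filtering — adequate for ensemble-scale inputs, not for clustering the
  whole PDB.
* Family labels come from the metadata table; no profile-HMM search is
  performed.
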