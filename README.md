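# flexwobble

Structural flexibility and secondary-structure wobble analysis of protein
conformational ensembles.

Crystal structures of the *same* protein sequence, deposited independently,
are not identical — and neither is the data derived from them. That matters
whenever resolved structures (or their secondary-structure strings and
structure-based sequence alignments) serve as the gold standard for
evaluating prediction methods. `flexwobble` is for structural
bioinformaticians who want to quantify that variability:

* **Structural groups.** Chains are clustered at 0.99 sequence identity;
  groups are filtered by the survey rules (X-ray resolution < 3.5 Å,
  more than 4 structures per sequence, at least 3 unique proteins per
  family).
* **3D flexibility.** All within-group structure pairs are superposed
  (Kabsch least squares over backbone Cα) and scored by RMSD and TM-score
  (`d0 = 1.24 (L−15)^{1/3} − 1.8`, clamped at 0.5 Å). An iterative
  structure-based aligner (dynamic programming on the TM-score site
  similarity `1/(1+(d/d0)²)`) handles pairs below the identity threshold.
* **Secondary-structure wobble.** DSSP files are read when available;
  otherwise a simplified Kabsch–Sander assigner (electrostatic H-bond
  model, n-turn helices, bridge-pattern sheets) computes 8 states, reduced
  to 3 (`E→E`; `H,G,I→H`; rest `→C`). A group-alignment column with more
  than one 3-state label is a wobble site:
  `Rw = Nw/Na × 100`, with transition types `C<=>E`, `C<=>H`, `H<=>E`.
  The wobble total is regressed through the origin on the maximum pairwise
  wobble single; slope `s > 1` implies a fraction `(s−1)/s` of wobble
  sites existing only in intermediate conformations. Wobble-site states are
  also binned by 0.1 Å of resolution to correlate coil content with data
  quality, and wobble enrichment at mutation sites is tested by
  Yates-corrected chi-square.
* **Alignment variation and evolutionary distance.** Across two groups of a
  family, sites are classified from all cross-pair alignments as common /
  multi / gap (`Rx = Nx/Na × 100`, summing to 100%), secondary-structure
  state usage is profiled per class (wobble sites split their weight
  equally among observed states), and each group pair's extreme
  alignments are scored by the BLOSUM62 evolutionary distance
  `ED = (1 − 2ΣM(x,y)/(ΣM(x,x)+ΣM(y,y))) × 100`. Pairs where the
  structurally better comparison has the *higher* ED are exceptions,
  analysed by gap-opening/extension differences after terminal trimming.
* **Synthetic ensembles.** A deterministic generator builds families of
  groups with known hinge sites, melting (wobble) helices, point
  mutations and coil-correlated resolution, so the entire pipeline is
  testable without downloading a single structure.

## Worked example

```r
library(flexwobble)

# the two worked statistics behind the wobble analysis
wobble_ratio(72, 412)                                   # Eq.-style ratio
#> [1] 17.47573                                          # printed as 17.48%
chi_square_2x2(matrix(c(72, 340, 4027, 29872), 2, 2, byrow = TRUE))
#> 2x2 chi-square (Yates-corrected): X^2 = 11.59, df = 1, p = 0.0006621
evolutionary_distance("AA", "AR")
#> <ed_result> ED = 64.71 over 2 aligned sites (2*3 / 17)

# a full synthetic run
ds  <- generate_dataset(generator_config(seed = 42))
ds
#> <synthetic_dataset> 2 families, 6 groups, 60 structures (110 residues each), seed 42
rep <- run_pipeline(ds)
rep
#> <flex_pipeline>
#>  groups kept: 6 (dropped 0)
#>  within-group comparisons: 270, mean max RMSD 17.905 A
#>  wobble: 6 group table(s), Rw max 28.18%
#> <wobble_regression> n = 6: slope through origin 1.3342 (implied intermediate-conformation fraction 25.0%)
#>  alnvar: 6 group pair(s), mean Rc 0.00% Rm 95.52% Rg 4.48%
#> <exception_report> (rmsd) 6 group pair(s): 3 exception(s), 0 zero-difference
#>  quadrant census: I=1 II=0 III=0 IV=0 axis=0 origin=1
#> <exception_report> (tm) 6 group pair(s): 4 exception(s), 0 zero-difference
#>  quadrant census: I=2 II=1 III=0 IV=0 axis=1 origin=0
rep$resolution_curve
#> <resolution_coil_curve> 10 bin(s), PCC 0.920, slope 0.8892
```

Reading the output: the six synthetic groups produced 270 exhaustive
within-group comparisons; flexible groups drive the mean of the per-group
maximum RMSD, while rigid groups sit near zero. The highest group wobble
ratio was 28.18% of sites, and the origin-constrained regression of wobble
total on maximum wobble single (slope 1.33) implies that about a quarter
of wobble sites appear only in intermediate conformations. Across group
pairs, multi sites dominate in this seed because the flexible groups'
alignments disagree between conformers; the resolution–coil curve recovers
the generator's built-in positive relationship (PCC 0.92) between coil
content at wobble sites and the resolution value.

For real data, point `run_pipeline()` at a directory of PDB files plus a
tab-separated metadata table (`structure_id`, `group_id`, `family_id`) and
optionally a directory of classic DSSP files; every stage writes its table
to the output directory. The survey-scale published values (maximum RMSD
5.43 Å between two particular deposited chains, mean of per-group maximum
RMSD 1.06 Å, maximum wobble ratio 60.69%) require the corresponding
deposited structure set and are therefore only reproducible with those
downloads in place.

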