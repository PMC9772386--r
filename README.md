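# protomod

Proteome-wide comparison of predicted protein 3D structures, built for the
question of which metabolic modules are conserved between distantly related
microbes — for example between an ancient-lineage archaeon and a
deep-branching bacterium — when sequences alone are too divergent to tell.
It is aimed at structural bioinformaticians and microbial evolution groups
working with AlphaFold-style predicted proteomes (PDB files whose B-factor
column carries per-residue pLDDT confidence).

## What it computes

**Structural similarity (SiMax).** Two structures are matched by a
sequence-guided global alignment, superposed with the Kabsch algorithm, and
iteratively trimmed; with `L1`, `L2` the chain lengths, `N_mat` the matched
residues and RMSD the superposition residual,

    SiMax = max(L1, L2) * RMSD / N_mat   [Angstrom]

SiMax < 6 Å is the similar-structure criterion. Because
`max(L1, L2) >= N_mat`, SiMax is never smaller than the RMSD and penalizes
partial matches of long chains.

**Orthology (BBH).** Smith–Waterman local alignments (BLOSUM62, affine
gaps, Karlin–Altschul e-values) define bidirectional best hits, kept at
identity ≥ 30%, coverage > 70% on both sequences, e-value < 1e-5.

**Three-group pair classification.** Same-function pairs between two
proteomes are classified as

* group I — ortholog sequence, similar structure (SiMax < 6);
* group II — non-ortholog, similar structure;
* group III — non-ortholog, different structure;

and summarized per metabolic module (fractions and dominant group).

**Structural features.** Per protein: polar-contact hydrogen bonds (N/O
pairs ≤ 3.5 Å), salt bridges (acid O – base N ≤ 4 Å), disulfides
(SG–SG < 2.1 Å), Shrake–Rupley SASA on a deterministic Fibonacci lattice,
relative surface area (SASA / probe-0 molecular surface), Kabsch–Sander
secondary structure collapsed to H/E/C, and two-sided Wilcoxon rank-sum
comparisons between proteomes (exact enumeration for small samples).

**Active sites.** A target is superposed onto a ligand-bearing reference
(required SiMax < 6); site residues are those with any heavy atom within
4 Å of the ligand in the reference frame.

**Enzyme-family clustering.** All-vs-all SiMax and global-alignment
identity matrices, average-linkage clustering, cluster cuts and taxon
concordance; dendrograms export as Newick.

**Macromolecular resilience.** From elastic neutron-scattering intensities
S(q, Δt), the Gaussian approximation `S = exp(-q^2 <x^2>/6)` yields the
mean-square displacement per temperature, and a weighted straight-line fit
gives the effective force constant `k' = 0.00276 / (d<x^2>/dT)` in N/m.

A seeded synthetic-data module generates every input with known ground
truth — idealized helix/hairpin proteomes with planted module/group
structure, ligand-bearing references, and elastic scans with linear MSD —
so the whole pipeline runs and is testable offline.

## Worked example

The numbered drivers under `analysis/` run the full demonstration; each is
a thin wrapper over package functions and writes its tables under
`results/workspace/`:

```sh
Rscript analysis/01_simulate.R     # proteomes, family, references, scans
Rscript analysis/02_features.R     # per-protein features + rank-sum tests
Rscript analysis/03_orthologs.R    # bidirectional best hits
Rscript analysis/04_classify.R     # SiMax, groups, module composition
Rscript analysis/05_active_site.R  # ligand-proximity site mapping
Rscript analysis/06_cluster.R      # enzyme-family clustering
Rscript analysis/07_resilience.R   # MSD and k' fits
```

`analysis/04_classify.R` prints, for the 137-pair/16-module demonstration:

```
Classified 137 pairs: I=96, II=17, III=24
Planted-label agreement: 100.0%
Module dominance:
 module_id  n    frac_I   frac_II frac_III dominant
       M01 12 1.0000000 0.0000000        0        I
       ...
       M13 12 0.4166667 0.5833333        0       II
```

i.e. every module recovers its planted dominant group, including the mixed
membrane-bound hydrogenase module M13 (5 group-I + 7 group-II subunits).
`analysis/07_resilience.R` prints the fitted stiffness per sample:

```
 sample   k_prime      k_error k_truth t_min t_max
   3DAC 0.6673915 0.0018406568    0.67   277   349
   A501 0.7856808 0.0063669589    0.78   277   310
 E.coli 0.3101612 0.0002964671    0.31   277   358
```

The hyperthermophile condition (A501) is the stiffest (k' ≈ 0.78 N/m), the
mesophile (E. coli) the softest (≈ 0.31 N/m): higher resilience, flatter
MSD-versus-temperature slope.

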