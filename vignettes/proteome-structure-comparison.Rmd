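---
title: "Methods: proteome-wide structure comparison and module conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide structure comparison and module conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protomod)
```

# Scope and model

`protomod` compares predicted 3D structures between whole proteomes to ask
which functions are conserved in structure even where sequences have
diverged beyond recognition. The pipeline is: per-protein structural
features; pairwise structural similarity (SiMax); sequence orthology
(bidirectional best hits, BBH); three-group classification of
same-function pairs; module-level composition; active-site mapping;
enzyme-family clustering; and, on the biophysics side, macromolecular
resilience from elastic neutron scattering. Every stage can run on
synthetic inputs with planted ground truth, which is how the test suite
and the acceptance script exercise it.

## Structural similarity: SiMax

For a protein pair we build a residue correspondence by global sequence
alignment (BLOSUM62, affine gaps), superpose the matched CA atoms with the
Kabsch algorithm (rotation constrained to determinant +1, so reflections
are excluded), and iteratively trim outlier pairs. With chain lengths
$L_1, L_2$ and $N_{mat}$ retained pairs,

$$\mathrm{SiMax} = \max(L_1, L_2)\,\frac{\mathrm{RMSD}}{N_{mat}},$$

in Angstrom; SiMax < 6 is the similar-structure rule, applied strictly.
Since $\max(L_1,L_2) \ge N_{mat}$, SiMax $\ge$ RMSD: a pair can only look
good if most of the longer chain participates in a tight superposition.

Three choices here were genuinely open and are worth recording:

* **Correspondence is sequence-guided, CA-only.** The score's original
  setting uses a dedicated structure aligner; no published geometric
  definition of the alignment step exists to reproduce. A global sequence
  alignment is the simplest deterministic, dependency-light choice, and
  the aligner is pluggable (all scoring goes through one internal
  function). RMSD over all shared heavy atoms of the matched residues is
  available as `rmsd_mode = "heavy"`; CA mode is the default because it is
  insensitive to side-chain placement differences between prediction
  pipelines.
* **Gap penalties are stiff (open 20, extend 4).** At the low identities
  where group II pairs live (~15%), permissive penalties let the aligner
  open spurious gaps and shift the register by a few residues, which
  inflates RMSD through no fault of the structures. Stiff penalties keep
  same-length alignments essentially gapless while still opening gaps for
  true indels, where the score gain is large. Both penalties are exposed
  in `run_config()`.
* **Trimming defines $N_{mat}$.** Pairs with residual beyond
  max(2 x RMSD, 3 Å) are dropped and the superposition repeated to a fixed
  point, never retaining fewer than max(0.3 x initial, 3) pairs. This is
  the package's operational definition of "aligned residues"; it converges
  in a few iterations on noisy-but-rigid pairs and removes isolated
  outliers exactly.

Alignment tie-breaking follows the deterministic traceback of the
underlying aligner (Biostrings), so repeated runs are byte-identical.

## Orthology

Smith–Waterman local alignment (BLOSUM62, gap open 11/extend 1, `X`
scored 0) gives per-pair scores; e-values use the ungapped
Karlin–Altschul form $E = K m n e^{-\lambda S}$ with $\lambda = 0.267$,
$K = 0.041$, with $n$ the total database length. A pair is an ortholog
iff it is a mutual best hit and passes identity ≥ 0.30, coverage > 0.70
on *both* sequences (the stricter reading of "coverage > 70%"), and
e-value < 1e-5. The identity cutoff is inclusive (≥ 30%); both the
threshold and the comparison are configurable. Because the aligner is
symmetric, the two directions of a BBH share identity and e-value; ties
for best hit break by lexicographic partner id. These approximations mean
absolute ortholog counts from heuristic database search tools will differ
somewhat; cutoff behavior and mutuality, not tool-exact counts, are the
tested surface.

## Classification and modules

Groups: I = ortholog with SiMax < 6; II = non-ortholog with SiMax < 6;
III = non-ortholog with SiMax ≥ 6. The combination ortholog-with-
different-structure is undefined in this scheme; it is flagged
`anomalous`, reported as III with a warning, and never silently binned.
Candidate pairs come from shared function labels plus explicitly declared
similar-function links (same reaction, different cofactor); one-to-many
function matches resolve to the lowest SiMax with alternates logged.
Module composition reports per-module group fractions and the plurality
group, with ties reported as no-dominant. Replicate SiMax values (e.g.
from different prediction models) feed `classification_stability()`,
which flags pairs whose group flips across the 6 Å threshold.

## Structural features

* Hydrogen bonds are *polar contacts*: unordered N/O–N/O atom pairs from
  different residues within 3.5 Å, excluding the covalent peptide
  O/C(i)–N(i+1) pair. No angle criterion by default — the underlying
  definition in the visualization tool this mirrors is undocumented, so
  the simplest distance rule is used and the cutoff exposed.
* Salt bridges: side-chain O of Asp/Glu vs side-chain N of Lys/Arg/His
  within 4 Å, counted once per residue pair (bidentate contacts would
  otherwise double-count; per-atom counting is available).
* Disulfides: SG–SG < 2.1 Å, strict.
* SASA: Shrake–Rupley with a deterministic Fibonacci sphere lattice
  (default 960 points/atom, probe 1.4 Å) and a fixed radius table
  (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, P 1.8 Å); bit-stable across runs.
  RSA divides by the same algorithm at probe 0 — the plainest reading of
  "molecular surface area" that stays self-consistent; per-residue
  max-ASA normalization is deliberately not the default.
* Secondary structure: Kabsch–Sander hydrogen-bond energy
  $E = 0.084\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN}) \times 332$
  kcal/mol with threshold −0.5 and an amide hydrogen placed from the
  previous residue's C=O frame; i→i+4 bond runs give H, ladder patterns
  give E, else C. This is an approximation by design: the three-state
  collapse discards the rarer eight-state classes.
* Rank-sum comparisons: midrank ties; exact enumeration of all group
  splits for $n_1+n_2 \le 12$ (valid under ties, which the standard
  exact implementation refuses), otherwise the normal approximation with
  continuity and tie corrections.

## Resilience

Per temperature, ln S vs $q^2$ is fitted over the instrument window
0.27–1.97 Å⁻¹ (weights $S^2/\sigma_S^2$, the delta method for the log
transform) and inverted through $S = \exp(-q^2\langle x^2\rangle/6)$;
the MSD series is then fitted with a weighted straight line and
$k' = 0.00276/(\mathrm{d}\langle x^2\rangle/\mathrm{d}T)$ N/m. For a
linear model the Levenberg–Marquardt solution *is* weighted least
squares, which is what the implementation uses (a test cross-checks
against an LM optimizer). A non-positive slope — softening with
temperature — is refused as non-physical rather than returned as a
negative stiffness.

# The synthetic-data generator

The generator emulates the statistical structure of the study conditions,
not protein physics:

* **Proteome pair.** 16 modules, 137 same-function pairs (the module
  sizes printed in the source study are used where stated — 19
  amino-acid-biosynthesis, 3 NAD(P)+, 5 upstream-glycolysis, 12 MBH with
  a 5 I / 7 II split, 13 MBS with 10 I / 3 II — the rest are this
  package's choice summing to 137). Group I pairs share a fold at ~50%
  identity, group II at ~15% (below the 30% cutoff), group III pairs put
  the partners on distinct folds (alpha helix vs two-strand beta
  hairpin); partner-B structures get isotropic coordinate noise
  (sd 1 Å per coordinate per group) plus a random rigid motion. Chain
  lengths are drawn from 60–90 residues. pLDDT fields are filled with
  N(90, 5) clipped to [0, 100], so default confidence filtering passes;
  lower means exercise the below-threshold path.
* **Folds.** Backbones come from standard internal coordinates with
  (phi, psi) = (−57, −47) for helices and (−139, 135) for lone strands.
  The hairpin's strands use (−129, 126), where the per-residue screw is
  an exact two-fold — a rigid antiparallel copy can then hydrogen-bond
  along the whole ladder — and the inter-strand placement is a
  deterministic grid search scored by Kabsch–Sander bond counts, cached
  per length.
* **Elastic scans.** $S(q,T) = \exp(-q^2(a+bT)/6)(1+\varepsilon)$ with
  $\varepsilon \sim N(0, \mathrm{noise}^2)$ on the 0.27–1.97 Å⁻¹ grid.
  The three demonstration conditions use ground truths 0.78, 0.67 and
  0.31 N/m over heating ranges 277–310, 277–350 and 277–360 K, with an
  MSD baseline of 0.3 Å² at 277 K. The demonstration noise level is
  0.001 (relative), chosen so the replicate scatter of the fitted k'
  sits well inside the reported uncertainties of the measured values
  (±0.015–0.022 N/m), as for the instrument data; the coverage property
  is checked separately at noise 0.01, where it is self-calibrating.

What passing on this generator does **not** show: real predicted
proteomes have side chains, domain architecture, loops, and confidence
that correlates with disorder; the generator's folds are idealized
secondary-structure elements with CB stubs, its sequences are uniform
random, and its noise is isotropic. Recovery rates here validate the
pipeline's logic and thresholds, not its behavior on real structural
error modes (e.g. hinge motions, low-pLDDT tails, register shifts in
homology).

# Problem sizes and determinism

The shipped demonstration runs 137 pairs / 274 proteins, a 26-member
two-fold family, and three elastic scans (12–28 temperatures × 18 q
points); the analysis drivers complete in minutes on one CPU, and the
SASA/RSA columns of the feature stage are computed for a 40-protein
subsample per proteome (the other detectors run proteome-wide). All
randomness flows from explicit seeds; generators with a fixed seed are
bit-reproducible, stage outputs embed a configuration hash, and reruns
with unchanged config reproduce outputs byte-for-byte.

# Known limitations

* SiMax values depend on the correspondence; against structure-aligner
  implementations the absolute values for remote pairs can differ, so
  published per-protein SiMax values are not expected to reproduce
  exactly.
* The e-value model is ungapped Karlin–Altschul, not a full gapped
  BLAST statistic; ortholog counts at the e-value margin are
  tool-dependent.
* "Molecular surface area" as probe-0 Shrake–Rupley differs from a
  Connolly (solvent-excluded) surface; RSA values are comparable within
  this package, not across tools.
* The secondary-structure assignment is a three-state Kabsch–Sander
  approximation of an unpublished method; helix/sheet fractions should
  agree closely, per-residue labels near element boundaries may not.
* Multi-chain assemblies are out of scope (first chain only); insertion
  codes are rejected.
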