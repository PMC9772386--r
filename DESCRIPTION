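Package: protomod
Title: Proteome-Wide Protein Structure Comparison and Metabolic Module
    Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares predicted 3D protein structures between proteomes to
    classify same-function protein pairs by sequence orthology and
    structural similarity. Implements the SiMax length-normalized RMSD
    score with sequence-guided superposition and iterative trimming,
    bidirectional-best-hit ortholog detection with identity, coverage and
    Karlin-Altschul e-value cutoffs, three-group pair classification and
    metabolic-module composition, per-protein structural features
    (hydrogen bonds, salt bridges, disulfides, Shrake-Rupley solvent
    accessible surface area, relative surface area, secondary structure),
    active-site mapping by ligand proximity in a superposed reference
    frame, hierarchical clustering of enzyme families, and estimation of
    macromolecular resilience from elastic neutron scattering via the
    Gaussian approximation. A seeded synthetic-data generator produces
    toy proteomes, ligand-bearing references and elastic scans with known
    ground truth so every stage runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
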