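Package: ppiface
Title: Residue-Level Analysis and Classification of Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analyses two-chain protein complexes at residue level: computes
    solvent-accessible surface area (Shrake-Rupley quadrature, 1.4 A probe),
    detects interface residues from the change in accessible area on complex
    formation, summarises interface and surface polarity composition, assigns
    complexes to interface classes driven by nonpolar (class A) or polar
    (class B) contacts, counts intermolecular hydrogen bonds and salt bridges,
    scores solvation free-energy gain and a distance-dependent pairwise
    binding-energy potential, computes screened-Coulomb interface
    electrostatic complementarity, and compares feature distributions between
    classes with exact Wilcoxon rank-sum tests and Benjamini-Hochberg
    q-values. Includes a synthetic heterodimer generator with ground-truth
    manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
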