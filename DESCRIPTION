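Package: pepforge
Title: Protein-Peptide Interface Scoring, Conformational Sampling and
    Binding-Assay Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for structure-based peptide design calculations on
    protein-peptide systems such as MDM2/MDMX with linear, stapled and
    D-amino-acid peptides. Provides an empirical four-descriptor interface
    scoring function (hydrophobic and charged-group burial, hydrogen bonds,
    net salt bridges), a simplified heavy-atom force field (12-6 van der
    Waals, distance-dependent-dielectric electrostatics, Gaussian-exclusion
    implicit solvation, nonpolar surface-area term) with four rigid-body
    binding-energy flavors and a two-round minimization protocol,
    dihedral-space multiple-copy simulated annealing with minimization for
    peptide conformational ensembles, constrained Boltzmann-weighted affinity
    estimation around a bound backbone, structure-activity arithmetic and
    correlation statistics over bundled published tables, and exact direct
    and competitive fluorescence-anisotropy binding models with nonlinear Kd
    fitting and a titration simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
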