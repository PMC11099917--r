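Package: fibrilprofiler
Title: Ligand-Binding Profiling and Strain Typing of Amyloid Fibril Polymorphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for differentiating amyloid fibril polymorphs by their
    small-molecule ligand binding profiles. Implements exact mass-balance
    solvers for direct and two-site competitive binding equilibria, fitting
    of fluorescence intensity and anisotropy titrations to 1:1 binding
    isotherms (dissociation constants and the shared-site fraction, %BS1),
    replicate aggregation with t-based confidence intervals, paired
    significance tests, a synthetic titration-data generator with a
    ground-truth eight-polymorph alpha-synuclein reference panel, and
    decision-tree classification of fibril strains including an exhaustive
    search for a minimal discriminating assay panel.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
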