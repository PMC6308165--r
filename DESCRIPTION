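Package: peptox
Title: Peptide Cytotoxicity Assays and Pathway Activation Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing the anticancer cytotoxicity of
    cationic host-defense peptides. Computes sequence-derived
    physicochemical descriptors (monoisotopic and average mass,
    protonated-ion m/z, Kyte-Doolittle GRAVY, basic-residue census),
    quantifies plate-based hemolysis, LDH-release and MTT viability
    assays with four-parameter logistic IC50/HC50 estimation and
    censoring, classifies annexin V/propidium iodide cytometry events
    into quadrants and derives necrosis-versus-apoptosis kinetic
    signatures, and scores transcriptomic responses with the pathway
    activation strength (PAS) statistic built on case-to-normal
    expression ratios and activator/repressor pathway weights.
    Seeded synthetic-data generators emulate each assay with known
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    SummarizedExperiment,
    S4Vectors,
    limma,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
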