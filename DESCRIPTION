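Package: pepatlas
Title: Enteroendocrine Peptidomics: Precursor Mapping, Processing Analysis and Peptide Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for LC-MS/MS peptidomics of gut enteroendocrine
    cells. Maps identified peptides onto prohormone and granin precursors,
    aligns mouse/human homolog pairs and projects coordinates across species,
    classifies peptide termini against prohormone-convertase cleavage rules,
    detects and filters exoproteolytic peptide ladders, computes prevalence-
    filtered differential abundance between lean and diet-induced obese groups
    and fold-over-basal secretion statistics, ranks candidate bioactive
    peptides, and fits one-compartment pharmacokinetic models (half-life,
    non-compartmental AUC, bioavailability, steady-state infusion planning).
    Includes a seeded synthetic-data generator so the whole pipeline is
    testable without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
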