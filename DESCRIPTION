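Package: phosphoHLA2
Title: Discovery, Characterization and Prediction of Phosphorylated HLA-II Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining phosphorylated ligands of class II human
    leukocyte antigen (HLA-II) molecules from mass-spectrometry
    immunopeptidomics identification tables. Implements peptide-spectrum-match
    filtering, allele assignment by position weight matrix (PWM) scoring over
    a 23-letter alphabet (20 amino acids plus phospho-serine, -threonine and
    -tyrosine), binding-core identification with percent-rank calibration,
    phospho binding-motif construction and comparison, positional statistics
    of phosphosites, kinase substrate motif enrichment, and a
    leave-one-sample-out cross-validated predictor benchmark. A synthetic-data
    generator with known ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
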