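Package: iesflow
Title: Simulation and Analysis of Programmed DNA Elimination Phenotypes in
    Paramecium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for the computational phenotyping
    of programmed DNA elimination in the ciliate Paramecium tetraurelia. The
    package computes per-IES retention scores (IRS) from read alignments
    against paired somatic (MAC) and germline-inclusive (MAC+IES) references
    by junction-anchored read counting, analyses ensembles of retention
    scores (histograms, size stratification, subset overlaps, and
    cross-condition correlation with OLS, LOWESS and orthogonal-distance
    trends), classifies small-RNA reads into genome compartments by
    priority-ordered iterative matching with read subtraction, scores
    nucleosome density over IESs from MNase-seq fragments with
    mononucleosome size filtering and Mann-Whitney/Holm statistics, and
    classifies chromodomains as putative H3K9me- or H3K27me-type readers
    from aromatic-cage integrity, clasp polarity and predicted isoelectric
    point. A synthetic-data module generates toy genomes, annotations and
    simulated genomic, MNase and small-RNA read sets with known ground
    truth, so the whole pipeline runs end-to-end with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
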