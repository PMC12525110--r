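Package: kmerstrat
Title: CG-Stratified k-mer Spectrum Analysis of Genome Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds frequency-of-appearance spectra of genomic 8-mers,
    stratifies the 65,536-motif universe by dinucleotide content (0XY, 1XY,
    2XY classes for each of the 16 dinucleotides), and quantifies how far
    each stratum's internal 3-mer and 4-mer usage diverges from the
    genome-wide usage via a symmetric relative entropy, a distance deviation
    and an angular deviation.  Peak positions of smoothed stratum spectra are
    compared with a label-shuffling permutation test, CpG islands are
    detected by a sliding-window GC/observed-expected criterion and can be
    excised before re-analysis, and seeded synthetic genomes (i.i.d. or
    dinucleotide-Markov with tunable CpG suppression, optionally carrying
    embedded CpG islands) provide fully reproducible fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    zoo,
    Rcpp,
    methods,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
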