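Package: nucsense
Title: Differential MNase-seq Analysis of Nucleosome Sensitivity and
    Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for differential micrococcal nuclease (MNase) digestion
    experiments that distinguish MNase-sensitive from MNase-resistant
    nucleosomes. Builds normalized dyad-density and occupancy profiles from
    paired-end fragments (including dinucleosome-sized fragments), classifies
    genomic base pairs into MNase-sensitive/resistant and open/closed
    chromatin states, computes dinucleotide-frequency and A/T-content
    statistics, estimates nucleosome repeat lengths by Fourier analysis, and
    implements an exact one-dimensional hard-rod (Tonks gas) model of
    nucleosome positioning: equilibrium solver, closed-form density-to-energy
    inversion, a mono- and dinucleotide sequence-energy fit, and a
    TSS-anchored positioning model. A deterministic synthetic-data generator
    with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
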