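Package: histvar
Title: Histone Variant Quantification and ChIP-Seq Tag Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for histone variant analysis built around the
    H2A.J variant that accumulates in senescent cells. Computes proteoform
    masses and classifies H2A chromatographic fractions, matches deconvoluted
    top-down mass spectra to theoretical proteoforms and quantifies relative
    abundances as intensity fractions, performs in-silico propionylation and
    tryptic digestion to locate diagnostic peptides (Gly5-Arg12) and quantify
    variant fractions from chromatographic peak areas, and analyses stranded
    ChIP-seq tag libraries: duplicate and blacklist filtering, smoothed
    coverage tracks, chromosome-weighted strand cross-correlation with
    fragment-length peak calling, and TSS-anchored metagene log2(IP/Input)
    profiles in 60-bp windows. Seeded synthetic-data generators reproduce the
    statistical structure of each input so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: ChIPSeq, Proteomics, MassSpectrometry, Epigenetics, Software
RoxygenNote: 7.3.3
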