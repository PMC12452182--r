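Package: riboArch
Title: Contiguous Riboswitch Architecture Classification and Enrichment
    Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and classifying contiguous riboswitches
    in prokaryotic genomes. Starting from gene annotations, intergenic
    sequences and covariance-model aptamer hits (Infernal cmsearch tabular
    output), the package calibrates empirical bit-score cutoffs with
    dinucleotide-preserving sequence shuffles, detects Rho-independent
    transcription terminators with a built-in hairpin minimum-free-energy
    engine, groups aptamer hits into contiguous sets, classifies each set
    as tandemly arranged riboswitches or riboswitches with adjacent
    aptamers, and runs hypergeometric enrichment analyses over phyla,
    riboswitch families and orthologous gene groups (COGs). A synthetic
    genome-collection generator with planted ground truth supports
    end-to-end validation without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Genetics, Annotation, MotifDiscovery,
    StatisticalMethod, Transcription
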