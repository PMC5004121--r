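Package: middcontext
Title: Decomposition and Comparative Analysis of Non-CpG DNA Methylation Contexts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing non-CpG (mCH) DNA methylation from
    per-cytosine bisulfite-sequencing call files (BS-Seeker2 CGmap dialect).
    Implements minimum dependence decomposition (MiDD), a recursive
    chi-squared bipartition of 6-mer sequence contexts with cross-sample
    consensus, yielding a hierarchical motif tree of independent methylation
    sub-contexts (e.g. the CW/CC split of mCH). Also provides
    abundance-normalized position frequency matrices for methylation motifs,
    rank-based (Spearman) sample clustering of 6-mer context preferences,
    enrichment of recurrently methylated CW sites in gene subregions and
    repeat families via per-autosome log2 odds ratios, chromosome-scale and
    metaregion methylation profiles, strand-asymmetry (skew) statistics, and
    a fully seeded synthetic methylome cohort generator with planted ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    ape,
    zoo,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
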