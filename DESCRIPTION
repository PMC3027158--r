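Package: medipTile
Title: CpG-Island Tiling-Array Design and MeDIP-chip Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for promoter CpG-island (CGI) methylation profiling with
    methyl-DNA immunoprecipitation (MeDIP) on two-channel tiling microarrays.
    Predicts CGIs in strand-aware promoter windows by windowed GC content and
    observed/expected CpG ratio, tiles 60-mer probes across islands with
    genome-uniqueness filtering at 55-bp resolution, analyses Cy5/Cy3 channel
    intensities (control-mean normalization, presence/intensity/variability
    filters, Welch tests with fold-change cut-offs, median-relative
    methylation classes, PCA quality control, hypergeometric term enrichment,
    expression concordance), quantifies percent methylation from direct
    bisulfite-sequencing C/T peak areas and global 5-methylcytosine from HPLC
    peak areas, and simulates genomes, methylation states, array channels,
    bisulfite traces and HPLC profiles so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
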