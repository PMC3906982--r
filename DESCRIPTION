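Package: tfdirect
Title: Direct Target Gene Identification from ChIP-Seq Binding and
    Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide identification of a transcription factor's direct
    target genes by integrating ChIP-seq peak locations with microarray-style
    differential expression. Implements peak genomic-feature classification
    (promoter, UTRs, exon, intron, downstream, intergenic) with
    size-normalized densities, nearest-TSS distance profiling, replicate
    reproducibility by windowed tag-density correlation, summit-flank
    extraction and IUPAC consensus motif scanning for the AT-rich Abd-B-type
    site, per-gene ANOVA/fold-change responsive calls, binding-gene and
    direct-target bookkeeping, and hypergeometric gene-set
    over-representation with Benjamini-Hochberg FDR. Ships a ground-truthed
    synthetic data generator (toy genome, gene models, replicate peak and tag
    sets with tunable inter-replicate correlation and planted motifs, a
    3-vs-3 expression matrix with planted fold changes) so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
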