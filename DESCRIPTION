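Package: hairpinseq
Title: Small RNA Sequencing Analysis for Plant miRNA Discovery and Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genome-based microRNA discovery from
    small RNA sequencing libraries in plants, built around a four-library
    genotype-by-stage design (two genotypes, juvenile and adult stages).
    Provides read cleanup (3' adapter trimming, length and quality filtering)
    and collapsing to unique tags with per-library counts; ungapped genomic
    mapping with at most one mismatch and classification against structural
    RNA and repeat annotation; homology-based calling of conserved miRNAs and
    de novo discovery of novel miRNAs by hairpin excision with mature/star
    duplex validation (two-nucleotide 3' overhangs) under a built-in
    nested-structure folding engine; reads-per-million expression profiling
    with fold-change, presence/absence and inverse-pattern calls;
    complementarity-based target prediction with positional mismatch penalties
    and duplex-energy ratios; regional-amplification qPCR cleavage-evidence
    analysis; and a deterministic synthetic-data generator that embeds hairpin
    loci among structural RNA and repeat loci for validation of the whole
    pipeline. A packaged 75-entry novel miRNA catalog supports worked
    examples and census statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
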