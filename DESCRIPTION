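Package: bulkscan
Title: QTL-Seq Bulked-Segregant Mapping with Simulation-Based Confidence Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bulked-segregant QTL mapping (QTL-seq) for F2 populations:
    per-site SNP-index and delta SNP-index statistics from pooled allele
    depths, read-depth / spurious-index / homozygosity filtering, sliding
    genomic windows, Monte-Carlo confidence bands under the no-QTL null,
    candidate-region calling, pseudo-reference construction by substitution
    of a parent's homozygous SNPs, and classification of candidate-region
    SNPs against gene models (exon/intron, synonymous/non-synonymous).
    Includes a fully seeded F2 bulk-sequencing simulator (Haldane map
    function, extreme-phenotype bulks, Poisson depth, binomial read
    sampling) so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
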