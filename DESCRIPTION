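Package: clonevar
Title: Clonal Bacterial Resequencing with Wild-Type-Calibrated Variant Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing clonal bacterial mutant genomes
    against their wild-type parent from short-read resequencing data.
    Simulates Illumina-like paired-end reads from annotated reference
    genomes with an explicit mutation truth table, quality-trims reads,
    maps them with a k-mer seed-and-extend aligner, marks duplicate pairs,
    builds per-site pileups and calls SNVs and short indels, filters calls
    with empirical-null thresholds calibrated from wild-type
    self-resequencing false positives (shared-variant subtraction, relative
    coverage and population-fraction rules), detects copy-number gains and
    longer losses from comparative coverage, annotates variant effects at
    codon level with the bacterial genetic code, and clusters strains and
    genes by shared mutated loci using binary-distance complete-linkage
    clustering. Ships transcriptions of a published mutant-strain variant
    catalogue as fixtures for reproducible recurrence analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
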