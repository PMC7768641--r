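Package: strscreen
Title: Genome-Wide Screening of Short Tandem Repeat Expansions from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates short tandem repeat (STR) copy numbers at cataloged loci
    from long-read alignments, aggregates per-genome allele calls into a
    population normal-repeat-range database (per-locus minimum, 95th
    percentile and sample standard deviation), and scores new observations
    against that database to prioritise putatively pathogenic repeat
    expansions using a deviation score with region-dependent thresholds.
    Includes a divide-and-conquer genome-scan driver with time-budget kill
    and regroup semantics, and a deterministic simulator of catalogs,
    population allele counts and noisy locus-spanning reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Rsamtools,
    GenomicRanges,
    IRanges,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
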