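Package: BloomAlign
Title: Partitioned Short-Read Alignment with Bloom-Filter Read Dispatch
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Aligns short reads against large or fragmented references by
    partitioning the target sequences into balanced subsets (keeping
    assembly-graph-connected contigs together), summarising each
    partition's b-mer content in a Bloom filter, dispatching each read only
    to the partitions whose filter reports a hit, aligning partitions
    independently with a pluggable aligner (a built-in exact-match
    seed-and-extend mapper is included), and merging the per-partition SAM
    outputs into a final result equivalent to aligning against the
    unpartitioned reference.  Ships a ground-truthed read simulator so the
    whole workflow is testable without external data or binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    Biostrings,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
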