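Package: msgasm
Title: Genome Assembly with Multi-Step Bi-Directed de Bruijn Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A short-read genome assembler built on the multi-step
    bi-directed de Bruijn graph. Reads are decomposed into canonical
    k-molecules (a k-mer paired with its reverse complement), connected by
    bi-directed edges, cleaned by frequency thresholds, and compacted by an
    associative edge-merging operation scheduled in round-synchronous,
    conflict-free batches so that every unanimous path collapses in a
    logarithmic number of rounds. Heuristic contig extension resolves tips,
    self-loops, parallel edges and coverage-balanced cross vertices before
    contigs are emitted with standard assembly statistics (N50, maximum
    length, total bases). Includes a seeded read simulator (random and
    repeat-free genomes, tiled or sampled reads, substitution errors) and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stringi,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
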