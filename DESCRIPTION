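Package: sfstools
Title: Sample-Specific String Detection in Long-Read Sequencing Data
Version: 0.1.0
Authors@R:
    person("sfstools", "developers", email = "sfstools@example.org",
           role = c("aut", "cre"))
Description: Mapping-free comparative genome analysis through substring-free
    sample-specific strings (SFS): given a target read set and a reference
    read or genome set, enumerates the minimal substrings of the targets that
    never occur in the references.  Provides an FMD-index (a bidirectional
    FM-index over a DNA collection and its reverse complements) with
    constant-time backward and forward bi-interval extension, the Ping-Pong
    search algorithm in its exact (quadratic worst case) and relaxed (linear
    time, edit-distance bounded) variants, abundance filtering of the
    resulting string table, a brute-force oracle solver for validation, a
    diploid trio simulator with coordinate-tracked long reads for end-to-end
    benchmarking, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
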