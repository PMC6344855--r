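Package: periscan
Title: Detection of Periodic DNA and Protein Repeats by k-mer Periodicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised, global detection of periodically repeating DNA and
    protein sequences (tandem, degenerate and interspaced repeats, including
    CRISPR-like arrays) from FASTA or GenBank input. A sliding-window
    cumulative k-mer score locates highly repetitive regions; a
    position-period matrix of identical k-mer pair distances estimates the
    dominant repeat period and a periodicity score; period-sized unit
    fragments are multiply aligned, circularly punctuated and mapped back to
    produce a masked consensus motif. Includes CRISPR candidate filtering,
    interval-overlap benchmark statistics (region overlap agreement, recall,
    precision, positive likelihood ratio), and a seeded synthetic-repeat
    generator with a noise-tolerance experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
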