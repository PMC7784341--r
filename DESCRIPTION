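Package: ribocollide
Title: Analysis of Ribosome Collisions from Disome Footprint Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of ribosome collisions from disome-seq, the
    sequencing of mRNA fragments protected by two stacked ribosomes.
    Classifies monosome and disome footprints by length and reading
    frame, assigns the A- and P-site of the leading ribosome at codon
    resolution via fixed 5'-end offset rules, and quantifies
    translational pausing signals at the A-site, P-site, and exit
    tunnel as Mantel-Haenszel common odds ratios stratified by gene
    against an mRNA-seq or gene-composition background. Includes
    metagene profiling, pause calling and monosome/disome pause
    overlap, a permutation test for cross-species pause conservation,
    a closed-form ribosome geometry model for disome footprint
    lengths, helix/gap association and peptide positional-enrichment
    tests, and a synthetic ribosome-traffic simulator with known
    dwell-time ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
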