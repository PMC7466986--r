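Package: chromforge
Title: Linkage-Map Guided Chromosome Assembly, Inversion Breakpoint
    Localization and Centromere Repeat Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds chromosome-level sequences from assembly contigs and a
    dense SNP linkage map (marker placement by flanking-sequence search,
    linkage-group assignment, chimeric-contig detection and breaking,
    cM-based ordering and orientation, AGP emission), compares two
    chromosome-level genomes through unique k-mer anchors chained into
    strand-consistent synteny blocks to call single and double chromosomal
    inversions with breakpoint intervals, scans genomes for AT-rich
    tandem-repeat arrays as centromere candidates (with Tandem Repeats
    Finder import), and derives sex-specific recombination profiles,
    recombination-suppressed regions and chromosome-morphology calls.
    Includes a synthetic-genome generator that plants inversions,
    centromeric satellite arrays, fragmented and chimeric contigs and a
    heterochiasmic marker map with known ground truth, so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
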