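Package: ppbwt
Title: Chunk-Parallel Positional Burrows-Wheeler Transform for Haplotype Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the positional Burrows-Wheeler transform (PBWT) of a
    phased, biallelic haplotype panel and reports haplotype matches (all
    matches above a minimum length, and set-maximal matches). The positional
    prefix and divergence arrays are constructed chunk-by-chunk: each genomic
    chunk is built independently from sentinel-initialised arrays, then the
    approximate arrays are corrected in a single step per chunk boundary, so
    the expensive sweeps parallelise while producing output identical to the
    sequential algorithm. Includes readers and writers for phased VCF and
    plain 0/1 matrix panels, a match-report TSV format, binary array
    checkpoints, and a seeded synthetic-panel generator with plantable
    duplicate-haplotype groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    tibble,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
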