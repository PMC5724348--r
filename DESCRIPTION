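Package: kmatchdist
Title: Alignment-Free Phylogenetic Distances from k-Mismatch Common Substring Spectra
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates pairwise evolutionary distances between DNA sequences
    without alignment.  For every position of one sequence the longest exact
    match anywhere in the other sequence is found with an enhanced suffix
    array, and the gap-free extension after the first mismatch, up to k
    further mismatches, is recorded.  Under a gap-free Jukes-Cantor model
    the length distribution of these extensions is a mixture of a large
    background and a small homologous negative-binomial component; the
    position of the second (homologous) peak of the smoothed spectrum yields
    the per-site match probability and hence the Jukes-Cantor distance.
    Includes the closed-form length distributions, a sequence-pair
    simulator, peak detection, all-vs-all distance matrices and PHYLIP
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
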