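Package: biobits
Title: Informational Indexes and Entropic Laws of Genome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes k-mer dictionaries, empirical k-entropies and the
    informational indexes of whole genomes: the logarithmic length LG,
    the entropic (EC) and anti-entropic (AC) components of LG obtained by
    evaluating the k-mer entropy at the double logarithmic length
    2LG = lg2(n), the lexical index LX, the anti-entropic fraction AF,
    the horizontal eccentricity EH, and the biobit genomic complexity
    measure BB. Includes a suffix-array engine (SA-IS with Kasai LCP) for
    k-mer spectra and maximal repeat length at large k, seeded Bernoullian
    genome simulation with the random-genome theory of maximal repeats and
    entropy maxima, verification of the informational genomic laws, and
    genome-perturbation experiments testing law survival under deletions
    and window shuffles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
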