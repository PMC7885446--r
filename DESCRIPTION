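Package: molexpand
Title: Demographic Inference and Rate Calibration from Mitochondrial
    Mismatch Distributions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and dates sudden demographic expansions from aligned
    mitochondrial haplotype sequences. Provides haplotype collapsing and
    diversity summaries, Tajima's D and Fu's Fs neutrality tests with
    coalescent-simulation p-values, least-squares fitting of the
    sudden-expansion (Rogers-Harpending) mismatch-distribution model with a
    parametric bootstrap (SSD and raggedness tests, percentile confidence
    intervals for the expansion parameter tau), median-joining haplotype
    networks with star-shape summaries, a seedable coalescent simulator for
    constant-size and instantaneous-expansion demographies, and conversion
    of tau to expansion times and substitution rates against late-Quaternary
    biogeographic calibration points.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
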