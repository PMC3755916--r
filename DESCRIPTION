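Package: segshare
Title: Identifying Pedigree Relationships from Shared Genome Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo gene-dropping simulation of identity-by-descent
    (IBD) segment sharing between uniparental relatives under the Haldane
    crossover model, and likelihood-ratio machinery for discriminating
    pedigree relationships from the number, end-position and length of
    shared segments on each chromosome.  Provides a catalog of nineteen
    relationships spanning full-sib, half-sib and lineal family bases,
    empirical per-chromosome outcome distributions, genome-wide
    log-likelihood-ratio moments (including the Kullback-Leibler distance
    between relationships), normal-approximation misclassification
    probabilities, held-out assignment experiments, and closed-form
    approximations for expected segment counts and lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
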