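Package: twotaxon
Title: Two-Taxon Test for Gene Flow from Genealogical Asymmetry
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects post-divergence gene flow between two populations from a
    single unphased diploid genome per population, with no outgroup and no
    polarization. Implements closed-form and semi-analytic expectations for
    genealogical incongruence and external-branch asymmetry (Ai, Am) under the
    two-population isolation-with-migration model via an exact enumeration of
    the 95 event paths of the structured coalescent, a Monte-Carlo
    structured-coalescent oracle with block-jackknife confidence intervals,
    an estimator of the Am statistic from VCF genotype data across a ladder
    of block sizes, and a generator of fully synthetic VCF fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
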