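Package: gammaMaxT
Title: Permutation-Based Multiple Testing for Genome-Wide SNP Interaction
    Scans
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exhaustive pairwise SNP-SNP interaction scanning with
    model-based multifactor dimensionality reduction (MB-MDR) statistics
    and family-wise error rate control by step-down maxT permutation
    testing.  Three interchangeable backends are provided: classical maxT
    (exact, memory-heavy), a memory-bounded variant that stores only the
    n best observed statistics together with each permutation's exact
    maximum over the remaining pairs, and gammaMAXT, which replaces that
    exhaustive maximum by a draw from a point-mass-at-zero plus
    shifted-gamma tail mixture fitted to a random sample of null
    statistics.  Includes simulators for null genotype data and two-locus
    penetrance-table epistasis with heritability calibration, missingness
    injection, a file-based split/merge workflow for parallel execution,
    and a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
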