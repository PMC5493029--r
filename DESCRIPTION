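Package: neutralsad
Title: Neutral-Theory Analysis of Species Abundance Distributions in
    Microbiome Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Hubbell's neutral theory of biodiversity to per-sample
    species abundance distributions from OTU count tables.  Implements the
    Ewens sampling formula and its maximum-likelihood estimate of the
    fundamental biodiversity number theta, Etienne's dispersal-limited
    sampling formula with joint (theta, m) maximum likelihood built on
    log-space Stirling-number machinery, sequential (urn) simulation of
    neutral local communities, the exact neutrality test that locates an
    observed sample's likelihood within an ensemble of simulated neutral
    communities, likelihood-ratio comparison of the two formulas, and
    two-group cohort summaries (neutrality pass rates with Fisher's exact
    test, group mean theta with a t-test).  Includes a synthetic-cohort
    generator and readers/writers for plain TSV OTU tables and the mothur
    "shared" format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
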