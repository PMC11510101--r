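Package: microgblup
Title: Variance Partitioning of Host Genomic and Gut Microbial Effects on
    Growth and Feed Efficiency Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-step genomic and microbial best linear unbiased prediction
    for growth and feed efficiency traits. Derives average daily gain, feed
    conversion ratio and residual feed intake from raw growth records; builds
    pedigree (A), genomic (VanRaden G), hybrid (H-inverse) and microbial
    (O = MM'/m) relationship matrices; estimates variance components for
    animal models with genomic, microbial and maternal permanent environmental
    random effects by average-information REML, in single-trait and bivariate
    form; and reports heritability, microbiability and genetic correlations
    with delta-method standard errors. A seedable synthetic-herd generator
    with Mendelian gene dropping provides ground-truth data for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
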