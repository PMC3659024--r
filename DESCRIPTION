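Package: dualped
Title: Double-Pedigree Animal Models for Genetic and Cultural Inheritance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions the inherited component of behavioral phenotypic
    variance into additive genetic and cultural components with an extended
    ("double pedigree") animal model.  Builds the additive genetic
    relationship matrix A from a genealogical pedigree by the tabular method,
    and a cultural relationship matrix C from a cultural (rearing) pedigree,
    from culture identity, or from weighted social-contact records.  Fits
    variance components by restricted maximum likelihood over arbitrary
    dense covariance structures, reports genetic and cultural heritabilities,
    boundary-corrected likelihood-ratio tests and AIC model comparisons.
    Includes a simulator of partial cross-fostering designs (factorial
    cultures x environments x families) that make the two inherited
    components statistically separable, and Monte Carlo diagnostics of
    identifiability, power and misattribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
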