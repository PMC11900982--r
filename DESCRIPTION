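Package: cotracer
Title: Differential Metabolomics and 13C Isotope Tracing for Co-Culture
    Crosstalk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for interrogating metabolic crosstalk in
    mixed-cell (tumor-hepatocyte) co-cultures. Provides differential
    metabolite-pool analysis with an analytical 1:1 dilution control,
    construction and natural-abundance correction of 13C mass isotopologue
    distributions for isotope tracing untargeted metabolomics (ITUM),
    discriminant ITUM (standardized PCA over isotopologue enrichment
    variables, PC1-loading selection, co-enrichment correlation networks
    and clustering), fuel-utilization quantification from NMR integrals
    (net rates, lactate:glucose ratio, ketone bodies, adenylate energy
    charge), and gene-metabolite correlation-network integration. A
    synthetic co-culture generator with planted ground truth emulates the
    statistical structure of every input for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
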