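Package: mmnet
Title: Multi-Weight Multimorbidity Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares multimorbidity networks from binary
    condition data under five pairwise measures of association: odds
    ratio, lift, phi correlation, Salton cosine index, and joint
    frequencies normalised by iterative proportional fitting. Pairs
    above the 90th percentile of each weight distribution form a
    weighted network; communities are detected by modularity-based
    Leiden clustering and weighted degree, closeness and betweenness
    centralities are computed. Cross-measure concordance is summarised
    with overlap counts, prevalence-stratified contributions and
    Cohen's kappa. Includes a Gaussian-copula generator of synthetic
    cohorts with specified condition prevalences and a planted block
    association structure, and bundled reference tables (27 chronic
    conditions and 56 strongly associated pairs) from a national
    death-certificate multimorbidity study of women aged 85 and over.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tools,
    MASS
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    jsonlite,
    withr,
    xml2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
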