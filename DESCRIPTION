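Package: traitSAM
Title: Trait-Specific Expression Profiling with Quantitative-Response SAM
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Permutation-based significance analysis of microarrays (SAM)
    with a quantitative response, for profiling probe-trait associations
    across diverse genotypes. Expression of every probe is regressed on a
    morpho-physiological trait weighted to [0,1] across genotypes; scores
    d = r/(s + s0) are compared against a permutation null to estimate
    false discovery rates and q-values, and probes are selected at combined
    FDR and score thresholds. Includes strict readers for the tabular
    interchange formats, a synthetic-data generator emulating an
    8-genotype x 2-condition x 3-replicate salt-stress study design with
    trait-linked spike-in probes, quantile normalization, hypergeometric
    GO singular enrichment analysis, chromosome assignment from rice
    RAP-DB locus identifiers, RAP-to-MSU identifier conversion, and
    interaction-subnetwork extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
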