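Package: tempsel
Title: Temporal Selection Analysis at a Candidate Locus with Neutral Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting temporal selection at a candidate gene
    against a background of neutral microsatellite loci in a
    before/after-intervention sampling design with an affected and a
    control population. Provides a two-deme Wright-Fisher forward
    simulator with epoch-switched viability selection and migration,
    Genepop and tabular input/output, Weir-Cockerham F-statistics with
    allele- and individual-permutation nulls, exact Fisher r x c and
    Mann-Whitney U tests by full enumeration, genotype-survival fitness
    ratios, per-million read-count normalization with between-site
    ratio-of-change, correlation-matrix PCA of water chemistry, and a
    seeded end-to-end pipeline that emits report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
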