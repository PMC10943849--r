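Package: pcbdechlor
Title: PCB Dechlorination Microcosm Analysis: Congener Accounting, qPCR
    Quantification and Community Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing microbial reductive dechlorination of
    polychlorinated biphenyls (PCBs) in anaerobic microcosms. Provides a
    structural model of the 209 PCB congeners in chlorophenyl-ring notation
    (enumeration, canonicalization, ortho/meta/para classification, flanking
    context, single-dechlorination products), dechlorination statistics over
    congener time series (chlorines per biphenyl, positional decomposition,
    activity calling against an abiotic-control threshold, lag time,
    para/meta preference classification, pathway-graph inference with
    non-negative flux attribution), qPCR standard-curve calibration and
    quantification of organohalide-respiring bacteria and reductive
    dehalogenase genes (ratio bands, dominance), community ecology on
    taxon-by-sample tables (OHRB screening, alpha diversity, Bray-Curtis,
    principal coordinates, prevalence-filtered Spearman co-occurrence
    networks with Benjamini-Hochberg control, a normalized stochasticity
    ratio null model), seeded synthetic-data generators for every input
    format, and an end-to-end pipeline with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    vegan,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
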