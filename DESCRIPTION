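Package: msihetero
Title: Metabolic Heterogeneity Analysis for Imaging Mass Spectrometry
Version: 0.1.0
Authors@R: person("VARIANZ", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantifying intratumoural metabolic heterogeneity from
    imaging mass spectrometry (MSI) datacubes. Pixels from a patient cohort are
    pooled and segmented into metabolic subpopulations by K-means clustering under
    correlation distance; per-patient heterogeneity is scored with Simpson's
    diversity index and split by a cutoff-optimised log-rank criterion;
    subpopulations are linked to survival through a cluster-presence-threshold by
    K grid of Cox proportional-hazards models selected by AIC, pairwise
    Andersen-Gill comparisons and response associations; discriminative metabolite
    channels are found by pixel-wise Mann-Whitney tests with Benjamini-Hochberg
    control and fold-change filtering, annotated via negative-mode adduct rules,
    tested for pathway over-representation and assembled into Spearman correlation
    networks. A synthetic-cohort generator with planted subpopulation, survival
    and response structure provides a ground-truth test surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    xml2,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
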