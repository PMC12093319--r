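Package: metaboclock
Title: Metabolomic Aging Clocks and Trajectory Analysis for Experimentally Evolved Fly Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing metabolomic aging in experimental-evolution
    designs with two selection regimes, two selection histories, replicate
    populations, and multiple sampling ages. Implements the normalization
    chain (completeness filter, log transform, within-sample centering,
    batch residualization), covariance-matrix PCA with mixed-model
    divergence tests, partial least-squares regime discrimination,
    within-regime elastic-net age clocks with leave-one-replicate-out
    prediction, between-regime clocks and the four-coefficient age
    acceleration model, per-metabolite linear mixed models with
    Benjamini-Hochberg control, group-mean clustering with the
    within-cluster sum-of-squares elbow rule, aged-phenotype cluster
    flagging, network-diffusion pathway enrichment with a permutation
    empirical p-value, and cohort mortality summaries. A synthetic-data
    generator emulating the study design makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    lme4,
    igraph,
    mixOmics,
    pROC,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
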