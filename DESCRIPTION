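Package: microstrat
Title: Stratification of Gut Microbiota Steady States, Diet Groups and
    Health Associations in Child Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for prospective child-cohort gut
    microbiome studies. Stratifies OTU-level community profiles into
    microbiota steady states by Ward clustering of Spearman correlations,
    derives genus co-abundance groups (CAGs) from Kendall correlation
    networks with q-value FDR control, computes alpha diversity (Shannon,
    observed features, Faith phylogenetic diversity) and weighted and
    unweighted UniFrac distances, performs principal coordinates analysis
    and correspondence analysis, fits environmental vectors and
    permutational MANOVA, clusters food-frequency questionnaires into
    dietary groups, computes the Healthy Food Diversity index and
    macronutrient summaries, runs age-adjusted median regressions of
    clinical markers on ordination axes, and tests diet-by-microbiota
    combinations for phenotype enrichment with Fisher's exact test. A
    synthetic cohort generator with known ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    stats,
    utils,
    tools,
    jsonlite,
    quantreg,
    yaml
Suggests:
    biomformat,
    mclust,
    optparse,
    phangorn,
    picante,
    phyloseq,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
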