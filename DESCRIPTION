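Package: onsetOmics
Title: Paired Tumor-Normal Transcriptome and Methylome Contrasts by Age of Onset
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mixed-model ANOVA machinery for paired tumor-normal omics
    designs with early- versus late-onset group contrasts: per-feature
    paired ANOVA with a random person effect and method-of-moments variance
    components, tissue-by-onset interaction models, gene-set level mixed
    ANOVA with signed fold changes and confidence intervals, chi-square
    enrichment scores, beta-value differential methylation calling with
    Benjamini-Hochberg FDR and a five-class interaction/Venn partition,
    clinical contingency analyses, and a synthetic-data generator that
    emulates the paired design so the whole pipeline can be run and
    validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: DifferentialExpression, DifferentialMethylation, GeneSetEnrichment,
    Epigenetics, Transcriptomics, StatisticalMethod
RoxygenNote: 7.3.3
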