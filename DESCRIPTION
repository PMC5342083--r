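Package: ageTrends
Title: Age-Trajectory Analysis of Cross-Sectional Expression Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting age-associated expression trends from
    cross-sectional transcriptome cohorts. Samples are weighted inversely to
    the number of cohort members within a moving age window, compensating for
    skewed age distributions; per-probe trajectories are smoothed with a
    weighted quadratic regression of log2 intensity on age; probes are filtered
    by a Benjamini-Hochberg false discovery rate and an absolute fold-change
    threshold; standardized trajectories are clustered by K-means under
    Euclidean or absolute-correlation distance; and the age-position (the age
    at which opposite-inclination trajectory groups conjoin) is located.
    Includes cohort comparison utilities (overlap with direction concordance,
    age-range matching, age splits) and a synthetic cohort generator with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: GeneExpression, Regression, Clustering, Transcriptomics, Aging
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'AgeExpressionSet.R'
    'ageTrends-package.R'
    'clustering.R'
    'compare.R'
    'io.R'
    'pipeline.R'
    'preprocess.R'
    'simulate.R'
    'trendfit.R'
    'utils.R'
    'weighting.R'
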