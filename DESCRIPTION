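Package: somaticHotspots
Title: Detection of Somatic Mutation Hotspots with Patient-Specific
    Background Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects somatic mutation hotspots in cancer whole-genome
    cohorts. A patient- and position-specific background mutation
    probability is estimated by logistic regression on sequence-context,
    epigenomic and structural covariates chosen by cross-validated
    LASSO stability selection over bootstrap subsamples. Each 21-bp
    window is then tested for an excess of mutated patients with an
    exact Poisson-binomial recurrence test, and p-values are corrected
    genome-wide (or over user-supplied regions) with the
    Benjamini-Hochberg procedure, counting every analyzable nucleotide
    as a hypothesis. Includes a fully synthetic data generator (genome,
    covariate tracks, cohort mutation catalogs with spiked hotspots)
    used for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    Matrix,
    glmnet,
    jsonlite,
    ggplot2,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
biocViews: SomaticMutation, WholeGenome, Regression, FeatureExtraction,
    StatisticalMethod, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'baselines.R'
    'design.R'
    'features.R'
    'io.R'
    'lasso.R'
    'model.R'
    'pipeline.R'
    'plots.R'
    'sampler.R'
    'scanner.R'
    'simulate.R'
    'somaticHotspots-package.R'
    'utils.R'
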