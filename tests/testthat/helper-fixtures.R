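# Fixture builders shared across test files. Everything is generated in
# code; files go to per-test temporary paths.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

## A genome from literal contig sequences.
makeGenome <- function(...) {
    seqs <- c(...)
    g <- Biostrings::DNAStringSet(unname(seqs))
    names(g) <- names(seqs)
    g
}

## Write a mutation TSV and read it back through the parser.
makeCatalog <- function(genome, df) {
    path <- tempfile(fileext = ".tsv")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    suppressMessages(readMutations(path, genome, verbose = FALSE))
}

writeBed <- function(df) {
    path <- tempfile(fileext = ".bed")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    path
}

## A ready-made small simulated cohort reused by several files.
smallSim <- function(seed = 7L, genomeLength = 60000L, nSamples = 12L,
                     baseRate = 2e-4, spikes = NULL, ...) {
    cfg <- simulationConfig(genomeLength = genomeLength,
                            nSamples = nSamples, baseRate = baseRate,
                            spikes = spikes, ...)
    g <- simulateGenome(cfg$genomeLength, cfg$nContigs, seed = seed)
    tr <- simulateTracks(g, cfg, seed = seed + 1L)
    sim <- simulateCatalog(g, tr, cfg, seed = seed + 2L)
    list(genome = g, tracks = tr, catalog = sim$catalog,
         truth = sim$truth, config = cfg, mask = buildMask(g))
}

## A bare background model with hand-set coefficients, for arithmetic
## checks of the prediction contract.
bareModel <- function(intercept = 0, offset = 0, coefficients = numeric(),
                      se = NULL, samples = c("S1", "S2"),
                      burden_z = c(0, 0), specs = NULL) {
    if (is.null(se)) se <- rep(1, length(coefficients))
    names(se) <- names(coefficients)
    if (is.null(specs))
        specs <- featureManifest(list(), context = "none",
                                 localRate = FALSE)
    new("BackgroundModel",
        coefficients = coefficients, se = se,
        zvalues = if (length(coefficients)) coefficients / se else numeric(),
        intercept = intercept, offset = offset, variantClass = "SNV",
        featureNames = as.character(setdiff(names(coefficients),
                                            "burden_z")),
        designInfo = list(specs = specs,
                          encoding = list(standardize = list()),
                          selected = setdiff(names(coefficients),
                                             "burden_z"),
                          sampleCovariateNames = "burden_z",
                          burdenCenter = 0),
        sampleCovariates = data.frame(sample = samples, burden = 0L,
                                      burden_z = burden_z),
        method = "glm")
}

## Exhaustive Poisson-binomial tail by enumerating all 2^N outcomes.
pbTailBruteForce <- function(q, k) {
    N <- length(q)
    if (k == 0) return(1)
    tot <- 0
    for (m in 0:(2^N - 1)) {
        bits <- as.integer(intToBits(m))[seq_len(N)]
        if (sum(bits) >= k)
            tot <- tot + prod(ifelse(bits == 1, q, 1 - q))
    }
    tot
}
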