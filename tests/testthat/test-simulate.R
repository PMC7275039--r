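test_that("the random genome respects length, contigs and GC content", {
    g <- simulateGenome(10000, nContigs = 2, gc = 0.4, seed = 1)
    expect_equal(sum(width(g)), 10000)
    expect_length(g, 2L)
    gc <- sum(letterFrequency(g, "GC")) / 10000
    expect_lt(abs(gc - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
    g2 <- simulateGenome(10000, nContigs = 2, gc = 0.4, seed = 1)
    expect_identical(as.character(g), as.character(g2))
    expect_error(simulateGenome(100), ">= 1000")
})

test_that("binary track coverage hits the configured fraction", {
    cfg <- simulationConfig(genomeLength = 1000000L,
        binaryTracks = list(b = list(coverage = 0.2, beta = 0)),
        continuousTracks = list())
    g <- simulateGenome(cfg$genomeLength, seed = 2)
    tr <- simulateTracks(g, cfg, seed = 3)
    covered <- sum(width(tr$b@intervals))
    expect_lt(abs(covered - 200000) / 200000, 0.05)
    # zero coverage gives an empty track; same seed reproduces intervals
    cfg0 <- simulationConfig(genomeLength = 1000000L,
        binaryTracks = list(b = list(coverage = 0, beta = 0)),
        continuousTracks = list())
    expect_equal(length(simulateTracks(g, cfg0, seed = 3)$b@intervals), 0L)
    tr2 <- simulateTracks(g, cfg, seed = 3)
    expect_identical(as.data.frame(tr$b@intervals),
                     as.data.frame(tr2$b@intervals))
})

test_that("catalog size matches the configured rate", {
    cfg <- simulationConfig(genomeLength = 100000L, nSamples = 10L,
        baseRate = 1e-4, burdenSD = 0,
        binaryTracks = list(), continuousTracks = list())
    g <- simulateGenome(cfg$genomeLength, seed = 4)
    counts <- vapply(1:10, function(s) {
        sim <- simulateCatalog(g, list(), cfg, seed = 100 + s)
        length(variants(sim$catalog))
    }, numeric(1))
    expected <- 1e-4 * 100000 * 10
    expect_lt(abs(mean(counts) - expected),
              4 * sqrt(expected) / sqrt(10))
})

test_that("spiked windows recruit the expected number of samples", {
    cfg <- simulationConfig(genomeLength = 50000L, nSamples = 30L,
        baseRate = 1e-6, binaryTracks = list(), continuousTracks = list(),
        spikes = data.frame(contig = "chr1", start = 25000, end = 25020,
                            successProb = 0.5))
    g <- simulateGenome(cfg$genomeLength, seed = 5)
    hits <- vapply(1:10, function(s) {
        sim <- simulateCatalog(g, list(), cfg, seed = 200 + s)
        v <- variants(sim$catalog)
        inWin <- start(v) >= 25000 & start(v) <= 25020
        length(unique(mcols(v)$sample[inWin]))
    }, numeric(1))
    expect_lt(abs(mean(hits) - 15), 4 * sqrt(30 * 0.25) / sqrt(10))
})

test_that("a binary-track effect shifts rates by exp(beta) in the rare
           regime", {
    cfg <- simulationConfig(genomeLength = 500000L, nSamples = 20L,
        baseRate = 1e-4, burdenSD = 0,
        binaryTracks = list(b = list(coverage = 0.3, beta = 1)),
        continuousTracks = list())
    g <- simulateGenome(cfg$genomeLength, seed = 6)
    tr <- simulateTracks(g, cfg, seed = 7)
    sim <- simulateCatalog(g, tr, cfg, seed = 8)
    v <- variants(sim$catalog)
    inTrack <- overlapsAny(v, tr$b@intervals)
    covered <- sum(width(tr$b@intervals))
    rateIn <- sum(inTrack) / (covered * 20)
    rateOut <- sum(!inTrack) / ((500000 - covered) * 20)
    expect_lt(abs(rateIn / rateOut - exp(1)), 0.5)
})

test_that("indel simulation exercises both variant classes", {
    cfg <- simulationConfig(genomeLength = 50000L, nSamples = 5L,
        baseRate = 1e-4, indelRate = 5e-5,
        binaryTracks = list(), continuousTracks = list())
    g <- simulateGenome(cfg$genomeLength, seed = 9)
    sim <- simulateCatalog(g, list(), cfg, seed = 10)
    cls <- mcols(variants(sim$catalog))$class
    expect_true(all(c("SNV", "indel") %in% cls))
    # indel records have a two-base reference span
    v <- variants(sim$catalog)
    expect_true(all(width(v[mcols(v)$class == "indel"]) == 2L))
})

test_that("fixtures written to disk re-read into the same catalog", {
    sim <- smallSim(seed = 71)
    dir <- tempfile("fx")
    paths <- writeFixtures(dir, sim$genome, sim$tracks, sim$catalog,
                           sim$truth)
    g2 <- readGenome(paths$genome)
    expect_identical(as.character(g2), as.character(sim$genome))
    cat2 <- suppressMessages(readMutations(paths$mutations, g2,
                                           verbose = FALSE))
    expect_equal(length(variants(cat2)), length(variants(sim$catalog)))
    tr <- readTrack(paths$peaks, "binary")
    expect_identical(as.data.frame(tr@intervals)[, 1:3],
                     as.data.frame(sim$tracks$peaks@intervals)[, 1:3])
    truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
    expect_equal(truth$intercept, qlogis(sim$config$baseRate))
})
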