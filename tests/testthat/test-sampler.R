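test_that("all mutated sites are used when below the cap, with balance", {
    sim <- smallSim(seed = 31)
    tab <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV", seed = 1)
    v <- variants(sim$catalog)
    pts <- GenomicRanges::resize(v[mcols(v)$class == "SNV"], 1, fix = "start")
    inMask <- sum(IRanges::overlapsAny(
        pts, somaticHotspots:::contextMask(sim$genome, sim$mask)))
    expect_equal(tab@nMutated, inMask)
    expect_equal(tab@nUnmutated, tab@nMutated)
    expect_equal(unname(samplingFractions(tab)[["f1"]]), 1)
    expect_lt(samplingFractions(tab)[["f0"]], 1)
})

test_that("the cap subsamples mutated sites and records f1", {
    sim <- smallSim(seed = 32)
    tab <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV",
                       maxMutated = 50L, seed = 2)
    expect_equal(tab@nMutated, 50L)
    expect_equal(tab@nUnmutated, 50L)
    total <- sum(mcols(variants(sim$catalog))$class == "SNV")
    expect_lte(samplingFractions(tab)[["f1"]], 50 / total + 1e-12)
})

test_that("sampling is deterministic under a fixed seed", {
    sim <- smallSim(seed = 33)
    t1 <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV", seed = 5)
    t2 <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV", seed = 5)
    expect_identical(as.data.frame(t1@sites), as.data.frame(t2@sites))
    t3 <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV", seed = 6)
    expect_false(identical(as.data.frame(t1@sites),
                           as.data.frame(t3@sites)))
})

test_that("label-0 rows never coincide with a catalog mutation", {
    sim <- smallSim(seed = 34)
    v <- variants(sim$catalog)
    mutKey <- paste(as.character(seqnames(v)), start(v), mcols(v)$sample)
    for (s in 1:5) {
        tab <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV",
                           seed = s)
        gr <- tab@sites[mcols(tab@sites)$label == 0]
        key <- paste(as.character(seqnames(gr)), start(gr),
                     mcols(gr)$sample)
        expect_length(intersect(key, mutKey), 0)
    }
})

test_that("degenerate inputs error out", {
    sim <- smallSim(seed = 35)
    # no indels in this cohort
    expect_error(sampleSites(sim$catalog, sim$mask, sim$genome, "indel"),
                 "no in-mask")
    # a mask smaller than the requested non-mutated draw
    tiny <- GRanges("chr1", IRanges(1000, 1040))
    expect_error(sampleSites(sim$catalog, tiny, sim$genome, "SNV"),
                 "mask too small|no in-mask")
})

test_that("non-mutated positions are uniform over the mask", {
    sim <- smallSim(seed = 36, genomeLength = 20000L)
    nBins <- 10L
    L <- sum(width(sim$genome))
    breaks <- seq(0, L, length.out = nBins + 1)
    pass <- 0L
    for (s in 1:20) {
        tab <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV",
                           seed = 100 + s)
        gr <- tab@sites[mcols(tab@sites)$label == 0]
        cnt <- table(cut(start(gr), breaks))
        p <- suppressWarnings(chisq.test(cnt)$p.value)
        if (p > 0.01) pass <- pass + 1L
    }
    expect_gte(pass, 18L)
})

test_that("design matrix rows align with site-table order", {
    sim <- smallSim(seed = 37)
    tracks <- c(sim$tracks,
                list(local_rate = computeLocalRate(sim$catalog, sim$genome)))
    specs <- featureManifest(tracks)
    tab <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV", seed = 3)
    d <- buildDesignMatrix(tab, sim$genome, tracks, specs)
    expect_equal(nrow(d$X), tab@nMutated + tab@nUnmutated)
    expect_identical(d$y, mcols(tab@sites)$label)

    # permuting rows permutes the design identically
    perm <- sample(length(tab@sites))
    tabP <- new("SiteTable", sites = tab@sites[perm],
                variantClass = "SNV", nMutated = tab@nMutated,
                nUnmutated = tab@nUnmutated,
                samplingFractions = samplingFractions(tab))
    dP <- buildDesignMatrix(tabP, sim$genome, tracks, specs,
                            info = d$info)
    expect_identical(as.matrix(dP$X), as.matrix(d$X)[perm, ])
})
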