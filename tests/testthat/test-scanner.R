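test_that("Poisson-binomial tail matches hand-enumerated examples", {
    # q = (.1,.2,.3), k=2: brute force over all 8 outcomes gives 0.098
    expect_equal(poissonBinomialTail(c(0.1, 0.2, 0.3), 2), 0.098,
                 tolerance = 1e-12)
    # homogeneous q reduces to the binomial survival function
    expect_equal(poissonBinomialTail(rep(0.01, 100), 3),
                 1 - pbinom(2, 100, 0.01), tolerance = 1e-12)
    expect_equal(poissonBinomialTail(c(0.4, 0.9, 0.2), 0), 1)
    expect_error(poissonBinomialTail(c(0.1, 0.2), 3), "exceeds")
})

test_that("the DP tail agrees with exhaustive enumeration", {
    set.seed(314)
    for (rep in 1:20) {
        N <- sample(2:8, 1)
        q <- runif(N, 0, 0.9)
        for (k in 0:N)
            expect_equal(poissonBinomialTail(q, k), pbTailBruteForce(q, k),
                         tolerance = 1e-12)
    }
})

test_that("tails are monotone in k and in each success probability", {
    set.seed(99)
    q <- runif(20, 0, 0.5)
    tails <- vapply(0:20, function(k) poissonBinomialTail(q, k), numeric(1))
    expect_true(all(diff(tails) < 0))
    for (i in c(1, 7, 20)) {
        q2 <- q; q2[i] <- q2[i] + 0.3
        expect_gt(poissonBinomialTail(q2, 5), poissonBinomialTail(q, 5))
    }
})

test_that("padded BH equals textbook BH on the explicit vector", {
    set.seed(272)
    for (rep in 1:30) {
        nEval <- sample(1:40, 1)
        mTot <- nEval + sample(0:5000, 1)
        p <- runif(nEval)^sample(1:4, 1)
        ours <- bhCorrect(p, mTot)
        full <- p.adjust(c(p, rep(1, mTot - nEval)), method = "BH")
        expect_equal(ours, full[seq_len(nEval)], tolerance = 1e-12)
    }
    # no padding: identical to standard BH
    p <- c(0.001, 0.02, 0.4)
    expect_equal(bhCorrect(p, 3), p.adjust(p, "BH"))
    # extreme padding clips at 1
    expect_equal(bhCorrect(1e-9, 2.5e9), 1)
    # the worked two-value case against the brute-force oracle
    expect_equal(bhCorrect(c(0.001, 0.002), 1000),
                 p.adjust(c(0.001, 0.002, rep(1, 998)), "BH")[1:2])
    expect_error(bhCorrect(runif(10), 5), "mTotal")
})

test_that("candidate enumeration follows the window geometry", {
    g <- makeGenome(c1 = paste(rep("ACGT", 500), collapse = ""))
    mask <- buildMask(g)
    # two samples at one position: all 21 centers qualify
    df <- data.frame(chrom = "c1", pos = c(1000, 1000), ref = "T",
                     alt = c("A", "C"), sample = c("S1", "S2"))
    df$ref <- substring(as.character(g[["c1"]]), df$pos, df$pos)
    cat <- makeCatalog(g, df)
    cands <- enumerateCandidates(cat, mask)
    expect_equal(length(cands), 21L)
    expect_equal(range(cands$center), c(990, 1010))
    expect_true(all(cands$nSamples == 2L))

    # 30 bp apart: no 21-bp window contains both
    df2 <- data.frame(chrom = "c1", pos = c(1000, 1030), ref = "x",
                      alt = "A", sample = c("S1", "S2"))
    df2$ref <- substring(as.character(g[["c1"]]), df2$pos, df2$pos)
    df2$alt <- ifelse(df2$ref == "A", "G", "A")
    expect_equal(length(enumerateCandidates(makeCatalog(g, df2), mask)), 0L)

    # one sample mutated twice is not recurrence across samples
    df3 <- data.frame(chrom = "c1", pos = c(1000, 1005), ref = "x",
                      alt = "A", sample = "S1")
    df3$ref <- substring(as.character(g[["c1"]]), df3$pos, df3$pos)
    df3$alt <- ifelse(df3$ref == "A", "G", "A")
    expect_equal(length(enumerateCandidates(makeCatalog(g, df3), mask)), 0L)

    expect_error(enumerateCandidates(cat, mask, l = 20), "odd")
    expect_error(enumerateCandidates(cat, mask, n = 0), ">= 1")

    # raising n shrinks the candidate set monotonically
    c2 <- enumerateCandidates(cat, mask, n = 2)
    c3 <- enumerateCandidates(cat, mask, n = 3)
    expect_true(all(c3$center %in% c2$center))
})

test_that("window success probabilities follow the product form", {
    g <- simulateGenome(5000, seed = 3)
    mask <- buildMask(g)
    pConst <- 1e-4
    m <- bareModel(intercept = qlogis(pConst), samples = c("S1", "S2"))
    field <- probabilityField(m, g, list(), mask)
    win <- GRanges("chr1", IRanges(1000, 1020))
    q <- windowSuccessProbs(field, win)
    expect_equal(unname(q), rep(1 - (1 - pConst)^21, 2), tolerance = 1e-9)

    # masked-out positions are skipped from the product
    mask2 <- setdiff(mask, GRanges("chr1", IRanges(1010, 1020)))
    field2 <- probabilityField(m, g, list(), mask2)
    q2 <- windowSuccessProbs(field2, win)
    expect_equal(unname(q2)[1], 1 - (1 - pConst)^10, tolerance = 1e-9)
})

test_that("genome and region mode agree on p-values, differ on q-values", {
    sim <- smallSim(seed = 61, spikes = data.frame(
        contig = "chr1", start = c(10000, 40000), end = c(10020, 40020),
        successProb = 0.6))
    tracks <- c(sim$tracks,
                list(local_rate = computeLocalRate(sim$catalog, sim$genome)))
    specs <- featureManifest(tracks, context = "none")
    tab <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV", seed = 4)
    m <- fitBackgroundModel(tab, sim$catalog, sim$genome, tracks, specs)
    gRes <- callHotspots(m, sim$catalog, sim$genome, tracks, sim$mask)
    roi <- GRanges("chr1", IRanges(5000, 15000))
    rRes <- callHotspots(m, sim$catalog, sim$genome, tracks, sim$mask,
                         mode = "region", regions = roi)
    gw <- scannedWindows(gRes); rw <- scannedWindows(rRes)
    shared <- findOverlaps(rw, gw, type = "equal")
    expect_gt(length(shared), 0)
    expect_equal(rw$pvalue[queryHits(shared)],
                 gw$pvalue[subjectHits(shared)], tolerance = 1e-12)
    expect_equal(rRes@mTotal, 10001)
    # same p, smaller hypothesis count => q-values scale down
    expect_true(all(rw$fdr[queryHits(shared)] <=
                    gw$fdr[subjectHits(shared)] + 1e-12))
    expect_error(callHotspots(m, sim$catalog, sim$genome, tracks,
                              sim$mask, mode = "region"), "region")
})

test_that("baseline models reduce correctly and share the scan machinery", {
    g <- simulateGenome(100000, seed = 8)
    mask <- buildMask(g)
    # equal burden: per-sample and shared-rate baselines coincide
    s <- as.character(g[["chr1"]])
    pos <- seq(5000, 52000, by = 1000)
    df <- data.frame(chrom = "chr1",
                     pos = rep(pos, 2),
                     ref = substring(s, rep(pos, 2), rep(pos, 2)),
                     alt = "x",
                     sample = rep(c("S1", "S2"), each = length(pos)))
    df$alt <- ifelse(df$ref == "A", "G", "A")
    # make two samples share three clustered positions
    clus <- data.frame(chrom = "chr1", pos = c(70001, 70006),
                       ref = substring(s, c(70001, 70006),
                                       c(70001, 70006)),
                       alt = "x", sample = c("S1", "S2"))
    clus$alt <- ifelse(clus$ref == "A", "G", "A")
    cat <- makeCatalog(g, rbind(df, clus))
    b1 <- baselineModels(cat, g, mask, "binomial_avg")
    b2 <- baselineModels(cat, g, mask, "poibin_sample")
    expect_equal(scannedWindows(b1)$pvalue, scannedWindows(b2)$pvalue,
                 tolerance = 1e-10)
    # shared-rate q is the closed-form binomial window probability
    r <- length(variants(cat)) / (sum(width(mask)) * 2)
    w1 <- scannedWindows(b1)
    full <- width(w1) == 21L
    expect_equal(unname(w1$meanProb[full][1]), 1 - (1 - r)^21,
                 tolerance = 1e-9)
    expect_error(baselineModels(cat, g, mask, "poibin_rt"),
                 "replication-timing")
})

test_that("more informed baselines call no more hotspots than naive ones", {
    # rate strongly modulated by a replication-timing-like profile
    calls <- matrix(0L, nrow = 2, ncol = 2)
    for (s in 1:2) {
        cfg <- simulationConfig(genomeLength = 200000L, nSamples = 20L,
            baseRate = 1e-4, burdenSD = 0.2,
            binaryTracks = list(),
            continuousTracks = list(rt = list(period = 50000,
                amplitude = 1.5, noiseSD = 0.05, beta = 1)))
        g <- simulateGenome(cfg$genomeLength, seed = 500 + s)
        tr <- simulateTracks(g, cfg, seed = 600 + s)
        sim <- simulateCatalog(g, tr, cfg, seed = 700 + s)
        mask <- buildMask(g)
        b1 <- baselineModels(sim$catalog, g, mask, "binomial_avg")
        b4 <- baselineModels(sim$catalog, g, mask, "poibin_rt_local",
                             rtTrack = tr$rt)
        calls[s, ] <- c(length(hotspots(b1)), length(hotspots(b4)))
    }
    expect_gte(sum(calls[, 1]), sum(calls[, 2]))
})
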