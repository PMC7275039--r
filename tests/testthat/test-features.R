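test_that("mask arithmetic: exclusions and N runs partition the genome", {
    g <- makeGenome(c1 = paste(rep("A", 100), collapse = ""))
    excl <- GRanges("c1", IRanges(1, 40))
    m <- buildMask(g, mappability = excl)
    expect_equal(sum(width(m)), 60)

    # no masks, no Ns: the full genome
    m2 <- buildMask(g)
    expect_equal(sum(width(m2)), 100)

    gN <- makeGenome(c1 = "AANNAA")
    expect_equal(sum(width(buildMask(gN))), 4)

    # per-contig partition |analyzable| + |excluded union N| = length
    g3 <- makeGenome(c1 = "ACGTNNACGTACGTNNACGT",
                     c2 = "AAAACCCCGGGGTTTTAAAA")
    excl3 <- GRanges(c("c1", "c2"), IRanges(c(1, 5), c(6, 12)))
    m3 <- buildMask(g3, blacklist = excl3)
    covered <- reduce(c(excl3, GRanges(c("c1", "c1"),
                                       IRanges(c(5, 15), c(6, 16)))))
    for (ct in c("c1", "c2")) {
        a <- sum(width(m3[seqnames(m3) == ct]))
        e <- sum(width(covered[seqnames(covered) == ct]))
        expect_equal(a + e, 20)
    }

    # unknown contig in a mask is ignored with a warning
    expect_warning(buildMask(g, mappability = GRanges("cX", IRanges(1, 5))),
                   "absent")
})

test_that("sequence context collapses to the pyrimidine strand", {
    g <- makeGenome(c1 = "AACGTAA")
    ctx <- sequenceContextAt(g, "c1", 4)   # center G -> collapse
    expect_true(ctx$available)
    expect_identical(ctx$centerClass, "CG")
    expect_identical(ctx$penta, "TACGT")
    expect_identical(ctx$tri, "ACG")
    expect_identical(ctx$left1, "A")       # left of collapsed 5-mer
    expect_identical(ctx$right2, "GT")

    # A-centered with T flanks stays on the A/T class
    g2 <- makeGenome(c1 = "TTATT")
    ctx2 <- sequenceContextAt(g2, "c1", 3)
    expect_identical(ctx2$centerClass, "AT")
    # trinucleotide is the center slice of the pentanucleotide
    expect_identical(ctx2$tri, substr(ctx2$penta, 2, 4))

    # truncated flank and N in window are unavailable
    expect_false(sequenceContextAt(g, "c1", 1)$available)
    gn <- makeGenome(c1 = "AANTAAG")
    expect_false(sequenceContextAt(gn, "c1", 4)$available)
})

test_that("strand collapse is an involution under reverse complement", {
    set.seed(42)
    g <- simulateGenome(2000, seed = 9)
    rc <- DNAStringSet(reverseComplement(g[[1]]))
    names(rc) <- names(g)
    L <- width(g)[1]
    pos <- sample(3:(L - 2), 200)
    a <- sequenceContextAt(g, "chr1", pos)
    b <- sequenceContextAt(rc, "chr1", L - pos + 1)
    expect_identical(a$penta, b$penta)
    expect_identical(a$tri, b$tri)
    expect_identical(a$centerClass, b$centerClass)
    expect_identical(a$left2, b$left2)
})

test_that("homopolymer indel feature requires runs longer than 5", {
    g <- makeGenome(c1 = "GGCAAAAAACGGGGGCCCCCCCTT")
    #                     123456789012345678901234
    expect_equal(indelHomopolymerFeature(g, "c1", 6), 1L)   # 6xA run
    expect_equal(indelHomopolymerFeature(g, "c1", 12), 0L)  # 5xG only
    expect_equal(indelHomopolymerFeature(g, "c1", 18), 1L)  # 7xC run
    # a span overlapping a long run counts
    expect_equal(indelHomopolymerFeature(g, "c1", 2, 4), 1L)
    expect_equal(indelHomopolymerFeature(g, "c1", 1, 2), 0L)
})

test_that("local mutation rate matches direct counts and truncation", {
    g <- makeGenome(c1 = paste(rep("ACGT", 37500), collapse = ""))  # 150 kb
    df <- data.frame(chrom = "c1",
                     pos = c(11, 23, 35, 47, 59, 120001),
                     ref = "G", alt = "T",
                     sample = c("S1", "S1", "S1", "S2", "S2", "S1"))
    df$ref <- substring(as.character(g[["c1"]]), df$pos, df$pos)
    cat <- makeCatalog(g, df)
    lr <- computeLocalRate(cat, g, binWidth = 100000L)
    iv <- lr@intervals
    expect_equal(width(iv), c(100000L, 50000L))
    expect_equal(mcols(iv)$score[1], 5 / (100000 * 2))
    expect_equal(mcols(iv)$score[2], 1 / (50000 * 2))
    # conservation: sum(rate x width x nSamples) = class count
    expect_equal(sum(mcols(iv)$score * width(iv) * 2), 6)
    # empty bins are zero
    df2 <- df[df$pos < 100, , drop = FALSE]
    lr2 <- computeLocalRate(makeCatalog(g, df2), g, binWidth = 100000L)
    expect_equal(mcols(lr2@intervals)$score[2], 0)
})

test_that("sample burden counts per class with zeros for absent classes", {
    g <- makeGenome(c1 = "ACGTACGTACGTACGTACGT")
    df <- data.frame(chrom = "c1", pos = c(3, 7, 11, 5),
                     ref = c("G", "G", "G", "AC"),
                     alt = c("T", "A", "C", "A"),
                     sample = c("S1", "S1", "S1", "S2"))
    cat <- makeCatalog(g, df)
    b <- sampleBurden(cat, "SNV")
    expect_equal(b[["S1"]], 3L)
    expect_equal(b[["S2"]], 0L)        # S2 has only an indel
    expect_equal(sampleBurden(cat, "indel")[["S2"]], 1L)
})

test_that("design rows are deterministic and equivariant to spec order", {
    sim <- smallSim(seed = 21)
    tracks <- c(sim$tracks,
                list(local_rate = computeLocalRate(sim$catalog, sim$genome)))
    specs <- featureManifest(tracks, context = "standard")
    pos <- c(101, 5021, 30011)
    d1 <- assembleDesign(sim$genome, tracks, specs, "chr1", pos)
    d2 <- assembleDesign(sim$genome, tracks, specs, "chr1", pos)
    expect_identical(as.matrix(d1$X), as.matrix(d2$X))

    specsR <- specs[rev(seq_len(nrow(specs))), , drop = FALSE]
    d3 <- assembleDesign(sim$genome, tracks, specsR, "chr1", pos)
    common <- intersect(colnames(d1$X), colnames(d3$X))
    expect_identical(as.matrix(d1$X[, common]), as.matrix(d3$X[, common]))

    # binary overlay encodes membership at the queried position
    tr <- sim$tracks$peaks
    inside <- start(tr@intervals)[1] + 2L
    ct <- as.character(seqnames(tr@intervals))[1]
    d4 <- assembleDesign(sim$genome, tracks, specs, ct, inside)
    expect_equal(unname(as.matrix(d4$X)[, "peaks"]), 1)
})
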