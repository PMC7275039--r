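test_that("case-control fit recovers the truth after offset correction", {
    # population Bernoulli draws from a known logistic model, balanced
    # case-control subsample, fit + offset correction
    recov <- vapply(1:5, function(s) {
        set.seed(400 + s)
        N <- 400000L
        x <- rbinom(N, 1, 0.3)
        p <- plogis(-4 + 1.5 * x)
        y <- rbinom(N, 1, p)
        cases <- which(y == 1)
        ctrls <- sample(which(y == 0), length(cases))
        idx <- c(cases, ctrls)
        f1 <- 1
        f0 <- length(ctrls) / (N - length(cases))
        X <- matrix(x[idx], ncol = 1, dimnames = list(NULL, "x"))
        m <- fitBackground(X, y[idx],
                           samplingFractions = c(f1 = f1, f0 = f0))
        c(beta = unname(m@coefficients[["x"]]),
          int = m@intercept - m@offset)
    }, numeric(2))
    expect_lt(max(abs(recov["beta", ] - 1.5)), 0.1)
    expect_lt(max(abs(recov["int", ] - (-4))), 0.1)
})

test_that("with no features the corrected intercept is the population
           log-odds", {
    set.seed(99)
    N <- 200000L
    y <- rbinom(N, 1, 0.001)
    cases <- which(y == 1)
    ctrls <- sample(which(y == 0), length(cases))
    idx <- c(cases, ctrls)
    f0 <- length(ctrls) / (N - length(cases))
    m <- fitBackground(matrix(numeric(0), nrow = length(idx), ncol = 0),
                       y[idx], samplingFractions = c(f1 = 1, f0 = f0))
    # balanced sample: fitted intercept ~ 0; correction restores the prior
    expect_lt(abs(m@intercept), 0.05)
    expect_lt(abs((m@intercept - m@offset) - qlogis(mean(y))), 0.15)
})

test_that("doubling the control draw changes the intercept, not the
           corrected predictions", {
    set.seed(123)
    N <- 300000L
    x <- rbinom(N, 1, 0.3)
    y <- rbinom(N, 1, plogis(-3.5 + x))
    cases <- which(y == 1)
    ctl1 <- sample(which(y == 0), length(cases))
    ctl2 <- sample(which(y == 0), 2L * length(cases))
    fit <- function(ctrls) {
        idx <- c(cases, ctrls)
        fitBackground(matrix(x[idx], ncol = 1,
                             dimnames = list(NULL, "x")), y[idx],
                      samplingFractions = c(
                          f1 = 1, f0 = length(ctrls) / (N - length(cases))))
    }
    m1 <- fit(ctl1); m2 <- fit(ctl2)
    expect_gt(abs(m1@intercept - m2@intercept), 0.3)
    corrected1 <- (m1@intercept - m1@offset) + m1@coefficients[["x"]]
    corrected2 <- (m2@intercept - m2@offset) + m2@coefficients[["x"]]
    expect_lt(abs(corrected1 - corrected2), 0.1)
})

test_that("constant columns are dropped with an informative warning", {
    set.seed(5)
    X <- cbind(good = rbinom(500, 1, 0.4), dead = rep(0, 500))
    y <- rbinom(500, 1, 0.5)
    expect_warning(m <- fitBackground(X, y), "dead")
    expect_false("dead" %in% names(m@coefficients))
    expect_true("good" %in% names(m@coefficients))
})

test_that("prediction arithmetic follows the logistic contract", {
    g <- makeGenome(chr1 = paste(rep("ACGT", 250), collapse = ""))
    m0 <- bareModel(intercept = 0, offset = 0)
    p <- predictProbability(m0, "S1", "chr1", 100, g, list())
    expect_equal(p, 0.5)

    m1 <- bareModel(intercept = -log(999))
    expect_equal(predictProbability(m1, "S1", "chr1", 100, g, list()),
                 0.001, tolerance = 1e-12)

    # burden coefficient shifts log-odds linearly between samples
    m2 <- bareModel(intercept = -6,
                    coefficients = c(burden_z = 0.8),
                    burden_z = c(0.5, -0.25))
    p1 <- predictProbability(m2, "S1", "chr1", 100, g, list())
    p2 <- predictProbability(m2, "S2", "chr1", 100, g, list())
    expect_equal(qlogis(p1) - qlogis(p2), 0.8 * 0.75, tolerance = 1e-10)

    expect_error(predictProbability(m0, "nope", "chr1", 100, g, list()),
                 "unknown sample")
    mask <- GRanges("chr1", IRanges(1, 50))
    expect_error(predictProbability(m0, "S1", "chr1", 100, g, list(),
                                    mask = mask), "outside")
})

test_that("Z-value table is sorted by |Z| with aliased columns absent", {
    m <- bareModel(coefficients = c(a = 0.5, b = -1.0, c = 0.32),
                   se = c(a = 0.1, b = 0.3125, c = 0.1))
    zt <- zvalueTable(m)
    expect_equal(zt$zvalue[1], 5.0)
    expect_identical(zt$feature, c("a", "b", "c"))
    expect_equal(abs(zt$zvalue), sort(abs(zt$zvalue), decreasing = TRUE))
})

test_that("model JSON serialization round-trips predictions", {
    sim <- smallSim(seed = 51)
    tracks <- c(sim$tracks,
                list(local_rate = computeLocalRate(sim$catalog, sim$genome)))
    specs <- featureManifest(tracks)
    tab <- sampleSites(sim$catalog, sim$mask, sim$genome, "SNV", seed = 2)
    m <- suppressWarnings(
        fitBackgroundModel(tab, sim$catalog, sim$genome, tracks, specs))
    path <- tempfile(fileext = ".json")
    writeBackgroundModel(m, path)
    m2 <- readBackgroundModel(path)
    pos <- seq(1001, 1101, by = 10)
    s <- sampleIDs(sim$catalog)[1]
    expect_equal(
        predictProbability(m, s, "chr1", pos, sim$genome, tracks),
        predictProbability(m2, s, "chr1", pos, sim$genome, tracks),
        tolerance = 1e-12)
    expect_equal(modelPseudoR2(m2), modelPseudoR2(m), tolerance = 1e-12)
})
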