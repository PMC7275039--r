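test_that("the 1-SE rule silences pure-noise features", {
    n <- 4000L; p <- 10L
    allzero <- 0L
    for (s in 1:20) {
        set.seed(1000 + s)
        X <- Matrix::Matrix(matrix(rbinom(n * p, 1, 0.3), n, p),
                            sparse = TRUE)
        y <- rbinom(n, 1, 0.5)
        res <- cvLassoPath(X, y, seed = s, nlambda = 50,
                           returnFit = TRUE)
        if (length(res$support) == 0L) allzero <- allzero + 1L
    }
    expect_gte(allzero, 19L)
})

test_that("a strong effect survives the 1-SE rule", {
    set.seed(2024)
    n <- 10000L
    X <- cbind(rbinom(n, 1, 0.3),
               matrix(rbinom(n * 9, 1, 0.3), n, 9))
    colnames(X) <- paste0("f", 1:10)
    y <- rbinom(n, 1, plogis(-0.5 + 2 * X[, 1]))
    res <- cvLassoPath(Matrix::Matrix(X, sparse = TRUE), y, seed = 3,
                       returnFit = TRUE)
    expect_true(1L %in% res$support)
})

test_that("duplicated columns do not break the cross-validated path", {
    set.seed(11)
    n <- 2000L
    X <- matrix(rbinom(n * 5, 1, 0.3), n, 5)
    X <- cbind(X, X[, 1])
    y <- rbinom(n, 1, plogis(-0.5 + 1.5 * X[, 1]))
    lam <- cvLassoPath(Matrix::Matrix(X, sparse = TRUE), y, seed = 4)
    expect_true(is.finite(lam) && lam > 0)
    expect_error(cvLassoPath(X, rep(1, n)), "single class")
})

test_that("stability selection recovers planted support on synthetic data", {
    set.seed(77)
    n <- 4000L; p <- 8L
    X <- matrix(rbinom(n * p, 1, 0.3), n, p)
    colnames(X) <- paste0("f", 1:p)
    y <- rbinom(n, 1, plogis(-0.8 + 1.2 * X[, 1] - 1.0 * X[, 2]))
    groups <- colnames(X)
    categories <- setNames(rep("epigenetic", p), groups)
    sel <- suppressWarnings(stabilitySelect(
        Matrix::Matrix(X, sparse = TRUE), y, groups, categories,
        nBoot = 20L, nlambda = 50L, seed = 5))
    expect_setequal(selectedFeatures(sel), c("f1", "f2"))
    freq <- featureFrequency(sel)
    # frequencies are multiples of 1/nBoot in [0, 1]
    expect_true(all(abs(freq * 20 - round(freq * 20)) < 1e-12))
    expect_gte(freq[["f1"]], 0.9)
})

test_that("recurrence thresholds are strict and monotone", {
    freq <- c(seqA = 0.90, seqB = 0.91, epiA = 0.75, epiB = 0.76)
    categories <- c(seqA = "sequence", seqB = "sequence",
                    epiA = "epigenetic", epiB = "epigenetic")
    sel <- applyThresholds(freq, categories)
    # frequency exactly at the threshold is NOT selected ("more than")
    expect_setequal(sel, c("seqB", "epiB"))

    # raising a threshold never enlarges the selected set
    for (thr in seq(0.5, 1, by = 0.1)) {
        s1 <- applyThresholds(freq, categories,
                              c(sequence = thr, default = thr))
        s2 <- applyThresholds(freq, categories,
                              c(sequence = thr + 0.05,
                                default = thr + 0.05))
        expect_true(all(s2 %in% s1))
    }
})

test_that("McFadden pseudo-R2 follows its definition", {
    expect_equal(mcfaddenR2(-100, -100), 0)
    n <- 500
    expect_equal(mcfaddenR2(0.8 * n * log(0.5), n * log(0.5)), 0.2)
    expect_error(mcfaddenR2(-1, 0), "degenerate")
})

test_that("model fit stabilizes as the sampled-site count grows", {
    gen <- function(n, seed) {
        set.seed(seed)
        x <- rbinom(n, 1, 0.3)
        y <- rbinom(n, 1, plogis(-1 + 1.5 * x))
        m <- glm(y ~ x, family = binomial())
        mcfaddenR2(as.numeric(logLik(m)),
                   as.numeric(logLik(glm(y ~ 1, family = binomial()))))
    }
    r2 <- vapply(1:3, function(s) {
        c(gen(500, 10 + s), gen(4000, 20 + s), gen(32000, 30 + s))
    }, numeric(3))
    gapSmall <- mean(abs(r2[2, ] - r2[1, ]))
    gapLarge <- mean(abs(r2[3, ] - r2[2, ]))
    # increments shrink as n grows: the fit saturates
    expect_lt(gapLarge, gapSmall + 0.02)
    expect_lt(gapLarge, 0.03)
})
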