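# Cross-validated LASSO logistic regression and bootstrap stability
# selection of background-model features.

## One penalized logistic path fit (glmnet does the heavy lifting; features
## are standardized upstream, so standardize = FALSE here).
.lasso_path <- function(X, y, lambda = NULL, nlambda = 100L,
                        lambdaMinRatio = 1e-4) {
    glmnet::glmnet(X, y, family = "binomial", lambda = lambda,
                   nlambda = nlambda, lambda.min.ratio = lambdaMinRatio,
                   standardize = FALSE, thresh = 1e-5)
}

#' Choose the LASSO penalty by 10-fold cross-validation and the 1-SE rule
#'
#' Fits the penalized logistic path on a log-spaced grid descending four
#' decades from the data-derived maximal penalty, estimates mean binomial
#' deviance by stratified k-fold cross-validation, and returns the largest
#' penalty whose mean CV deviance is within one standard error of the
#' minimum.
#'
#' @param X numeric (sparse) design matrix.
#' @param y 0/1 response; both classes must be present.
#' @param nfolds number of CV folds (stratified by label).
#' @param nlambda grid size.
#' @param lambdaMinRatio smallest/largest penalty ratio (1e-4 = 4 decades).
#' @param seed RNG seed for the fold assignment.
#' @param returnFit also return the full-data path fit and the support at
#'   the chosen penalty.
#' @return the chosen penalty (numeric scalar); with \code{returnFit = TRUE}
#'   a list \code{(lambda, fit, support)} where \code{support} indexes the
#'   nonzero coefficients at the chosen penalty.
#' @importFrom stats plogis sd
#' @export
cvLassoPath <- function(X, y, nfolds = 10L, nlambda = 100L,
                        lambdaMinRatio = 1e-4, seed = NULL,
                        returnFit = FALSE) {
    y <- as.numeric(y)
    if (length(unique(y)) < 2L)
        .stop_data("response has a single class; cannot cross-validate")
    full <- .lasso_path(X, y, nlambda = nlambda,
                        lambdaMinRatio = lambdaMinRatio)
    lam <- full$lambda
    fold <- withSeed(seed, {
        f <- integer(length(y))
        f[y == 1] <- sample(rep_len(seq_len(nfolds), sum(y == 1)))
        f[y == 0] <- sample(rep_len(seq_len(nfolds), sum(y == 0)))
        f
    })
    dev <- matrix(NA_real_, nfolds, length(lam))
    for (k in seq_len(nfolds)) {
        hold <- fold == k
        fk <- .lasso_path(X[!hold, , drop = FALSE], y[!hold], lambda = lam)
        eta <- as.matrix(X[hold, , drop = FALSE] %*% fk$beta)
        eta <- sweep(eta, 2L, fk$a0, "+")
        p <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
        yy <- y[hold]
        used <- seq_len(ncol(eta))
        dev[k, used] <- -2 * colMeans(yy * log(p) + (1 - yy) * log(1 - p))
    }
    ok <- colSums(is.na(dev)) == 0L
    lam <- lam[ok]; dev <- dev[, ok, drop = FALSE]
    cvm <- colMeans(dev)
    cvsd <- apply(dev, 2L, stats::sd) / sqrt(nfolds)
    imin <- which.min(cvm)
    i1se <- min(which(cvm <= cvm[imin] + cvsd[imin]))
    lambda <- lam[i1se]
    if (!returnFit) return(lambda)
    beta <- full$beta[, match(TRUE, abs(full$lambda - lambda) < 1e-12)]
    list(lambda = lambda, fit = full, support = which(beta != 0))
}

#' Bootstrap stability selection of background-model features
#'
#' Repeats cross-validated LASSO on \code{nBoot} half-subsamples (drawn
#' without replacement) and records, for every candidate feature, the
#' fraction of bootstraps in which any of its design columns had a nonzero
#' coefficient at the 1-SE penalty. A feature is selected when its frequency
#' strictly exceeds the recurrence threshold of its category: 0.90 for
#' sequence-context features, 0.75 for everything else (epigenetic,
#' structural, overlays). Sample-level covariates do not take part; they are
#' always included in the final model.
#'
#' @param X sparse design matrix of position-level features.
#' @param y 0/1 labels aligned with \code{X}.
#' @param groups column -> feature name map (from
#'   \code{\link{buildDesignMatrix}}).
#' @param categories named character, feature name -> category.
#' @param nBoot number of bootstraps (default 100).
#' @param fraction subsample fraction (default 0.5).
#' @param thresholds named numeric \code{c(sequence = 0.90, default = 0.75)};
#'   user-adjustable to control model size.
#' @param nfolds,nlambda,lambdaMinRatio passed to \code{\link{cvLassoPath}}.
#' @param seed master seed; per-bootstrap seeds are derived from it.
#' @param verbose progress logging.
#' @return a \linkS4class{SelectionResult}.
#' @export
stabilitySelect <- function(X, y, groups, categories, nBoot = 100L,
                            fraction = 0.5,
                            thresholds = c(sequence = 0.90, default = 0.75),
                            nfolds = 10L, nlambda = 100L,
                            lambdaMinRatio = 1e-4, seed = NULL,
                            verbose = FALSE) {
    feats <- unique(groups)
    if (length(feats) == 0L) .stop_data("empty candidate feature set")
    if (!all(feats %in% names(categories)))
        .stop_config("missing category for feature(s): ",
                     paste(setdiff(feats, names(categories)), collapse = ", "))
    n <- nrow(X)
    if (n < 200000L)
        warning("fewer than 200,000 training rows (", n, "); feature ",
                "selection may not have saturated", call. = FALSE)
    seeds <- deriveSeeds(seed %||% sample.int(.Machine$integer.max, 1L),
                         2L * nBoot)
    hits <- stats::setNames(numeric(length(feats)), feats)
    lambdas <- numeric(nBoot)
    m <- floor(fraction * n)
    for (b in seq_len(nBoot)) {
        rows <- withSeed(seeds[b], sample.int(n, m))
        res <- cvLassoPath(X[rows, , drop = FALSE], y[rows],
                           nfolds = nfolds, nlambda = nlambda,
                           lambdaMinRatio = lambdaMinRatio,
                           seed = seeds[nBoot + b], returnFit = TRUE)
        lambdas[b] <- res$lambda
        sel <- unique(groups[res$support])
        hits[sel] <- hits[sel] + 1
        if (verbose && b %% 10L == 0L)
            .log_msg("stability selection: bootstrap ", b, "/", nBoot)
    }
    freq <- hits / nBoot
    cat_of <- categories[feats]
    thr <- ifelse(cat_of == "sequence",
                  thresholds[["sequence"]], thresholds[["default"]])
    selected <- feats[freq[feats] > thr]
    methods::new("SelectionResult", frequency = freq,
                 category = cat_of, thresholds = thresholds,
                 selected = selected, nBoot = as.integer(nBoot),
                 fraction = fraction, lambdas = lambdas)
}

#' Apply recurrence thresholds to selection frequencies
#'
#' Pure helper implementing the strict "more than" rule: a feature is kept
#' only when its bootstrap recurrence frequency strictly exceeds its
#' category's threshold (sequence features 0.90, all others 0.75 by
#' default).
#'
#' @param frequency named numeric of selection frequencies.
#' @param categories named character, feature -> category.
#' @param thresholds named numeric \code{c(sequence = , default = )}.
#' @return character vector of selected feature names.
#' @export
applyThresholds <- function(frequency, categories,
                            thresholds = c(sequence = 0.90, default = 0.75)) {
    thr <- ifelse(categories[names(frequency)] == "sequence",
                  thresholds[["sequence"]], thresholds[["default"]])
    names(frequency)[frequency > thr]
}

#' McFadden's pseudo R-squared
#'
#' \code{1 - LL_model / LL_null}, the standard goodness-of-fit summary for
#' logistic models; the null model is intercept-only on the same data.
#'
#' @param modelLoglik log-likelihood of the fitted model.
#' @param nullLoglik log-likelihood of the intercept-only model (must be
#'   nonzero).
#' @return numeric scalar in [0, 1) for fitted models.
#' @export
mcfaddenR2 <- function(modelLoglik, nullLoglik) {
    if (nullLoglik == 0) .stop_data("degenerate null model (loglik = 0)")
    1 - modelLoglik / nullLoglik
}

#' Serialize a selection result
#'
#' @param x \linkS4class{SelectionResult}.
#' @param path output TSV (feature, category, frequency, selected).
#' @return (invisibly) the path.
#' @export
writeSelection <- function(x, path) {
    df <- data.frame(feature = names(x@frequency),
                     category = x@category[names(x@frequency)],
                     frequency = x@frequency,
                     selected = names(x@frequency) %in% x@selected)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
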