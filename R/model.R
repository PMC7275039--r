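# Patient- and position-specific background mutation model: unpenalized
# logistic fit on the selected features, with the case-control intercept
# correction applied at prediction time.

## Core logistic fit on a dense matrix with aliasing and separation handling.
.logistic_fit <- function(Xd, y, ridgeFallback = TRUE) {
    sepWarn <- FALSE
    fit <- withCallingHandlers(
        stats::glm.fit(cbind(`(Intercept)` = 1, Xd), y,
                       family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sepWarn <<- TRUE
            invokeRestart("muffleWarning")
        })
    coefs <- fit$coefficients
    aliased <- names(coefs)[is.na(coefs)]
    if (length(aliased)) {
        warning("dropping aliased column(s): ",
                paste(aliased, collapse = ", "), call. = FALSE)
        keep <- setdiff(colnames(Xd), aliased)
        return(.logistic_fit(Xd[, keep, drop = FALSE], y, ridgeFallback))
    }
    separated <- sepWarn || !fit$converged || any(abs(coefs) > 15)
    if (separated && ridgeFallback && ncol(Xd) > 0L) {
        warning("quasi-separation detected; refitting with a ridge-",
                "stabilized logistic model", call. = FALSE)
        rf <- glmnet::glmnet(Xd, y, family = "binomial", alpha = 0,
                             lambda = c(1, 0.1, 0.01, 1e-3),
                             standardize = FALSE)
        beta <- as.numeric(rf$beta[, ncol(rf$beta)])
        a0 <- rf$a0[length(rf$a0)]
        coefs <- c(`(Intercept)` = unname(a0),
                   stats::setNames(beta, colnames(Xd)))
        Xi <- cbind(1, Xd)
        p <- stats::plogis(as.numeric(Xi %*% coefs))
        W <- p * (1 - p)
        Iobs <- crossprod(Xi, Xi * W) +
            diag(c(0, rep(1e-3 * nrow(Xd), ncol(Xd))))
        se <- sqrt(diag(solve(Iobs)))
        return(list(coefficients = coefs,
                    se = stats::setNames(se, names(coefs)),
                    method = "ridge",
                    loglik = sum(y * log(pmax(p, 1e-300)) +
                                 (1 - y) * log(pmax(1 - p, 1e-300)))))
    }
    # SEs from the observed information matrix of the converged IRLS fit
    p <- fit$fitted.values
    W <- p * (1 - p)
    Xi <- cbind(1, Xd)
    Iobs <- crossprod(Xi, Xi * W)
    se <- sqrt(diag(solve(Iobs)))
    list(coefficients = coefs, se = stats::setNames(se, names(coefs)),
         method = "glm",
         loglik = sum(y * log(pmax(p, 1e-300)) +
                      (1 - y) * log(pmax(1 - p, 1e-300))))
}

#' Fit a logistic background model on a prepared design
#'
#' Matrix-level fitting primitive: unpenalized maximum-likelihood logistic
#' regression of mutated/non-mutated labels on the supplied columns, with
#' rank-deficient columns dropped (warning) and a ridge-stabilized fallback
#' under quasi-separation (warning). Because the training rows are a
#' balanced case-control subsample of the genome, predictions must subtract
#' the sampling offset \code{log(f1/f0)} from the fitted intercept; the
#' offset is recorded here and applied by the prediction functions.
#'
#' @param X numeric matrix (dense or sparse) of covariate columns.
#' @param y 0/1 labels.
#' @param samplingFractions named \code{c(f1 = , f0 = )} achieved sampling
#'   fractions (see \code{\link{sampleSites}}); \code{c(1, 1)} when the rows
#'   are not subsampled.
#' @param variantClass stored on the model.
#' @param designInfo,sampleCovariates optional metadata stored on the model
#'   (filled in by \code{\link{fitBackgroundModel}}).
#' @param featureNames names of the positional feature groups in \code{X}.
#' @return a \linkS4class{BackgroundModel}.
#' @export
fitBackground <- function(X, y, samplingFractions = c(f1 = 1, f0 = 1),
                          variantClass = "SNV", designInfo = list(),
                          sampleCovariates = data.frame(),
                          featureNames = character()) {
    Xd <- as.matrix(X)
    y <- as.numeric(y)
    keep <- rep(TRUE, ncol(Xd))
    if (ncol(Xd)) {
        allzero <- apply(Xd, 2L, function(v) all(v == v[1L]))
        if (any(allzero)) {
            warning("dropping constant column(s): ",
                    paste(colnames(Xd)[allzero], collapse = ", "),
                    call. = FALSE)
            keep <- !allzero
        }
    }
    fit <- .logistic_fit(Xd[, keep, drop = FALSE], y)
    coefs <- fit$coefficients
    intercept <- coefs[["(Intercept)"]]
    beta <- coefs[setdiff(names(coefs), "(Intercept)")]
    se <- fit$se[names(beta)]
    offset <- log(samplingFractions[["f1"]] / samplingFractions[["f0"]])
    designInfo$nullLoglik <- {
        pbar <- mean(y)
        length(y) * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
    }
    designInfo$loglik <- fit$loglik
    methods::new("BackgroundModel",
                 coefficients = beta, se = se, zvalues = beta / se,
                 intercept = intercept, offset = offset,
                 variantClass = variantClass,
                 featureNames = featureNames,
                 designInfo = designInfo,
                 sampleCovariates = sampleCovariates,
                 method = fit$method)
}

#' Fit the background model from a site table
#'
#' High-level fit: assembles the positional design for the sampled sites,
#' restricts it to the stability-selected features (all candidates when
#' \code{selection} is \code{NULL}), appends the always-included sample-level
#' covariates (log1p mutation burden, centered, plus any user columns), and
#' delegates to \code{\link{fitBackground}}. The returned model carries
#' everything needed to predict at new positions: encoding metadata,
#' standardization parameters and the per-sample covariate table.
#'
#' @param table \linkS4class{SiteTable} from \code{\link{sampleSites}}.
#' @param catalog \linkS4class{MutationCatalog} (for burden counts).
#' @param genome,tracks,specs as in \code{\link{assembleDesign}}.
#' @param selection optional \linkS4class{SelectionResult}.
#' @param userSampleCovariates optional data.frame keyed by \code{sample}
#'   with extra per-sample columns (signature proportions, subtype flags);
#'   they enter the model unpenalized.
#' @return a \linkS4class{BackgroundModel}.
#' @export
fitBackgroundModel <- function(table, catalog, genome, tracks, specs,
                               selection = NULL,
                               userSampleCovariates = NULL) {
    d <- buildDesignMatrix(table, genome, tracks, specs)
    selectedGroups <- if (is.null(selection)) unique(d$groups)
                      else selectedFeatures(selection)
    keep <- d$groups %in% selectedGroups
    Xpos <- d$X[, keep, drop = FALSE]
    groups <- d$groups[keep]

    burden <- sampleBurden(catalog, table@variantClass)
    burdenCenter <- mean(log1p(burden))
    sc <- data.frame(sample = names(burden),
                     burden = as.integer(burden),
                     burden_z = log1p(burden) - burdenCenter,
                     stringsAsFactors = FALSE)
    if (!is.null(userSampleCovariates)) {
        if (!"sample" %in% names(userSampleCovariates))
            .stop_config("userSampleCovariates needs a 'sample' column")
        sc <- merge(sc, userSampleCovariates, by = "sample", sort = TRUE)
    }
    rowIdx <- match(d$sample, sc$sample)
    if (anyNA(rowIdx))
        .stop_data("site table contains samples without covariates")
    covCols <- setdiff(names(sc), c("sample", "burden"))
    Xsamp <- as.matrix(sc[rowIdx, covCols, drop = FALSE])
    colnames(Xsamp) <- covCols
    X <- cbind(as.matrix(Xpos), Xsamp)

    model <- fitBackground(
        X, d$y, samplingFractions = samplingFractions(table),
        variantClass = table@variantClass,
        designInfo = list(specs = specs, encoding = d$info,
                          selected = selectedGroups,
                          sampleCovariateNames = covCols,
                          burdenCenter = burdenCenter),
        sampleCovariates = sc,
        featureNames = selectedGroups)
    model
}

## Positional part of the linear predictor (corrected intercept included).
.position_eta <- function(model, genome, tracks, contig, positions) {
    di <- model@designInfo
    specs <- di$specs
    specs <- specs[specs$category == "sample_level" |
                   specs$name %in% di$selected, , drop = FALSE]
    d <- assembleDesign(genome, tracks, specs, contig, positions,
                        info = di$encoding)
    beta <- model@coefficients
    posCols <- intersect(colnames(d$X), names(beta))
    eta <- if (length(posCols))
        as.numeric(d$X[, posCols, drop = FALSE] %*% beta[posCols])
    else numeric(length(positions))
    list(eta = (model@intercept - model@offset) + eta,
         available = d$available)
}

## Sample-level part of the linear predictor.
.sample_eta <- function(model, sample) {
    sc <- model@sampleCovariates
    i <- match(sample, sc$sample)
    if (anyNA(i)) .stop_data("unknown sample(s): ",
                             paste(sample[is.na(i)], collapse = ", "))
    covCols <- model@designInfo$sampleCovariateNames
    covCols <- intersect(covCols, names(model@coefficients))
    if (!length(covCols)) return(numeric(length(sample)))
    Z <- as.matrix(sc[i, covCols, drop = FALSE])
    as.numeric(Z %*% model@coefficients[covCols])
}

#' Predict per-(sample, position) background mutation probabilities
#'
#' \code{p = logistic(corrected intercept + beta . x(position) +
#' gamma . z(sample))} where the corrected intercept is the fitted intercept
#' minus the case-control offset \code{log(f1/f0)}. Deterministic;
#' positions outside the supplied mask, positions without a valid context,
#' and samples unknown to the model are errors.
#'
#' @param model \linkS4class{BackgroundModel}.
#' @param sample a single cohort sample id.
#' @param contig contig name (scalar).
#' @param positions 1-based positions.
#' @param genome,tracks as used at training time.
#' @param mask optional analyzable \code{GRanges}; when supplied, every
#'   queried position must fall inside it.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictProbability <- function(model, sample, contig, positions, genome,
                               tracks, mask = NULL) {
    stopifnot(length(sample) == 1L)
    if (!is.null(mask)) {
        pts <- GenomicRanges::GRanges(rep(contig, length(positions)),
                                      IRanges::IRanges(positions, width = 1L))
        if (!all(IRanges::overlapsAny(pts, mask)))
            .stop_data("query position(s) outside the analyzable mask")
    }
    pe <- .position_eta(model, genome, tracks, contig, positions)
    if (!all(pe$available))
        .stop_data("query position(s) without a valid sequence context")
    stats::plogis(pe$eta + .sample_eta(model, sample))
}

#' Construct a probability field
#'
#' Bundles a fitted model with its genome, tracks and mask into a
#' deterministic (sample, position) -> probability lookup.
#'
#' @param model \linkS4class{BackgroundModel}.
#' @param genome \code{DNAStringSet}.
#' @param tracks named track list (must include \code{local_rate} when the
#'   model uses it).
#' @param mask analyzable \code{GRanges}.
#' @return a \linkS4class{ProbabilityField}.
#' @export
probabilityField <- function(model, genome, tracks, mask) {
    methods::new("ProbabilityField", model = model, genome = genome,
                 tracks = tracks, mask = mask)
}

#' @rdname probabilityField
#' @param field a \linkS4class{ProbabilityField}.
#' @param sample,contig,positions query (see
#'   \code{\link{predictProbability}}).
#' @export
fieldProbability <- function(field, sample, contig, positions) {
    predictProbability(field@model, sample, contig, positions,
                       field@genome, field@tracks, mask = field@mask)
}

#' Feature-importance table
#'
#' Per-feature Z-values (coefficient / standard error) of the fitted
#' background model, sorted by decreasing |Z| with name tie-breaking;
#' aliased (dropped) columns are absent.
#'
#' @param model \linkS4class{BackgroundModel}.
#' @return data.frame with columns \code{feature}, \code{coefficient},
#'   \code{se}, \code{zvalue}.
#' @export
zvalueTable <- function(model) {
    z <- model@zvalues
    if (length(z) == 0L)
        return(data.frame(feature = character(), coefficient = numeric(),
                          se = numeric(), zvalue = numeric()))
    df <- data.frame(feature = names(z),
                     coefficient = unname(model@coefficients),
                     se = unname(model@se),
                     zvalue = unname(z), stringsAsFactors = FALSE)
    df[order(-abs(df$zvalue), df$feature), , drop = FALSE]
}

#' McFadden pseudo R-squared of a fitted background model
#'
#' @param model \linkS4class{BackgroundModel} fitted by
#'   \code{\link{fitBackground}}.
#' @return numeric scalar.
#' @export
modelPseudoR2 <- function(model) {
    mcfaddenR2(model@designInfo$loglik, model@designInfo$nullLoglik)
}

#' Serialize / restore a background model
#'
#' The model is written as a versioned JSON text artifact holding the
#' coefficients, standard errors, sampling offset, encoding metadata and the
#' per-sample covariate table. Tracks and genome are not embedded; they are
#' re-supplied at prediction time.
#'
#' @param model \linkS4class{BackgroundModel}.
#' @param path JSON file path.
#' @return \code{writeBackgroundModel}: (invisibly) the path;
#'   \code{readBackgroundModel}: the restored model.
#' @export
writeBackgroundModel <- function(model, path) {
    di <- model@designInfo
    obj <- list(
        format = "somaticHotspots/background-model/1",
        variantClass = model@variantClass,
        intercept = model@intercept,
        offset = model@offset,
        method = model@method,
        coefficients = as.list(model@coefficients),
        se = as.list(model@se),
        featureNames = model@featureNames,
        selected = di$selected,
        sampleCovariateNames = di$sampleCovariateNames,
        burdenCenter = di$burdenCenter,
        loglik = di$loglik, nullLoglik = di$nullLoglik,
        specs = di$specs,
        standardize = lapply(di$encoding$standardize, as.list),
        sampleCovariates = model@sampleCovariates)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeBackgroundModel
#' @export
readBackgroundModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    std <- lapply(obj$standardize, unlist)
    methods::new("BackgroundModel",
        coefficients = unlist(obj$coefficients),
        se = unlist(obj$se),
        zvalues = unlist(obj$coefficients) / unlist(obj$se),
        intercept = obj$intercept, offset = obj$offset,
        variantClass = obj$variantClass,
        featureNames = as.character(obj$featureNames),
        designInfo = list(specs = as.data.frame(obj$specs),
                          encoding = list(standardize = std),
                          selected = as.character(obj$selected),
                          sampleCovariateNames =
                              as.character(obj$sampleCovariateNames),
                          burdenCenter = obj$burdenCenter,
                          loglik = obj$loglik, nullLoglik = obj$nullLoglik),
        sampleCovariates = as.data.frame(obj$sampleCovariates),
        method = obj$method)
}
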