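#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols metadata
NULL

#' Cohort somatic mutation catalog
#'
#' Holds per-sample somatic variants as a \link[GenomicRanges]{GRanges}
#' (1-based, width = reference-allele length) with metadata columns
#' \code{sample}, \code{ref}, \code{alt} and \code{class} (\code{"SNV"} or
#' \code{"indel"}), plus the cohort sample roster. Records are unique on
#' (contig, position, alt, sample).
#'
#' @slot variants \code{GRanges} of variant records.
#' @slot samples character vector of cohort sample identifiers.
#' @export
setClass("MutationCatalog",
    slots = c(variants = "GRanges", samples = "character"))

setValidity("MutationCatalog", function(object) {
    mc <- S4Vectors::mcols(object@variants)
    need <- c("sample", "ref", "alt", "class")
    if (!all(need %in% colnames(mc)))
        return(paste("variants must carry mcols:", paste(need, collapse = ", ")))
    if (length(object@variants)) {
        if (!all(mc$class %in% c("SNV", "indel")))
            return("variant class must be 'SNV' or 'indel'")
        if (!all(mc$sample %in% object@samples))
            return("every record's sample must be in the sample roster")
        key <- paste(as.character(GenomicRanges::seqnames(object@variants)),
                     GenomicRanges::start(object@variants), mc$alt, mc$sample)
        if (anyDuplicated(key))
            return("duplicate (contig, position, alt, sample) records")
    }
    TRUE
})

#' Position-addressable genomic covariate track
#'
#' A binary overlay (interval membership) or continuous profile (piecewise
#' constant value with a default outside covered intervals), queryable at any
#' genomic position.
#'
#' @slot name feature name.
#' @slot kind \code{"binary"} or \code{"continuous"}.
#' @slot intervals \code{GRanges}; continuous tracks carry a \code{score}
#'   metadata column.
#' @slot default value returned at uncovered positions (0 for binary).
#' @export
setClass("GenomicTrack",
    slots = c(name = "character", kind = "character",
              intervals = "GRanges", default = "numeric"))

setValidity("GenomicTrack", function(object) {
    if (!object@kind %in% c("binary", "continuous"))
        return("kind must be 'binary' or 'continuous'")
    if (object@kind == "continuous") {
        sc <- S4Vectors::mcols(object@intervals)$score
        if (length(object@intervals) && (is.null(sc) || !all(is.finite(sc))))
            return("continuous tracks need finite 'score' values")
    }
    TRUE
})

#' Balanced training-site table
#'
#' The sampled mutated and non-mutated (position, sample) pairs used to fit
#' the background model, together with the sampling fractions needed for the
#' case-control intercept correction: \code{f1} = drawn / total mutated sites,
#' \code{f0} = drawn / total analyzable non-mutated position-sample pairs.
#'
#' @slot sites \code{GRanges} points with mcols \code{sample} and \code{label}
#'   (1 = mutated, 0 = non-mutated).
#' @slot variantClass \code{"SNV"} or \code{"indel"}.
#' @slot nMutated,nUnmutated row counts by label.
#' @slot samplingFractions named numeric, \code{c(f1 = , f0 = )}.
#' @export
setClass("SiteTable",
    slots = c(sites = "GRanges", variantClass = "character",
              nMutated = "integer", nUnmutated = "integer",
              samplingFractions = "numeric"))

setValidity("SiteTable", function(object) {
    f <- object@samplingFractions
    if (!all(c("f1", "f0") %in% names(f)))
        return("samplingFractions must be named c(f1=, f0=)")
    if (any(f <= 0 | f > 1)) return("sampling fractions must lie in (0, 1]")
    mc <- S4Vectors::mcols(object@sites)
    if (!all(c("sample", "label") %in% colnames(mc)))
        return("sites must carry mcols 'sample' and 'label'")
    TRUE
})

#' Stability-selection result
#'
#' Per-feature selection frequencies over LASSO bootstraps and the selected
#' feature set after applying category-specific recurrence thresholds
#' (a feature is kept only when its frequency strictly exceeds the threshold
#' for its category).
#'
#' @slot frequency named numeric in [0, 1], one entry per candidate feature.
#' @slot category named character, feature -> category.
#' @slot thresholds named numeric, \code{c(sequence = 0.90, default = 0.75)}.
#' @slot selected character vector of selected feature names.
#' @slot nBoot number of bootstraps.
#' @slot fraction subsample fraction per bootstrap.
#' @slot lambdas per-bootstrap regularization strength chosen by the 1-SE rule.
#' @export
setClass("SelectionResult",
    slots = c(frequency = "numeric", category = "character",
              thresholds = "numeric", selected = "character",
              nBoot = "integer", fraction = "numeric", lambdas = "numeric"))

setValidity("SelectionResult", function(object) {
    if (!all(object@selected %in% names(object@frequency)))
        return("selected features must be a subset of candidates")
    if (any(object@frequency < 0 | object@frequency > 1))
        return("frequencies must lie in [0, 1]")
    TRUE
})

#' Patient- and position-specific background mutation model
#'
#' An unpenalized logistic regression fit on the balanced training sites,
#' restricted to stability-selected positional features plus always-included
#' sample-level covariates. Stores the case-control offset
#' \code{log(f1/f0)}; predictions subtract it from the fitted intercept so
#' probabilities are on the genome-wide prior scale.
#'
#' @slot coefficients,se,zvalues named numerics for non-intercept terms.
#' @slot intercept fitted intercept (uncorrected).
#' @slot offset \code{log(f1/f0)} case-control sampling offset.
#' @slot variantClass \code{"SNV"} or \code{"indel"}.
#' @slot featureNames selected positional feature (group) names.
#' @slot designInfo encoding metadata (context configuration, one-hot levels,
#'   continuous standardization, burden centering) needed to rebuild design
#'   rows at prediction time.
#' @slot sampleCovariates data.frame keyed by \code{sample} with the
#'   sample-level covariate values used at prediction time.
#' @slot method \code{"glm"} or \code{"ridge"} (separation fallback).
#' @export
setClass("BackgroundModel",
    slots = c(coefficients = "numeric", se = "numeric", zvalues = "numeric",
              intercept = "numeric", offset = "numeric",
              variantClass = "character", featureNames = "character",
              designInfo = "list", sampleCovariates = "data.frame",
              method = "character"))

setValidity("BackgroundModel", function(object) {
    if (length(object@coefficients) &&
        !identical(names(object@coefficients), names(object@zvalues)))
        return("coefficients and zvalues must be aligned")
    if (length(object@zvalues) && !all(is.finite(object@zvalues)))
        return("Z-values must be finite for estimable coefficients")
    TRUE
})

#' Deterministic (sample, position) -> probability field
#'
#' Thin handle bundling a fitted \linkS4class{BackgroundModel} with the genome,
#' tracks and analyzable mask it predicts over. Evaluations are pure: the same
#' query always returns the same probability; positions outside the mask are
#' an error.
#'
#' @slot model fitted \linkS4class{BackgroundModel}.
#' @slot genome \code{DNAStringSet}.
#' @slot tracks named list of \linkS4class{GenomicTrack}.
#' @slot mask analyzable \code{GRanges}.
#' @export
setClass("ProbabilityField",
    slots = c(model = "BackgroundModel", genome = "DNAStringSet",
              tracks = "list", mask = "GRanges"))

#' Hotspot scan results
#'
#' All evaluated candidate windows (with Poisson-binomial p-values and padded
#' Benjamini-Hochberg q-values) plus the merged significant hotspot calls.
#'
#' @slot windows \code{GRanges} of every evaluated candidate window; mcols
#'   \code{center}, \code{nSamples}, \code{nMutations}, \code{meanProb},
#'   \code{pvalue}, \code{fdr}.
#' @slot hotspots \code{GRanges} of merged calls below the FDR threshold.
#' @slot mTotal number of hypotheses used for the BH correction (analyzable
#'   nucleotides in genome mode; masked region nucleotides in region mode).
#' @slot params list of scan parameters (l, n, fdrThreshold, mode, ...).
#' @export
setClass("HotspotResults",
    slots = c(windows = "GRanges", hotspots = "GRanges",
              mTotal = "numeric", params = "list"))

#' Ground truth of a simulated cohort
#'
#' @slot spikes \code{GRanges} of spiked hotspot windows (mcol
#'   \code{successProb}).
#' @slot beta named numeric, true per-track log-odds coefficients.
#' @slot intercept true intercept on the logit scale.
#' @slot burdenShift named numeric, per-sample log-odds shifts.
#' @slot config the \code{simulationConfig()} list used.
#' @export
setClass("TruthSet",
    slots = c(spikes = "GRanges", beta = "numeric", intercept = "numeric",
              burdenShift = "numeric", config = "list"))
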