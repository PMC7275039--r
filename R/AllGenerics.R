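#' @include AllClasses.R
NULL

#' Accessors for somaticHotspots objects
#'
#' Small accessor family: \code{variants()} returns the variant
#' \code{GRanges} of a catalog, \code{sampleIDs()} its sample roster,
#' \code{hotspots()} / \code{scannedWindows()} the merged calls and all
#' evaluated windows of a scan, \code{selectedFeatures()} /
#' \code{featureFrequency()} the outcome of stability selection, and
#' \code{samplingFractions()} the (f1, f0) pair of a site table.
#'
#' @param x an object of the documented class.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases variants sampleIDs hotspots scannedWindows selectedFeatures
#'   featureFrequency samplingFractions
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("hotspots", function(x) standardGeneric("hotspots"))
#' @rdname accessors
#' @export
setGeneric("scannedWindows", function(x) standardGeneric("scannedWindows"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("featureFrequency", function(x) standardGeneric("featureFrequency"))
#' @rdname accessors
#' @export
setGeneric("samplingFractions", function(x) standardGeneric("samplingFractions"))

#' @rdname accessors
setMethod("variants", "MutationCatalog", function(x) x@variants)
#' @rdname accessors
setMethod("sampleIDs", "MutationCatalog", function(x) x@samples)
#' @rdname accessors
setMethod("hotspots", "HotspotResults", function(x) x@hotspots)
#' @rdname accessors
setMethod("scannedWindows", "HotspotResults", function(x) x@windows)
#' @rdname accessors
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)
#' @rdname accessors
setMethod("featureFrequency", "SelectionResult", function(x) x@frequency)
#' @rdname accessors
setMethod("samplingFractions", "SiteTable", function(x) x@samplingFractions)

setMethod("show", "MutationCatalog", function(object) {
    v <- object@variants
    cls <- table(factor(S4Vectors::mcols(v)$class, c("SNV", "indel")))
    cat("MutationCatalog with", length(v), "records (",
        cls[["SNV"]], "SNV,", cls[["indel"]], "indel ) across",
        length(object@samples), "samples\n")
})

setMethod("show", "GenomicTrack", function(object) {
    cat("GenomicTrack '", object@name, "' (", object@kind, "): ",
        length(object@intervals), " intervals, default ", object@default,
        "\n", sep = "")
})

setMethod("show", "SiteTable", function(object) {
    f <- signif(object@samplingFractions, 4)
    cat("SiteTable (", object@variantClass, "): ", object@nMutated,
        " mutated + ", object@nUnmutated, " non-mutated sites; f1=",
        f[["f1"]], ", f0=", f[["f0"]], "\n", sep = "")
})

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult:", length(object@frequency), "candidates,",
        length(object@selected), "selected over", object@nBoot,
        "bootstraps\n")
    if (length(object@selected))
        cat("  selected:", paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "BackgroundModel", function(object) {
    cat("BackgroundModel (", object@variantClass, "): ",
        length(object@coefficients), " coefficients, corrected intercept ",
        signif(object@intercept - object@offset, 4),
        " (offset ", signif(object@offset, 4), "), fit = ", object@method,
        "\n", sep = "")
})

setMethod("show", "HotspotResults", function(object) {
    cat("HotspotResults:", length(object@windows), "windows evaluated,",
        length(object@hotspots), "hotspots at FDR <",
        object@params$fdrThreshold %||% 0.05,
        "( m =", format(object@mTotal, big.mark = ","), ")\n")
})

setMethod("show", "ProbabilityField", function(object) {
    cat("ProbabilityField over", length(object@mask), "mask intervals,",
        nrow(object@model@sampleCovariates), "samples\n")
})
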