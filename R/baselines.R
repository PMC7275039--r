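# The four reference background strategies the full model is compared
# against, reusing the scan/correction machinery with simpler per-sample
# per-position rates.

## Quantile-binned relative rate of a continuous track over the mask:
## rel(bin) = (fraction of mutations in bin) / (fraction of bases in bin),
## so the base-weighted mean relative rate is 1.
.relative_rate_by_quantile <- function(track, mask, events, nQuantiles = 5L) {
    # piecewise-constant values over the mask
    cov <- GenomicRanges::intersect(mask, track@intervals)
    pieces <- c(cov, GenomicRanges::setdiff(mask, track@intervals))
    vals <- .track_values_multi(track,
        as.character(GenomicRanges::seqnames(pieces)),
        GenomicRanges::start(pieces))
    w <- as.numeric(GenomicRanges::width(pieces))
    ord <- order(vals)
    cw <- cumsum(w[ord]) / sum(w)
    qgrp <- findInterval(cw, seq_len(nQuantiles - 1L) / nQuantiles) + 1L
    # value -> quantile bin lookup via break values
    brks <- vapply(seq_len(nQuantiles - 1L), function(b) {
        v <- vals[ord][qgrp <= b]
        if (length(v)) max(v) else -Inf     # empty quantile bin
    }, numeric(1L))
    binOf <- function(v) findInterval(v, brks, left.open = FALSE) + 1L
    baseFrac <- vapply(seq_len(nQuantiles), function(b)
        sum(w[binOf(vals) == b]) / sum(w), numeric(1L))
    evVals <- .track_values_multi(track, events$contig, events$pos)
    evFrac <- tabulate(binOf(evVals), nQuantiles) / max(nrow(events), 1L)
    rel <- ifelse(baseFrac > 0, evFrac / baseFrac, 0)
    list(rel = rel, binOf = binOf)
}

#' Baseline hotspot scans
#'
#' Re-runs the window scan under four simpler background strategies, in
#' increasing order of information used: (1) a binomial model with the
#' cohort's average genome-wide mutation rate shared by all samples;
#' (2) a Poisson-binomial model with per-sample genome-wide rates (burden /
#' mask size); (3) additionally modulating the per-sample rate by the
#' quantile-binned relative mutation rate of a replication-timing profile;
#' (4) additionally modulating by the 100-kb local mutation rate. More
#' informed baselines are expected to call fewer hotspots.
#'
#' @param catalog \linkS4class{MutationCatalog}.
#' @param genome \code{DNAStringSet}.
#' @param mask analyzable \code{GRanges}.
#' @param variant one of \code{"binomial_avg"}, \code{"poibin_sample"},
#'   \code{"poibin_rt"}, \code{"poibin_rt_local"}.
#' @param rtTrack continuous replication-timing \linkS4class{GenomicTrack}
#'   (required for variants 3 and 4).
#' @param localRateTrack 100-kb local-rate track from
#'   \code{\link{computeLocalRate}} (required for variant 4; computed from
#'   the catalog when absent).
#' @param variantClass \code{"SNV"} or \code{"indel"}.
#' @param l,n,fdrThreshold scan parameters as in \code{\link{callHotspots}}.
#' @param nQuantiles quantile bins for the replication-timing modulation.
#' @return a \linkS4class{HotspotResults}.
#' @export
baselineModels <- function(catalog, genome, mask,
                           variant = c("binomial_avg", "poibin_sample",
                                       "poibin_rt", "poibin_rt_local"),
                           rtTrack = NULL, localRateTrack = NULL,
                           variantClass = c("SNV", "indel"),
                           l = 21L, n = 2L, fdrThreshold = 0.05,
                           nQuantiles = 5L) {
    variant <- match.arg(variant)
    variantClass <- match.arg(variantClass)
    if (variant %in% c("poibin_rt", "poibin_rt_local") && is.null(rtTrack))
        .stop_config("variant '", variant,
                     "' requires a replication-timing track")
    if (variant == "poibin_rt_local" && is.null(localRateTrack))
        localRateTrack <- computeLocalRate(catalog, genome,
                                           variantClass = variantClass)
    maskBases <- sum(as.numeric(GenomicRanges::width(mask)))
    samples <- sampleIDs(catalog)
    burden <- sampleBurden(catalog, variantClass)
    total <- sum(burden)
    perSample <- if (variant == "binomial_avg")
        rep(total / (maskBases * length(samples)), length(samples))
    else burden / maskBases
    names(perSample) <- samples

    v <- variants(catalog)
    pts <- GenomicRanges::resize(
        v[S4Vectors::mcols(v)$class == variantClass], 1L, fix = "start")
    ev <- data.frame(contig = as.character(GenomicRanges::seqnames(pts)),
                     pos = GenomicRanges::start(pts),
                     stringsAsFactors = FALSE)
    rtMod <- NULL
    if (variant %in% c("poibin_rt", "poibin_rt_local"))
        rtMod <- .relative_rate_by_quantile(rtTrack, mask, ev, nQuantiles)
    localMean <- if (variant == "poibin_rt_local")
        total / (maskBases * length(samples)) else NULL

    probFun <- function(ct, pos) {
        mod <- rep(1, length(pos))
        if (!is.null(rtMod)) {
            vv <- trackValues(rtTrack, ct, pos)
            mod <- mod * rtMod$rel[rtMod$binOf(vv)]
        }
        if (!is.null(localMean)) {
            lr <- trackValues(localRateTrack, ct, pos)
            mod <- mod * (lr / localMean)
        }
        outer(unname(perSample), mod)
    }
    posFilter <- function(ct, pos)
        IRanges::overlapsAny(
            GenomicRanges::GRanges(ct, IRanges::IRanges(pos, width = 1L)),
            mask)
    cands <- enumerateCandidates(catalog, mask, l = l, n = n,
                                 variantClass = variantClass)
    res <- .scan_core(cands, samples, probFun, posFilter, maskBases,
                      fdrThreshold)
    windows <- res$windows
    S4Vectors::mcols(windows)$meanProb <- res$meanProb
    S4Vectors::mcols(windows)$pvalue <- res$pvalue
    S4Vectors::mcols(windows)$fdr <- res$fdr
    if (length(windows))
        windows <- windows[order(windows$pvalue,
            as.character(GenomicRanges::seqnames(windows)),
            GenomicRanges::start(windows))]
    sig <- windows[windows$fdr < fdrThreshold]
    hot <- .merge_calls(sig, catalog, variantClass)
    methods::new("HotspotResults", windows = windows, hotspots = hot,
                 mTotal = maskBases,
                 params = list(l = l, n = n, fdrThreshold = fdrThreshold,
                               mode = "genome", baseline = variant,
                               variantClass = variantClass))
}
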