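# Descriptive figures: genome-wide Manhattan plot of window p-values,
# feature-importance Z-value barplot, and per-hotspot lollipop plot.

#' Manhattan plot of scanned windows
#'
#' \code{-log10(p)} of every evaluated window against its genomic
#' coordinate (contigs laid end to end); windows below the FDR threshold
#' are highlighted in magenta. Renders an empty frame without error when no
#' windows were evaluated.
#'
#' @param results \linkS4class{HotspotResults}.
#' @param fdrThreshold highlight threshold (default the scan's own).
#' @return a ggplot object.
#' @import ggplot2
#' @export
plotManhattan <- function(results,
                          fdrThreshold = results@params$fdrThreshold) {
    w <- scannedWindows(results)
    if (length(w) == 0L) {
        return(ggplot2::ggplot() +
               ggplot2::labs(x = "genomic position", y = "-log10 p") +
               ggplot2::theme_minimal())
    }
    ct <- as.character(GenomicRanges::seqnames(w))
    lens <- GenomeInfoDb::seqlengths(w)
    if (any(is.na(lens))) lens[is.na(lens)] <- tapply(
        GenomicRanges::end(w), ct, max)[names(lens)[is.na(lens)]]
    offs <- c(0, cumsum(as.numeric(lens)))[seq_along(lens)]
    names(offs) <- names(lens)
    df <- data.frame(x = offs[ct] + w$center,
                     y = -log10(pmax(w$pvalue, 1e-300)),
                     significant = w$fdr < fdrThreshold)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$significant)) +
        ggplot2::geom_point(size = 1) +
        ggplot2::scale_color_manual(
            values = c(`FALSE` = "grey40", `TRUE` = "magenta"),
            guide = "none") +
        ggplot2::labs(x = "genomic position", y = "-log10 p") +
        ggplot2::theme_minimal()
}

#' Feature-importance barplot
#'
#' Horizontal bars of the background-model Z-values, ordered by decreasing
#' |Z| (the order of \code{\link{zvalueTable}}).
#'
#' @param ztable data.frame from \code{\link{zvalueTable}} (or a
#'   \linkS4class{BackgroundModel}).
#' @return a ggplot object.
#' @export
plotFeatureImportance <- function(ztable) {
    if (methods::is(ztable, "BackgroundModel")) ztable <- zvalueTable(ztable)
    if (nrow(ztable) == 0L)
        .stop_data("no features to plot (empty Z-value table)")
    ztable$feature <- factor(ztable$feature, levels = rev(ztable$feature))
    ggplot2::ggplot(ztable, ggplot2::aes(x = .data$zvalue,
                                         y = .data$feature)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = "Z-value", y = NULL) +
        ggplot2::theme_minimal()
}

#' Lollipop plot of one hotspot
#'
#' Per-position stem heights give the number of distinct mutated samples at
#' each position in the call window and its flanks; the window itself is
#' shaded.
#'
#' @param call a length-1 \code{GRanges} hotspot call.
#' @param catalog \linkS4class{MutationCatalog}.
#' @param flank flank width in bp (default 50).
#' @param variantClass \code{"SNV"} or \code{"indel"}.
#' @return a ggplot object.
#' @export
plotLollipop <- function(call, catalog, flank = 50L,
                         variantClass = c("SNV", "indel")) {
    stopifnot(length(call) == 1L)
    variantClass <- match.arg(variantClass)
    ct <- as.character(GenomicRanges::seqnames(call))
    lo <- GenomicRanges::start(call) - flank
    hi <- GenomicRanges::end(call) + flank
    v <- variants(catalog)
    v <- GenomicRanges::resize(
        v[S4Vectors::mcols(v)$class == variantClass], 1L, fix = "start")
    sel <- as.character(GenomicRanges::seqnames(v)) == ct &
        GenomicRanges::start(v) >= lo & GenomicRanges::start(v) <= hi
    pos <- GenomicRanges::start(v)[sel]
    smp <- S4Vectors::mcols(v)$sample[sel]
    agg <- if (length(pos))
        stats::aggregate(smp, by = list(pos = pos),
                         FUN = function(x) length(unique(x)))
    else data.frame(pos = integer(), x = integer())
    ggplot2::ggplot(agg, ggplot2::aes(x = .data$pos, y = .data$x)) +
        ggplot2::annotate("rect", xmin = GenomicRanges::start(call) - 0.5,
                          xmax = GenomicRanges::end(call) + 0.5,
                          ymin = -Inf, ymax = Inf, alpha = 0.15,
                          fill = "magenta") +
        ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
        ggplot2::geom_point(size = 2, color = "steelblue") +
        ggplot2::labs(x = paste0(ct, ":", lo, "-", hi),
                      y = "mutated samples") +
        ggplot2::theme_minimal()
}
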