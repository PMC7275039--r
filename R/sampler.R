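# Training-site sampler: balanced mutated / non-mutated (position, sample)
# pairs over the analyzable mask, with the sampling fractions recorded for
# the case-control intercept correction.

## Uniformly sample n positions (with replacement across draws) from a mask.
.sample_mask_positions <- function(mask, n) {
    w <- GenomicRanges::width(mask)
    tot <- sum(as.numeric(w))
    u <- ceiling(stats::runif(n) * tot)
    cw <- cumsum(as.numeric(w))
    iv <- findInterval(u - 1, cw) + 1L
    off <- u - c(0, cw)[iv]
    list(contig = as.character(GenomicRanges::seqnames(mask))[iv],
         pos = GenomicRanges::start(mask)[iv] + as.integer(off) - 1L)
}

#' Sample the balanced training-site table
#'
#' Draws up to \code{maxMutated} mutated sites of the given variant class
#' uniformly without replacement (all of them when fewer exist, mirroring the
#' behaviour for cohorts below the cap), and an equal number of non-mutated
#' (position, sample) pairs: positions uniform over the analyzable mask, each
#' paired with a cohort sample drawn uniformly and verified non-mutated at
#' that position. Both classes are restricted to positions with a valid
#' (N-free, non-truncated) 5-mer context so every row can be featurized.
#' The achieved sampling fractions f1 (mutated) and f0 (non-mutated pairs)
#' are recorded; the background-model fit uses \code{log(f1/f0)} to put
#' predicted probabilities back on the genome-wide scale.
#'
#' @param catalog \linkS4class{MutationCatalog}.
#' @param mask analyzable \code{GRanges} from \code{\link{buildMask}}.
#' @param genome \code{DNAStringSet}.
#' @param variantClass \code{"SNV"} or \code{"indel"}.
#' @param maxMutated cap on mutated sites (default 1e6).
#' @param seed RNG seed for reproducible draws.
#' @return a \linkS4class{SiteTable}.
#' @export
sampleSites <- function(catalog, mask, genome,
                        variantClass = c("SNV", "indel"),
                        maxMutated = 1000000L, seed = NULL) {
    variantClass <- match.arg(variantClass)
    cmask <- contextMask(genome, mask)
    if (length(cmask) == 0L) .stop_data("empty analyzable mask")
    v <- variants(catalog)
    v <- v[S4Vectors::mcols(v)$class == variantClass]
    pts <- GenomicRanges::resize(v, 1L, fix = "start")
    inMask <- IRanges::overlapsAny(pts, cmask)
    ev <- data.frame(
        contig = as.character(GenomicRanges::seqnames(pts))[inMask],
        pos = GenomicRanges::start(pts)[inMask],
        sample = S4Vectors::mcols(pts)$sample[inMask],
        stringsAsFactors = FALSE)
    total1 <- nrow(ev)
    if (total1 == 0L)
        .stop_data("no in-mask ", variantClass,
                   " mutations to train on")
    samples <- sampleIDs(catalog)
    maskBases <- sum(as.numeric(GenomicRanges::width(cmask)))
    totalPairs <- maskBases * length(samples) - total1
    withSeed(seed, {
        m <- min(maxMutated, total1)
        keep <- if (m < total1) sort(sample.int(total1, m)) else seq_len(total1)
        mut <- ev[keep, , drop = FALSE]
        if (m > totalPairs)
            .stop_data("mask too small: ", m, " non-mutated pairs requested ",
                       "from ", totalPairs, " available")
        mutKey <- paste(ev$contig, ev$pos, ev$sample)
        ctl <- data.frame(contig = character(), pos = integer(),
                          sample = character())
        while (nrow(ctl) < m) {
            draw <- .sample_mask_positions(cmask, 2L * (m - nrow(ctl)) + 10L)
            cand <- data.frame(contig = draw$contig, pos = draw$pos,
                               sample = sample(samples,
                                               length(draw$pos),
                                               replace = TRUE),
                               stringsAsFactors = FALSE)
            key <- paste(cand$contig, cand$pos, cand$sample)
            ok <- !(key %in% mutKey) &
                !duplicated(key) &
                !(key %in% paste(ctl$contig, ctl$pos, ctl$sample))
            ctl <- rbind(ctl, cand[ok, , drop = FALSE])
        }
        ctl <- ctl[seq_len(m), , drop = FALSE]
    })
    all <- rbind(cbind(mut, label = 1L), cbind(ctl, label = 0L))
    gr <- GenomicRanges::GRanges(all$contig,
        IRanges::IRanges(all$pos, width = 1L),
        sample = all$sample, label = all$label,
        seqinfo = .genome_seqinfo(genome))
    methods::new("SiteTable", sites = gr, variantClass = variantClass,
                 nMutated = as.integer(m), nUnmutated = as.integer(m),
                 samplingFractions = c(f1 = m / total1, f0 = m / totalPairs))
}

#' Build the sparse design matrix of a site table
#'
#' Expands every site row into its position-level feature encoding (see
#' \code{\link{assembleDesign}}); row order follows the site-table order and
#' sample-level covariates are appended later by the model fit, which knows
#' the per-row sample.
#'
#' @param table \linkS4class{SiteTable}.
#' @param genome,tracks,specs as in \code{\link{assembleDesign}}.
#' @param info encoding metadata to reuse (\code{NULL} = estimate here).
#' @return list with \code{X}, \code{y}, \code{groups}, \code{info},
#'   \code{sample} (per-row sample id).
#' @export
buildDesignMatrix <- function(table, genome, tracks, specs, info = NULL) {
    gr <- table@sites
    d <- assembleDesign(genome, tracks, specs,
                        as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr), info = info)
    if (!all(d$available))
        stop("internal error: site table contains rows without valid context")
    list(X = d$X, y = S4Vectors::mcols(gr)$label, groups = d$groups,
         info = d$info, sample = S4Vectors::mcols(gr)$sample)
}
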