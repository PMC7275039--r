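# Hotspot scan: candidate 21-bp windows, exact Poisson-binomial recurrence
# p-values against the background model, and genome-scale Benjamini-Hochberg
# correction with P = 1 padding for never-evaluated nucleotides.

#' Enumerate candidate hotspot windows
#'
#' Every analyzable nucleotide is in principle a hypothesis (its
#' \code{l}-bp window, centered on it); in practice only centers whose
#' window contains mutations from at least \code{n} distinct samples are
#' evaluated, and all remaining centers are implicitly assigned P = 1 during
#' the correction. Windows are clipped at contig ends; centers must lie in
#' the analyzable mask.
#'
#' @param catalog \linkS4class{MutationCatalog}.
#' @param mask analyzable \code{GRanges} (region-restricted in region mode).
#' @param l odd window length in bp (default 21).
#' @param n minimum number of distinct mutated samples (default 2); raise it
#'   for large cohorts to require a higher recurrence frequency and to
#'   shrink the evaluated set.
#' @param variantClass \code{"SNV"} or \code{"indel"}.
#' @return \code{GRanges} of candidate windows with mcols \code{center},
#'   \code{nSamples} (distinct mutated samples) and \code{nMutations},
#'   ordered by contig and center.
#' @importFrom IRanges IRanges coverage slice
#' @export
enumerateCandidates <- function(catalog, mask, l = 21L, n = 2L,
                                variantClass = c("SNV", "indel")) {
    variantClass <- match.arg(variantClass)
    if (l %% 2L == 0L) .stop_config("window length l must be odd, got ", l)
    if (n < 1L) .stop_config("minimum recurrence n must be >= 1, got ", n)
    h <- (l - 1L) %/% 2L
    v <- variants(catalog)
    v <- v[S4Vectors::mcols(v)$class == variantClass]
    pts <- GenomicRanges::resize(v, 1L, fix = "start")
    si <- GenomeInfoDb::seqinfo(pts)
    out <- list()
    for (ct in unique(as.character(GenomicRanges::seqnames(pts)))) {
        sel <- as.character(GenomicRanges::seqnames(pts)) == ct
        pos <- GenomicRanges::start(pts)[sel]
        smp <- S4Vectors::mcols(pts)$sample[sel]
        len <- GenomeInfoDb::seqlengths(si)[[ct]]
        if (is.na(len)) len <- max(pos) + h
        # distinct-sample coverage: each sample contributes 0/1 per center
        covSum <- NULL
        for (s in unique(smp)) {
            r <- IRanges::reduce(IRanges::IRanges(
                pmax(pos[smp == s] - h, 1L), pmin(pos[smp == s] + h, len)))
            cv <- IRanges::coverage(r, width = len)
            covSum <- if (is.null(covSum)) cv else covSum + cv
        }
        hot <- IRanges::slice(covSum, lower = n, rangesOnly = TRUE)
        if (length(hot) == 0L) next
        centers <- unlist(lapply(seq_along(hot), function(i)
            seq(IRanges::start(hot)[i], IRanges::end(hot)[i])))
        # centers must themselves be analyzable
        maskCt <- mask[as.character(GenomicRanges::seqnames(mask)) == ct]
        inMask <- IRanges::overlapsAny(
            IRanges::IRanges(centers, width = 1L),
            IRanges::ranges(maskCt))
        centers <- centers[inMask]
        if (!length(centers)) next
        win <- IRanges::IRanges(pmax(centers - h, 1L),
                                pmin(centers + h, len))
        hits <- IRanges::findOverlaps(win, IRanges::IRanges(pos, width = 1L))
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        nSamples <- vapply(split(smp[sh], factor(qh, seq_along(win))),
                           function(x) length(unique(x)), integer(1L))
        nMut <- tabulate(qh, length(win))
        gr <- GenomicRanges::GRanges(ct, win, center = centers,
                                     nSamples = unname(nSamples),
                                     nMutations = nMut)
        out[[ct]] <- gr[gr$nSamples >= n]
    }
    if (!length(out)) {
        gr <- GenomicRanges::GRanges(seqinfo = si)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            center = integer(), nSamples = integer(),
            nMutations = integer())
        return(gr)
    }
    res <- suppressWarnings(do.call(c, unname(out)))
    GenomeInfoDb::seqlevels(res) <- GenomeInfoDb::seqlevels(si)
    GenomeInfoDb::seqinfo(res) <- si
    res[order(match(as.character(GenomicRanges::seqnames(res)),
                    GenomeInfoDb::seqlevels(si)), res$center)]
}

#' Per-sample window success probabilities
#'
#' The probability that a given sample carries at least one mutation in the
#' window, assuming independence across window positions:
#' \code{q_i = 1 - prod_j (1 - p_ij)}. Masked positions and positions
#' without a valid context contribute nothing to the product (they are
#' skipped), keeping the hypothesis count consistent with the P = 1 padding.
#'
#' @param field \linkS4class{ProbabilityField}.
#' @param window a length-1 \code{GRanges} (or anything coercible).
#' @param samples sample ids; defaults to the model's roster.
#' @return named numeric vector of per-sample success probabilities.
#' @export
windowSuccessProbs <- function(field, window,
                               samples = field@model@sampleCovariates$sample) {
    stopifnot(length(window) == 1L)
    ct <- as.character(GenomicRanges::seqnames(window))
    pos <- seq(GenomicRanges::start(window), GenomicRanges::end(window))
    keepMask <- IRanges::overlapsAny(
        GenomicRanges::GRanges(ct, IRanges::IRanges(pos, width = 1L)),
        field@mask)
    pos <- pos[keepMask]
    if (!length(pos))
        return(stats::setNames(numeric(length(samples)), samples))
    pe <- .position_eta(field@model, field@genome, field@tracks, ct, pos)
    eta <- pe$eta[pe$available]
    sEta <- .sample_eta(field@model, samples)
    q <- vapply(sEta, function(se) {
        p <- stats::plogis(eta + se)
        -expm1(sum(log1p(-p)))
    }, numeric(1L))
    stats::setNames(q, samples)
}

#' Exact Poisson-binomial tail probability
#'
#' \code{P(K >= k)} where K is the number of successes among independent
#' Bernoulli trials with success probabilities \code{q}. Computed by exact
#' dynamic-programming convolution of the probability mass function in
#' O(N^2); numerically stable in double precision for the cohort sizes this
#' test runs at (hundreds to a few thousand samples). \code{k = 0} returns
#' exactly 1.
#'
#' @param q success probabilities in [0, 1).
#' @param k observed count (0..N).
#' @return the tail probability, clipped into (1e-300, 1].
#' @export
poissonBinomialTail <- function(q, k) {
    N <- length(q)
    if (k < 0L || k != round(k)) .stop_config("k must be a whole number >= 0")
    if (k > N) .stop_config("k (", k, ") exceeds the number of trials (",
                            N, ")")
    if (k == 0L) return(1)
    q <- pmin(pmax(q, 0), 1 - 1e-16)
    f <- c(1, numeric(N))
    for (i in seq_len(N)) {
        qi <- q[i]
        fi <- f[seq_len(i)]
        f[seq_len(i)] <- fi * (1 - qi)
        f[2:(i + 1)] <- f[2:(i + 1)] + fi * qi
    }
    min(max(sum(f[(k + 1):(N + 1)]), 1e-300), 1)
}

#' Benjamini-Hochberg correction over a padded hypothesis set
#'
#' Adjusts the p-values of the evaluated windows as if the remaining
#' \code{mTotal - length(p)} never-evaluated nucleotides had been tested
#' with P = 1: identical to running textbook BH on the explicitly padded
#' vector, but without materializing billions of ones. In genome mode
#' \code{mTotal} is the number of analyzable nucleotides; in region mode the
#' number of masked nucleotides inside the regions of interest.
#'
#' @param p p-values of the evaluated windows.
#' @param mTotal total number of hypotheses (\code{>= length(p)}).
#' @return FDR (q-) values aligned with \code{p}, clipped to [0, 1].
#' @export
bhCorrect <- function(p, mTotal) {
    m <- length(p)
    if (mTotal < m)
        .stop_config("mTotal (", mTotal, ") < number of evaluated tests (",
                     m, ")")
    if (m == 0L) return(numeric())
    ord <- order(p)
    adj <- mTotal * p[ord] / seq_len(m)
    # padding entries all equal 1, so the step-up running minimum is capped
    # at 1 exactly as if they were appended
    adj <- rev(cummin(rev(pmin(adj, 1))))
    out <- numeric(m)
    out[ord] <- adj
    pmin(pmax(out, 0), 1)
}

## Shared scan core. probFun(contig, positions) must return a matrix
## [samples x positions] of per-position mutation probabilities (positions
## already mask-filtered by the caller through `posFilter`).
.scan_core <- function(cands, samples, probFun, posFilter, mTotal,
                       fdrThreshold, threads = 1L) {
    nW <- length(cands)
    if (nW == 0L)
        return(list(windows = cands, pvalue = numeric(),
                    fdr = numeric(), meanProb = numeric()))
    cts <- as.character(GenomicRanges::seqnames(cands))
    pvals <- numeric(nW); meanProb <- numeric(nW)
    scanContig <- function(ct) {
        idx <- which(cts == ct)
        lo <- GenomicRanges::start(cands)[idx]
        hi <- GenomicRanges::end(cands)[idx]
        pos <- unique(sort(unlist(lapply(seq_along(idx), function(i)
            seq(lo[i], hi[i])))))
        keep <- posFilter(ct, pos)
        pos <- pos[keep]
        P <- probFun(ct, pos)            # samples x positions
        P <- pmin(pmax(P, 0), 1 - 1e-12)
        L1M <- log1p(-P)
        res <- matrix(0, nrow = length(idx), ncol = 2L)
        for (i in seq_along(idx)) {
            j <- which(pos >= lo[i] & pos <= hi[i])
            k <- S4Vectors::mcols(cands)$nSamples[idx[i]]
            if (length(j) == 0L) {
                q <- numeric(nrow(P))
            } else if (length(j) == 1L) {
                q <- -expm1(L1M[, j])
            } else {
                q <- -expm1(rowSums(L1M[, j, drop = FALSE]))
            }
            res[i, 1L] <- poissonBinomialTail(q, k)
            res[i, 2L] <- mean(q)
        }
        res
    }
    ctList <- unique(cts)
    resList <- if (threads > 1L && .Platform$OS.type == "unix") {
        parallel::mclapply(ctList, scanContig, mc.cores = threads)
    } else {
        lapply(ctList, scanContig)
    }
    for (ii in seq_along(ctList)) {
        idx <- which(cts == ctList[ii])
        pvals[idx] <- resList[[ii]][, 1L]
        meanProb[idx] <- resList[[ii]][, 2L]
    }
    fdr <- bhCorrect(pvals, mTotal)
    list(windows = cands, pvalue = pvals, fdr = fdr, meanProb = meanProb)
}

## Merge overlapping significant windows that share at least one mutated
## position; the minimum-p window represents the merged hotspot.
.merge_calls <- function(sig, catalog, variantClass) {
    if (length(sig) <= 1L) return(sig)
    v <- variants(catalog)
    v <- GenomicRanges::resize(
        v[S4Vectors::mcols(v)$class == variantClass], 1L, fix = "start")
    ord <- order(as.character(GenomicRanges::seqnames(sig)),
                 GenomicRanges::start(sig))
    sig <- sig[ord]
    hits <- GenomicRanges::findOverlaps(sig, v)
    posOf <- split(GenomicRanges::start(v)[S4Vectors::subjectHits(hits)],
                   factor(S4Vectors::queryHits(hits), seq_along(sig)))
    cluster <- integer(length(sig)); cluster[1L] <- 1L
    curPos <- posOf[[1L]]
    curEnd <- GenomicRanges::end(sig)[1L]
    curCt <- as.character(GenomicRanges::seqnames(sig))[1L]
    for (i in seq_along(sig)[-1L]) {
        ct <- as.character(GenomicRanges::seqnames(sig))[i]
        joins <- ct == curCt &&
            GenomicRanges::start(sig)[i] <= curEnd &&
            length(intersect(posOf[[i]], curPos)) > 0L
        if (joins) {
            cluster[i] <- cluster[i - 1L]
            curPos <- union(curPos, posOf[[i]])
            curEnd <- max(curEnd, GenomicRanges::end(sig)[i])
        } else {
            cluster[i] <- cluster[i - 1L] + 1L
            curPos <- posOf[[i]]
            curEnd <- GenomicRanges::end(sig)[i]
            curCt <- ct
        }
    }
    merged <- lapply(split(seq_along(sig), cluster), function(ii) {
        sub <- sig[ii]
        rep <- sub[which.min(sub$pvalue)]
        out <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(rep),
            IRanges::IRanges(min(GenomicRanges::start(sub)),
                             max(GenomicRanges::end(sub))))
        smp <- S4Vectors::mcols(v)$sample[IRanges::overlapsAny(v, out) &
            as.character(GenomicRanges::seqnames(v)) ==
                as.character(GenomicRanges::seqnames(out))]
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(
            center = rep$center,
            nSamples = length(unique(smp)),
            nMutations = length(smp),
            meanProb = rep$meanProb,
            pvalue = rep$pvalue, fdr = rep$fdr)
        out
    })
    out <- suppressWarnings(do.call(c, unname(merged)))
    out[order(out$pvalue, as.character(GenomicRanges::seqnames(out)),
              GenomicRanges::start(out))]
}

#' Call mutation hotspots
#'
#' End-to-end scan against a fitted background model: candidate windows are
#' enumerated, per-sample window success probabilities computed from the
#' model, Poisson-binomial tail p-values evaluated at the observed number of
#' distinct mutated samples, and q-values obtained by Benjamini-Hochberg
#' over all analyzable nucleotides (genome mode) or all masked nucleotides
#' of the regions of interest (region mode). Overlapping significant windows
#' sharing a mutated position are merged into one reported hotspot (union
#' span; the minimum-p window is the representative).
#'
#' @param model \linkS4class{BackgroundModel}.
#' @param catalog \linkS4class{MutationCatalog}.
#' @param genome,tracks as at training time.
#' @param mask analyzable \code{GRanges}.
#' @param l,n window length and minimum distinct mutated samples.
#' @param fdrThreshold report hotspots with \code{fdr < fdrThreshold}.
#' @param mode \code{"genome"} or \code{"region"}.
#' @param regions \code{GRanges} of regions of interest (region mode).
#' @param merge merge overlapping significant windows (default TRUE).
#' @param threads number of worker processes for contig-block parallelism;
#'   affects runtime only, never results (windows are partitioned by contig
#'   and reassembled in a fixed order).
#' @return a \linkS4class{HotspotResults}.
#' @export
callHotspots <- function(model, catalog, genome, tracks, mask, l = 21L,
                         n = 2L, fdrThreshold = 0.05,
                         mode = c("genome", "region"), regions = NULL,
                         merge = TRUE, threads = 1L) {
    mode <- match.arg(mode)
    if (mode == "region" && is.null(regions))
        .stop_config("region mode requires a region set")
    scanMask <- if (mode == "region")
        GenomicRanges::reduce(GenomicRanges::intersect(mask, regions))
    else mask
    mTotal <- sum(as.numeric(GenomicRanges::width(scanMask)))
    if (mTotal == 0) .stop_data("empty scan mask")
    cands <- enumerateCandidates(catalog, scanMask, l = l, n = n,
                                 variantClass = model@variantClass)
    cmask <- contextMask(genome, scanMask)
    sc <- model@sampleCovariates
    sEta <- .sample_eta(model, sc$sample)
    probFun <- function(ct, pos) {
        pe <- .position_eta(model, genome, tracks, ct, pos)
        outer(sEta, pe$eta, function(a, b) stats::plogis(a + b))
    }
    posFilter <- function(ct, pos) {
        IRanges::overlapsAny(
            GenomicRanges::GRanges(ct, IRanges::IRanges(pos, width = 1L)),
            cmask)
    }
    sc_res <- .scan_core(cands, sc$sample, probFun, posFilter, mTotal,
                         fdrThreshold, threads)
    windows <- sc_res$windows
    if (length(windows)) {
        S4Vectors::mcols(windows)$meanProb <- sc_res$meanProb
        S4Vectors::mcols(windows)$pvalue <- sc_res$pvalue
        S4Vectors::mcols(windows)$fdr <- sc_res$fdr
        windows <- windows[order(windows$pvalue,
                                 as.character(GenomicRanges::seqnames(windows)),
                                 GenomicRanges::start(windows))]
    } else {
        S4Vectors::mcols(windows)$meanProb <- numeric()
        S4Vectors::mcols(windows)$pvalue <- numeric()
        S4Vectors::mcols(windows)$fdr <- numeric()
    }
    sig <- windows[windows$fdr < fdrThreshold]
    hot <- if (merge) .merge_calls(sig, catalog, model@variantClass) else sig
    methods::new("HotspotResults", windows = windows, hotspots = hot,
                 mTotal = mTotal,
                 params = list(l = l, n = n, fdrThreshold = fdrThreshold,
                               mode = mode, merge = merge,
                               variantClass = model@variantClass))
}
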