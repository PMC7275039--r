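# Feature engine: analyzable mask, sequence contexts, homopolymer flag,
# 100-kb local mutation rate, and per-sample mutation burden.

#' Build the analyzable-position mask
#'
#' The analyzable set is the whole genome minus the union of the supplied
#' exclusion sets (poor-mappability regions, blacklist/immunoglobulin loci,
#' optionally coding regions for a non-coding scan) minus runs of N in the
#' reference. Masks on contigs absent from the genome are ignored with a
#' warning.
#'
#' @param genome \code{DNAStringSet}.
#' @param mappability,blacklist,coding optional exclusion \code{GRanges}
#'   (regions to remove).
#' @return a reduced \code{GRanges} of analyzable positions, carrying the
#'   genome's \code{seqinfo}.
#' @importFrom GenomicRanges GRanges reduce setdiff sort width
#' @importFrom Biostrings vmatchPattern
#' @export
buildMask <- function(genome, mappability = NULL, blacklist = NULL,
                      coding = NULL) {
    si <- .genome_seqinfo(genome)
    full <- GenomicRanges::GRanges(names(genome),
        IRanges::IRanges(1L, Biostrings::width(genome)), seqinfo = si)
    excl <- GenomicRanges::GRanges(seqinfo = si)
    for (m in list(mappability, blacklist, coding)) {
        if (is.null(m) || length(m) == 0L) next
        known <- as.character(GenomicRanges::seqnames(m)) %in% names(genome)
        if (!all(known)) {
            warning(sum(!known), " mask interval(s) on contigs absent from ",
                    "the genome ignored")
            m <- m[known]
        }
        GenomeInfoDb::seqlevels(m) <- GenomeInfoDb::seqlevels(si)
        GenomeInfoDb::seqinfo(m) <- si
        excl <- c(excl, m)
    }
    # N runs are never analyzable
    nhits <- Biostrings::vmatchPattern("N", genome)
    nruns <- GenomicRanges::GRanges(
        rep(names(genome), lengths(nhits)),
        unlist(IRanges::IRangesList(nhits), use.names = FALSE), seqinfo = si)
    excl <- GenomicRanges::reduce(c(excl, nruns))
    GenomicRanges::sort(GenomicRanges::setdiff(full, excl))
}

## Mask positions where a full, N-free 5-mer context exists: the mask shrunk
## away from contig edges and from any position within 2 bp of an N.
contextMask <- function(genome, mask) {
    si <- .genome_seqinfo(genome)
    len <- Biostrings::width(genome)
    keep <- len >= 5L
    inner <- GenomicRanges::GRanges(names(genome)[keep],
        IRanges::IRanges(3L, len[keep] - 2L), seqinfo = si)
    nhits <- Biostrings::vmatchPattern("N", genome)
    nruns <- GenomicRanges::GRanges(
        rep(names(genome), lengths(nhits)),
        unlist(IRanges::IRangesList(nhits), use.names = FALSE), seqinfo = si)
    if (length(nruns))
        nruns <- GenomicRanges::trim(GenomicRanges::resize(
            nruns, GenomicRanges::width(nruns) + 4L, fix = "center"))
    out <- GenomicRanges::intersect(mask, inner)
    GenomicRanges::sort(GenomicRanges::setdiff(out, nruns))
}

#' Strand-collapsed sequence context at positions
#'
#' Extracts the 5-mer centered at each position and reports it on the
#' pyrimidine strand of the center base (positions with a purine center are
#' reverse-complemented), the usual mutation-signature convention. The
#' trinucleotide is the center slice of the pentanucleotide; 1-bp and 2-bp
#' flanks are read off the collapsed 5-mer. Positions whose 5-mer is
#' truncated by a contig edge or contains N are flagged unavailable.
#'
#' @param genome \code{DNAStringSet}.
#' @param contig contig name (scalar).
#' @param positions 1-based positions on \code{contig}.
#' @return data.frame with columns \code{available}, \code{centerClass}
#'   (\code{"AT"} or \code{"CG"}), \code{penta}, \code{tri}, \code{left1},
#'   \code{right1}, \code{left2}, \code{right2} (NA where unavailable).
#' @importFrom Biostrings reverseComplement
#' @export
sequenceContextAt <- function(genome, contig, positions) {
    if (!contig %in% names(genome)) .stop_data("unknown contig: ", contig)
    s <- as.character(genome[[contig]])
    len <- nchar(s)
    ok <- positions >= 3L & positions <= len - 2L
    five <- rep(NA_character_, length(positions))
    if (any(ok)) {
        five[ok] <- substring(s, positions[ok] - 2L, positions[ok] + 2L)
        ok[ok] <- !grepl("N", five[ok], fixed = TRUE)
        five[!ok] <- NA_character_
    }
    center <- substr(five, 3L, 3L)
    pur <- !is.na(center) & center %in% c("A", "G")
    if (any(pur))
        five[pur] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(five[pur])))
    data.frame(
        available = ok,
        centerClass = ifelse(is.na(center), NA,
                             ifelse(center %in% c("A", "T"), "AT", "CG")),
        penta = five,
        tri = substr(five, 2L, 4L),
        left1 = substr(five, 2L, 2L),
        right1 = substr(five, 4L, 4L),
        left2 = substr(five, 1L, 2L),
        right2 = substr(five, 4L, 5L),
        stringsAsFactors = FALSE)
}

#' Homopolymer context of an indel site
#'
#' Returns 1 when a mononucleotide run longer than 5 bp overlaps any base of
#' the indel's reference span, the indel-model analogue of the SNV sequence
#' context (long A/T or C/G runs are a known source of indel-calling
#' artifacts).
#'
#' @param genome \code{DNAStringSet}.
#' @param contig contig name (scalar).
#' @param start,end 1-based reference span of the indel (default: a point).
#' @return integer 0/1 vector, one per (start, end) pair.
#' @export
indelHomopolymerFeature <- function(genome, contig, start, end = start) {
    if (!contig %in% names(genome)) .stop_data("unknown contig: ", contig)
    s <- as.character(genome[[contig]])
    len <- nchar(s)
    end <- rep_len(end, length(start))
    vapply(seq_along(start), function(i) {
        lo <- max(1L, start[i] - 6L); hi <- min(len, end[i] + 6L)
        r <- rle(strsplit(substr(s, lo, hi), "")[[1L]])
        runEnd <- lo - 1L + cumsum(r$lengths)
        runStart <- runEnd - r$lengths + 1L
        long <- r$lengths > 5L & r$values %in% c("A", "C", "G", "T")
        # a run truncated by the probe window cannot be called long or short
        # reliably, so extend the probe generously (6 bp) beyond the span
        hit <- long & runStart <= end[i] & runEnd >= start[i]
        as.integer(any(hit))
    }, integer(1L))
}

#' Local mutation rate in non-overlapping genomic bins
#'
#' Tiles each contig with \code{binWidth} bins (the last bin truncated at the
#' contig end) and computes the per-bin rate
#' count / (effective bin width x number of cohort samples), in mutations per
#' base per sample. Used as a structural covariate to absorb regional rate
#' variation that the other features do not explain.
#'
#' @param catalog \linkS4class{MutationCatalog}.
#' @param genome \code{DNAStringSet}.
#' @param binWidth bin width in bp (default 100 kb).
#' @param variantClass \code{"SNV"} or \code{"indel"}.
#' @return a continuous \linkS4class{GenomicTrack} named
#'   \code{"local_rate"} whose intervals are the bins and whose score is the
#'   rate.
#' @importFrom GenomicRanges tileGenome countOverlaps resize
#' @export
computeLocalRate <- function(catalog, genome, binWidth = 100000L,
                             variantClass = c("SNV", "indel")) {
    variantClass <- match.arg(variantClass)
    v <- variants(catalog)
    v <- v[S4Vectors::mcols(v)$class == variantClass]
    si <- .genome_seqinfo(genome)
    lens <- Biostrings::width(genome)
    bins <- suppressWarnings(do.call(c, lapply(seq_along(genome), function(i) {
        starts <- seq(1L, lens[i], by = binWidth)
        GenomicRanges::GRanges(names(genome)[i],
            IRanges::IRanges(starts, pmin(starts + binWidth - 1L, lens[i])),
            seqinfo = si)
    })))
    pts <- GenomicRanges::resize(v, 1L, fix = "start")
    GenomeInfoDb::seqlevels(pts) <- GenomeInfoDb::seqlevels(si)
    n <- GenomicRanges::countOverlaps(bins, pts)
    nSamples <- max(length(sampleIDs(catalog)), 1L)
    S4Vectors::mcols(bins)$score <-
        n / (GenomicRanges::width(bins) * nSamples)
    methods::new("GenomicTrack", name = "local_rate", kind = "continuous",
                 intervals = bins, default = 0)
}

#' Per-sample mutation burden
#'
#' Counts each cohort sample's records of the given variant class; every
#' sample in the roster is present (0 when it has none of that class).
#'
#' @param catalog \linkS4class{MutationCatalog}.
#' @param variantClass \code{"SNV"} or \code{"indel"}.
#' @return named integer vector, sample -> count.
#' @export
sampleBurden <- function(catalog, variantClass = c("SNV", "indel")) {
    variantClass <- match.arg(variantClass)
    v <- variants(catalog)
    sm <- S4Vectors::mcols(v)$sample[S4Vectors::mcols(v)$class == variantClass]
    out <- table(factor(sm, levels = sampleIDs(catalog)))
    stats::setNames(as.integer(out), names(out))
}
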