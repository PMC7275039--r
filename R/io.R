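# Readers and writers for on-disk artifacts. All coordinate-convention
# conversions between BED (0-based half-open) and the internal GRanges
# representation (1-based closed) happen here and nowhere else.

#' Read a reference genome from FASTA
#'
#' Loads all contigs, uppercases the sequence, and checks the alphabet is
#' restricted to A/C/G/T/N. Contig names are taken as the first whitespace
#' token of each header and must be unique.
#'
#' @param path path to a (optionally gzipped) FASTA file.
#' @return a \code{DNAStringSet} with \code{names()} the contig names.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTN"), fa)
#' g <- readGenome(fa)
#' width(g)
#' @importFrom Biostrings readDNAStringSet DNAStringSet letterFrequency width
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) .stop_data("genome file not found: ", path)
    g <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) .stop_data("malformed FASTA '", path,
                                                 "': ", conditionMessage(e)))
    if (length(g) == 0L) .stop_data("no sequences found in ", path)
    names(g) <- vapply(strsplit(names(g), "\\s+"), `[`, "", 1L)
    if (anyDuplicated(names(g)))
        .stop_data("duplicate contig names in ", path)
    g <- Biostrings::DNAStringSet(toupper(as.character(g)))
    bad <- Biostrings::letterFrequency(g, "ACGTN")[, 1L] != Biostrings::width(g)
    if (any(bad))
        .stop_data("non-ACGTN characters in contig(s): ",
                   paste(names(g)[bad], collapse = ", "))
    g
}

.genome_seqinfo <- function(genome) {
    GenomeInfoDb::Seqinfo(seqnames = names(genome),
                          seqlengths = Biostrings::width(genome))
}

#' Read a cohort somatic mutation catalog
#'
#' Accepts either a tab-separated table with columns \code{chrom}, \code{pos}
#' (1-based), \code{ref}, \code{alt}, \code{sample}, or a minimal VCF (the
#' sample identifier then comes from \code{sampleName}, defaulting to the file
#' base name). Records are classified as SNV (single-base substitution) or
#' indel (ref/alt length differ); equal-length multi-base substitutions are
#' dropped. Records on contigs absent from the genome, records whose reference
#' allele does not match the genome, and duplicate (contig, position, alt,
#' sample) records are dropped with logged counts, mirroring the expectation
#' that inputs were prefiltered upstream.
#'
#' @param path mutation file (TSV or VCF, optionally gzipped).
#' @param genome \code{DNAStringSet} reference genome.
#' @param format \code{"auto"} (by extension/header), \code{"tsv"} or
#'   \code{"vcf"}.
#' @param sampleName sample identifier for single-sample VCF input.
#' @param verbose log dropped-record counts via \code{message()}.
#' @return a \linkS4class{MutationCatalog}; dropped-record counts are stored
#'   in \code{metadata(variants(x))}.
#' @importFrom utils read.delim
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @export
readMutations <- function(path, genome, format = c("auto", "tsv", "vcf"),
                          sampleName = NULL, verbose = TRUE) {
    format <- match.arg(format)
    if (!file.exists(path)) .stop_data("mutation file not found: ", path)
    if (format == "auto") {
        first <- readLines(path, n = 1L)
        format <- if (grepl("^##fileformat=VCF", first) ||
                      grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    }
    if (format == "vcf") {
        ln <- readLines(path)
        ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
        if (length(ln) == 0L) {
            df <- data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             sample = character())
        } else {
            fld <- strsplit(ln, "\t", fixed = TRUE)
            if (any(lengths(fld) < 5L))
                .stop_data("VCF records with fewer than 5 fields in ", path)
            df <- data.frame(
                chrom = vapply(fld, `[`, "", 1L),
                pos = as.integer(vapply(fld, `[`, "", 2L)),
                ref = vapply(fld, `[`, "", 4L),
                alt = vapply(fld, `[`, "", 5L),
                sample = sampleName %||% sub("\\.vcf(\\.gz)?$", "",
                                             basename(path)))
        }
    } else {
        # colClasses keeps T/F alleles from being sniffed as logicals
        df <- utils::read.delim(path, stringsAsFactors = FALSE,
                                check.names = FALSE,
                                colClasses = "character")
        names(df) <- tolower(names(df))
        need <- c("chrom", "pos", "ref", "alt", "sample")
        if (!all(need %in% names(df)))
            .stop_data("mutation table is missing required column(s): ",
                       paste(setdiff(need, names(df)), collapse = ", "))
        df <- df[need]
        df$pos <- as.integer(df$pos)
    }
    df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
    df$sample <- as.character(df$sample)

    n0 <- nrow(df)
    dropped <- c(unknown_contig = 0L, ref_mismatch = 0L, duplicate = 0L,
                 unclassifiable = 0L)

    keep <- df$chrom %in% names(genome)
    dropped[["unknown_contig"]] <- sum(!keep)
    df <- df[keep, , drop = FALSE]
    # out-of-range positions can never match the reference
    if (nrow(df)) {
        len <- Biostrings::width(genome)[match(df$chrom, names(genome))]
        inrange <- df$pos >= 1L & (df$pos + nchar(df$ref) - 1L) <= len
        dropped[["ref_mismatch"]] <- dropped[["ref_mismatch"]] + sum(!inrange)
        df <- df[inrange, , drop = FALSE]
    }
    if (nrow(df)) {
        ok <- logical(nrow(df))
        for (ct in unique(df$chrom)) {
            i <- which(df$chrom == ct)
            s <- as.character(genome[[ct]])
            ok[i] <- substring(s, df$pos[i],
                               df$pos[i] + nchar(df$ref[i]) - 1L) == df$ref[i]
        }
        dropped[["ref_mismatch"]] <- dropped[["ref_mismatch"]] + sum(!ok)
        df <- df[ok, , drop = FALSE]
    }
    cls <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L & df$ref != df$alt,
                  "SNV",
                  ifelse(nchar(df$ref) != nchar(df$alt), "indel", NA))
    dropped[["unclassifiable"]] <- sum(is.na(cls))
    df <- df[!is.na(cls), , drop = FALSE]
    cls <- cls[!is.na(cls)]

    key <- paste(df$chrom, df$pos, df$alt, df$sample)
    dup <- duplicated(key)
    dropped[["duplicate"]] <- sum(dup)
    df <- df[!dup, , drop = FALSE]
    cls <- cls[!dup]

    if (any(dropped > 0L))
        .log_msg("dropped records: ",
                 paste(names(dropped), dropped, sep = "=", collapse = ", "),
                 " (", n0, " read, ", nrow(df), " kept)", verbose = verbose)

    ord <- order(match(df$chrom, names(genome)), df$pos, df$sample, df$alt)
    df <- df[ord, , drop = FALSE]; cls <- cls[ord]
    gr <- GenomicRanges::GRanges(
        df$chrom,
        IRanges::IRanges(df$pos, width = pmax(nchar(df$ref), 1L)),
        sample = df$sample, ref = df$ref, alt = df$alt, class = cls,
        seqinfo = .genome_seqinfo(genome))
    S4Vectors::metadata(gr) <- list(dropped = dropped, n_read = n0)
    methods::new("MutationCatalog", variants = gr,
                 samples = sort(unique(df$sample)))
}

#' Read a BED region set
#'
#' Parses a BED3+ file (0-based half-open) into a normalized region set:
#' sorted, merged and overlap-free. Zero- or negative-width records are
#' rejected with a warning.
#'
#' @param path BED file.
#' @param label optional label stored in \code{metadata()}.
#' @return a reduced \code{GRanges} (1-based closed, the usual in-memory
#'   convention).
#' @export
readRegions <- function(path, label = basename(path)) {
    if (!file.exists(path)) .stop_data("region file not found: ", path)
    gr <- .read_bedlike(path)
    out <- GenomicRanges::reduce(GenomicRanges::sort(gr))
    S4Vectors::metadata(out) <- list(label = label)
    out
}

## Minimal BED/bedGraph line parser. Hand-parsed (rather than delegated)
## so that degenerate records (start >= end) are rejected with a warning
## instead of aborting the read, per the region-set contract.
.read_bedlike <- function(path, scored = FALSE) {
    ln <- readLines(path)
    ln <- ln[nzchar(ln) & !grepl("^(#|track|browser)", ln)]
    if (length(ln) == 0L)
        return(GenomicRanges::GRanges())
    fld <- strsplit(ln, "[\t ]+")
    need <- if (scored) 4L else 3L
    if (any(lengths(fld) < need))
        .stop_data("records with fewer than ", need, " fields in ", path)
    chrom <- vapply(fld, `[`, "", 1L)
    start0 <- as.numeric(vapply(fld, `[`, "", 2L))
    end0 <- as.numeric(vapply(fld, `[`, "", 3L))
    if (anyNA(start0) || anyNA(end0))
        .stop_data("non-numeric coordinates in ", path)
    bad <- end0 <= start0
    if (any(bad))
        warning(sum(bad), " record(s) with start >= end rejected in ", path)
    gr <- GenomicRanges::GRanges(chrom[!bad],
            IRanges::IRanges(start = start0[!bad] + 1, end = end0[!bad]))
    if (scored)
        S4Vectors::mcols(gr)$score <-
            as.numeric(vapply(fld, `[`, "", 4L))[!bad]
    gr
}

#' Read a genomic feature track
#'
#' Binary tracks come from BED (membership = 1 inside intervals, 0 outside);
#' continuous tracks from bedGraph (piecewise-constant values with a
#' configurable default at uncovered positions). Overlapping bedGraph
#' intervals with conflicting values are an error.
#'
#' @param path BED (binary) or bedGraph (continuous) file.
#' @param kind \code{"binary"} or \code{"continuous"}.
#' @param name feature name (defaults to the file base name without
#'   extension).
#' @param default value at uncovered positions for continuous tracks.
#' @return a \linkS4class{GenomicTrack}.
#' @export
readTrack <- function(path, kind = c("binary", "continuous"),
                      name = sub("\\.[^.]*$", "", basename(path)),
                      default = 0) {
    kind <- match.arg(kind)
    if (!file.exists(path)) .stop_data("track file not found: ", path)
    if (kind == "binary") {
        gr <- GenomicRanges::reduce(GenomicRanges::sort(.read_bedlike(path)))
        return(methods::new("GenomicTrack", name = name, kind = "binary",
                            intervals = gr, default = 0))
    }
    gr <- GenomicRanges::sort(.read_bedlike(path, scored = TRUE))
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits)) {
        v1 <- S4Vectors::mcols(gr)$score[S4Vectors::queryHits(hits)]
        v2 <- S4Vectors::mcols(gr)$score[S4Vectors::subjectHits(hits)]
        if (any(v1 != v2))
            .stop_data("overlapping bedGraph intervals with conflicting ",
                       "values in ", path)
        gr <- GenomicRanges::sort(unique(gr))
    }
    methods::new("GenomicTrack", name = name, kind = "continuous",
                 intervals = gr, default = as.numeric(default))
}

#' Query a track at genomic positions
#'
#' @param track a \linkS4class{GenomicTrack}.
#' @param contig contig name (scalar, recycled) or vector.
#' @param positions 1-based positions.
#' @return numeric vector: 0/1 for binary tracks, the covering interval's
#'   value (or the default) for continuous tracks.
#' @export
trackValues <- function(track, contig, positions) {
    stopifnot(methods::is(track, "GenomicTrack"))
    pts <- GenomicRanges::GRanges(rep_len(contig, length(positions)),
                                  IRanges::IRanges(positions, width = 1L))
    # queries on contigs the track never saw are legitimate (-> default)
    if (track@kind == "binary") {
        suppressWarnings(
            as.numeric(IRanges::overlapsAny(pts, track@intervals)))
    } else {
        out <- rep_len(track@default, length(positions))
        hit <- suppressWarnings(GenomicRanges::findOverlaps(
            pts, track@intervals, select = "first"))
        got <- !is.na(hit)
        out[got] <- S4Vectors::mcols(track@intervals)$score[hit[got]]
        out
    }
}

#' Write (and read back) a hotspot table
#'
#' Tab-separated, one row per call, sorted by p-value with coordinate
#' tie-breaking. Columns: \code{chrom}, \code{start} (0-based), \code{end},
#' \code{length}, \code{n_mutated_samples}, \code{n_mutations},
#' \code{pvalue}, \code{fdr}, \code{mean_background_prob}.
#'
#' @param calls a \linkS4class{HotspotResults} or a \code{GRanges} carrying
#'   mcols \code{nSamples}, \code{nMutations}, \code{pvalue}, \code{fdr},
#'   \code{meanProb}.
#' @param path output file.
#' @return (invisibly) the path written.
#' @importFrom utils write.table
#' @export
writeHotspots <- function(calls, path) {
    gr <- if (methods::is(calls, "HotspotResults")) hotspots(calls) else calls
    mc <- S4Vectors::mcols(gr)
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        length = GenomicRanges::width(gr),
        n_mutated_samples = mc$nSamples,
        n_mutations = mc$nMutations,
        pvalue = mc$pvalue,
        fdr = mc$fdr,
        mean_background_prob = mc$meanProb,
        stringsAsFactors = FALSE)
    df <- df[order(df$pvalue, df$chrom, df$start), , drop = FALSE]
    for (col in c("pvalue", "fdr", "mean_background_prob"))
        df[[col]] <- sprintf("%.10g", df[[col]])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeHotspots
#' @export
readHotspots <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$start + 1L, df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        nSamples = df$n_mutated_samples, nMutations = df$n_mutations,
        pvalue = df$pvalue, fdr = df$fdr, meanProb = df$mean_background_prob)
    gr
}
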