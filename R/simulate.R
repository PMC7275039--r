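# Fully in-silico cohort generator: random genome, covariate tracks, and
# mutations drawn per (sample, position) from the same logistic model family
# the background fit assumes, with optional spiked hotspot windows.

#' Simulation configuration
#'
#' Defaults describe a desk-scale but realistic whole-genome cohort: a 1-Mb
#' genome, 30 tumors, a background rate of 5 mutations per megabase per
#' tumor (mid-range for adult solid cancers), log-normal inter-tumor burden
#' variation, one binary epigenetic overlay covering 20\% of the genome and
#' one smooth continuous profile standing in for replication timing.
#'
#' @param genomeLength total genome length in bp.
#' @param nContigs number of equally sized contigs.
#' @param gc GC fraction of the random genome.
#' @param nSamples cohort size.
#' @param baseRate background per-base per-sample mutation probability at
#'   covariate baseline (intercept = \code{qlogis(baseRate)}).
#' @param burdenSD standard deviation of per-sample log-odds shifts
#'   (log-normal burden heterogeneity).
#' @param binaryTracks named list; each element
#'   \code{list(coverage = , beta = )} describes one binary overlay: genome
#'   fraction covered and its true log-odds coefficient.
#' @param continuousTracks named list; each element \code{list(period = ,
#'   amplitude = , noiseSD = , beta = )} describes one smooth profile
#'   (sinusoid over the contig plus bin noise, piecewise constant in
#'   \code{binWidth} bins).
#' @param trackBinWidth bin width of continuous profiles, bp.
#' @param spikes \code{NULL}, or a data.frame with columns \code{contig},
#'   \code{start}, \code{end}, \code{successProb}: windows where each sample
#'   independently acquires a mutation with the given probability,
#'   overriding the background model.
#' @param indelRate per-base per-sample probability of a small deletion
#'   (0 disables indel simulation).
#' @return a validated config list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(genomeLength = 1000000L, nContigs = 1L,
                             gc = 0.41, nSamples = 30L, baseRate = 5e-6,
                             burdenSD = 0.4,
                             binaryTracks = list(
                                 peaks = list(coverage = 0.2, beta = 0.7)),
                             continuousTracks = list(
                                 reptime = list(period = 500000, amplitude = 1,
                                                noiseSD = 0.1, beta = 0.3)),
                             trackBinWidth = 1000L,
                             spikes = NULL, indelRate = 0) {
    if (genomeLength < 1000L) .stop_config("genomeLength must be >= 1000")
    if (baseRate <= 0 || baseRate >= 1)
        .stop_config("baseRate must be in (0, 1)")
    if (!is.null(spikes) &&
        !all(c("contig", "start", "end", "successProb") %in% names(spikes)))
        .stop_config("spikes needs columns contig, start, end, successProb")
    structure(list(genomeLength = as.integer(genomeLength),
                   nContigs = as.integer(nContigs), gc = gc,
                   nSamples = as.integer(nSamples), baseRate = baseRate,
                   burdenSD = burdenSD, binaryTracks = binaryTracks,
                   continuousTracks = continuousTracks,
                   trackBinWidth = as.integer(trackBinWidth),
                   spikes = spikes, indelRate = indelRate),
              class = "SimulationConfig")
}

#' Generate a random reference genome
#'
#' I.i.d. bases at the requested GC content, split over equally sized
#' contigs named \code{chr1..chrN}.
#'
#' @param length total genome length (>= 1000 bp).
#' @param nContigs number of contigs.
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @return a \code{DNAStringSet}.
#' @export
simulateGenome <- function(length, nContigs = 1L, gc = 0.4, seed = NULL) {
    if (length < 1000L) .stop_config("genome length must be >= 1000")
    lens <- diff(round(seq(0, length, length.out = nContigs + 1L)))
    withSeed(seed, {
        seqs <- vapply(lens, function(L)
            paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                         prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                  (1 - gc) / 2)),
                  collapse = ""), "")
        g <- Biostrings::DNAStringSet(seqs)
        names(g) <- paste0("chr", seq_len(nContigs))
        g
    })
}

#' Generate covariate tracks
#'
#' Binary overlays are unions of 1-kb intervals placed uniformly until the
#' configured genome fraction is covered; continuous profiles are
#' piecewise-constant sinusoids plus Gaussian bin noise, a stand-in for
#' replication timing.
#'
#' @param genome \code{DNAStringSet}.
#' @param config \code{\link{simulationConfig}} list.
#' @param seed RNG seed.
#' @return named list of \linkS4class{GenomicTrack}.
#' @export
simulateTracks <- function(genome, config, seed = NULL) {
    si <- .genome_seqinfo(genome)
    lens <- Biostrings::width(genome)
    total <- sum(as.numeric(lens))
    withSeed(seed, {
        tracks <- list()
        for (nm in names(config$binaryTracks)) {
            bt <- config$binaryTracks[[nm]]
            gr <- GenomicRanges::GRanges(seqinfo = si)
            target <- bt$coverage * total
            covered <- 0
            Lint <- 1000L
            while (covered < target && bt$coverage > 0) {
                k <- max(ceiling((target - covered) / Lint), 1L)
                ct <- sample(names(genome), k, replace = TRUE,
                             prob = lens / total)
                st <- vapply(ct, function(cc)
                    sample.int(max(lens[[match(cc, names(genome))]] - Lint,
                                   1L), 1L), integer(1L), USE.NAMES = FALSE)
                gr <- GenomicRanges::reduce(c(gr, GenomicRanges::GRanges(
                    ct, IRanges::IRanges(st, width = Lint), seqinfo = si)))
                covered <- sum(as.numeric(GenomicRanges::width(gr)))
            }
            tracks[[nm]] <- methods::new("GenomicTrack", name = nm,
                                         kind = "binary", intervals = gr,
                                         default = 0)
        }
        for (nm in names(config$continuousTracks)) {
            ctk <- config$continuousTracks[[nm]]
            pieces <- list()
            for (i in seq_along(genome)) {
                L <- lens[i]
                starts <- seq(1L, L, by = config$trackBinWidth)
                ends <- pmin(starts + config$trackBinWidth - 1L, L)
                mid <- (starts + ends) / 2
                val <- ctk$amplitude * sin(2 * pi * mid / ctk$period) +
                    stats::rnorm(length(mid), 0, ctk$noiseSD)
                pieces[[i]] <- GenomicRanges::GRanges(
                    names(genome)[i], IRanges::IRanges(starts, ends),
                    score = val, seqinfo = si)
            }
            tracks[[nm]] <- methods::new("GenomicTrack", name = nm,
                kind = "continuous",
                intervals = suppressWarnings(do.call(c, pieces)),
                default = 0)
        }
        tracks
    })
}

## Full-length per-base value vector of a track on one contig.
.track_profile <- function(track, ct, L) {
    iv <- track@intervals
    sel <- as.character(GenomicRanges::seqnames(iv)) == ct
    st <- pmax(GenomicRanges::start(iv)[sel], 1L)
    en <- pmin(GenomicRanges::end(iv)[sel], L)
    v <- rep(if (track@kind == "binary") 0 else track@default, L)
    val <- if (track@kind == "binary") rep(1, sum(sel))
           else S4Vectors::mcols(iv)$score[sel]
    for (i in seq_along(st))
        if (st[i] <= en[i]) v[st[i]:en[i]] <- val[i]
    v
}

## True positional log-odds for one contig (intercept + track effects).
.true_eta <- function(genome, tracks, config, ct) {
    L <- Biostrings::width(genome)[[match(ct, names(genome))]]
    eta <- rep(stats::qlogis(config$baseRate), L)
    for (nm in names(config$binaryTracks))
        eta <- eta + config$binaryTracks[[nm]]$beta *
            .track_profile(tracks[[nm]], ct, L)
    for (nm in names(config$continuousTracks))
        eta <- eta + config$continuousTracks[[nm]]$beta *
            .track_profile(tracks[[nm]], ct, L)
    eta
}

#' Simulate a cohort mutation catalog
#'
#' Draws one Bernoulli trial per (sample, position) with
#' \code{p = plogis(intercept + beta . x(position) + burdenShift_sample)} --
#' the same model family the background fit assumes, so parameter recovery
#' is directly testable. Spiked windows override the background: each sample
#' acquires a mutation at a uniform position inside the window with the
#' configured success probability. Alt alleles are uniform over the three
#' non-reference bases. When \code{indelRate > 0}, 1-bp deletions are
#' additionally placed (uniformly, enriched nowhere) to exercise the
#' SNV/indel split.
#'
#' @param genome \code{DNAStringSet}.
#' @param tracks named track list from \code{\link{simulateTracks}}.
#' @param config \code{\link{simulationConfig}} list.
#' @param seed RNG seed.
#' @return list with \code{catalog} (\linkS4class{MutationCatalog}) and
#'   \code{truth} (\linkS4class{TruthSet}).
#' @export
simulateCatalog <- function(genome, tracks, config, seed = NULL) {
    si <- .genome_seqinfo(genome)
    samples <- sprintf("S%02d", seq_len(config$nSamples))
    OTHER <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
    withSeed(seed, {
        shift <- stats::setNames(stats::rnorm(config$nSamples, 0,
                                              config$burdenSD), samples)
        rec <- list()
        maxP <- 0
        for (ct in names(genome)) {
            eta <- .true_eta(genome, tracks, config, ct)
            s_chr <- as.character(genome[[ct]])
            notN <- charToRaw(s_chr) != charToRaw("N")
            L <- nchar(s_chr)
            for (s in samples) {
                p <- stats::plogis(eta + shift[[s]])
                maxP <- max(maxP, max(p))
                hit <- which(notN & stats::runif(L) < p)
                if (length(hit)) {
                    ref <- substring(s_chr, hit, hit)
                    alt <- vapply(ref, function(r)
                        sample(OTHER[[r]], 1L), "", USE.NAMES = FALSE)
                    rec[[length(rec) + 1L]] <- data.frame(
                        contig = ct, pos = hit, ref = ref, alt = alt,
                        sample = s, class = "SNV",
                        stringsAsFactors = FALSE)
                }
                if (config$indelRate > 0) {
                    ih <- which(notN & stats::runif(L) < config$indelRate)
                    ih <- ih[ih < L]
                    nxt <- substring(s_chr, ih + 1L, ih + 1L)
                    ih <- ih[nxt != "N"]; nxt <- nxt[nxt != "N"]
                    if (length(ih))
                        rec[[length(rec) + 1L]] <- data.frame(
                            contig = ct, pos = ih,
                            ref = paste0(substring(s_chr, ih, ih), nxt),
                            alt = substring(s_chr, ih, ih), sample = s,
                            class = "indel", stringsAsFactors = FALSE)
                }
            }
        }
        if (maxP > 0.5)
            warning("background mutation probability exceeds 0.5 outside ",
                    "spikes; unrealistic regime", call. = FALSE)
        spikesGR <- GenomicRanges::GRanges(seqinfo = si)
        if (!is.null(config$spikes)) {
            sp <- config$spikes
            spikesGR <- GenomicRanges::GRanges(sp$contig,
                IRanges::IRanges(sp$start, sp$end),
                successProb = sp$successProb, seqinfo = si)
            for (i in seq_len(nrow(sp))) {
                s_chr <- as.character(genome[[sp$contig[i]]])
                for (s in samples) {
                    if (stats::runif(1L) < sp$successProb[i]) {
                        cand <- seq(sp$start[i], sp$end[i])
                        cand <- cand[substring(s_chr, cand, cand) != "N"]
                        if (!length(cand)) next
                        ps <- if (length(cand) == 1L) cand
                              else sample(cand, 1L)
                        ref <- substring(s_chr, ps, ps)
                        rec[[length(rec) + 1L]] <- data.frame(
                            contig = sp$contig[i], pos = ps, ref = ref,
                            alt = sample(OTHER[[ref]], 1L), sample = s,
                            class = "SNV", stringsAsFactors = FALSE)
                    }
                }
            }
        }
        df <- if (length(rec)) do.call(rbind, rec)
              else data.frame(contig = character(), pos = integer(),
                              ref = character(), alt = character(),
                              sample = character(), class = character())
        key <- paste(df$contig, df$pos, df$alt, df$sample)
        df <- df[!duplicated(key), , drop = FALSE]
        ord <- order(match(df$contig, names(genome)), df$pos, df$sample)
        df <- df[ord, , drop = FALSE]
        gr <- GenomicRanges::GRanges(df$contig,
            IRanges::IRanges(df$pos, width = pmax(nchar(df$ref), 1L)),
            sample = df$sample, ref = df$ref, alt = df$alt,
            class = df$class, seqinfo = si)
        catalog <- methods::new("MutationCatalog", variants = gr,
                                samples = samples)
        truth <- methods::new("TruthSet", spikes = spikesGR,
            beta = c(vapply(config$binaryTracks, `[[`, numeric(1L), "beta"),
                     vapply(config$continuousTracks, `[[`, numeric(1L),
                            "beta")),
            intercept = stats::qlogis(config$baseRate),
            burdenShift = shift, config = unclass(config))
        list(catalog = catalog, truth = truth)
    })
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the standard on-disk formats consumed by the readers: genome FASTA,
#' mutation TSV, binary-track BED, continuous-track bedGraph, and a truth
#' JSON, so end-to-end runs exercise the real parsers.
#'
#' @param dir output directory (created).
#' @param genome,tracks,catalog,truth simulation artifacts.
#' @return named list of file paths.
#' @importFrom Biostrings writeXStringSet
#' @export
writeFixtures <- function(dir, genome, tracks, catalog, truth = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  mutations = file.path(dir, "mutations.tsv"))
    Biostrings::writeXStringSet(genome, paths$genome)
    v <- variants(catalog)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(v)),
                     pos = GenomicRanges::start(v),
                     ref = S4Vectors::mcols(v)$ref,
                     alt = S4Vectors::mcols(v)$alt,
                     sample = S4Vectors::mcols(v)$sample)
    utils::write.table(df, paths$mutations, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (nm in names(tracks)) {
        tr <- tracks[[nm]]
        iv <- tr@intervals
        if (tr@kind == "binary") {
            p <- file.path(dir, paste0(nm, ".bed"))
            utils::write.table(data.frame(
                as.character(GenomicRanges::seqnames(iv)),
                GenomicRanges::start(iv) - 1L, GenomicRanges::end(iv)),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
        } else {
            p <- file.path(dir, paste0(nm, ".bedgraph"))
            utils::write.table(data.frame(
                as.character(GenomicRanges::seqnames(iv)),
                GenomicRanges::start(iv) - 1L, GenomicRanges::end(iv),
                sprintf("%.6g", S4Vectors::mcols(iv)$score)),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
        }
        paths[[nm]] <- p
    }
    if (!is.null(truth)) {
        paths$truth <- file.path(dir, "truth.json")
        sp <- truth@spikes
        jsonlite::write_json(list(
            intercept = truth@intercept,
            beta = as.list(truth@beta),
            burdenShift = as.list(truth@burdenShift),
            spikes = data.frame(
                contig = as.character(GenomicRanges::seqnames(sp)),
                start = GenomicRanges::start(sp),
                end = GenomicRanges::end(sp),
                successProb = if (length(sp))
                    S4Vectors::mcols(sp)$successProb else numeric())),
            paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    paths
}
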