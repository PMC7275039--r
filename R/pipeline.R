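# End-to-end orchestration: mask -> sample -> select -> fit -> scan ->
# correct -> report, with every stage's artifact written before the next
# begins and a manifest for reproducibility.

#' Run the full hotspot-discovery pipeline
#'
#' Executes the complete workflow against in-memory objects or file paths
#' and writes all artifacts into \code{outDir}: the analyzable mask summary,
#' the stability-selection table, the background model (JSON), the Z-value
#' table, the hotspot TSV, a run manifest and a log. Reruns with identical
#' inputs and seed produce byte-identical hotspot tables. When
#' \code{resume = TRUE} and a model artifact already exists in
#' \code{outDir}, sampling/selection/fitting are skipped.
#'
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param mutations \linkS4class{MutationCatalog} or mutation-file path.
#' @param outDir run directory (created).
#' @param tracks named list of \linkS4class{GenomicTrack} (a computed
#'   \code{local_rate} track is added automatically).
#' @param mappability,blacklist,coding optional exclusion \code{GRanges}.
#' @param regions \code{GRanges} of regions of interest (region mode).
#' @param mode \code{"genome"} or \code{"region"}.
#' @param variantClass \code{"SNV"} or \code{"indel"}.
#' @param context context-feature set for \code{\link{featureManifest}}.
#' @param l,n,fdrThreshold scan parameters.
#' @param maxMutated training-site cap (see \code{\link{sampleSites}}).
#' @param nBoot stability-selection bootstraps; \code{0} skips selection and
#'   keeps every candidate feature.
#' @param thresholds selection recurrence thresholds.
#' @param userSampleCovariates optional per-sample covariate data.frame.
#' @param seed master seed; stage seeds are derived from it.
#' @param threads scan worker processes (runtime only; results identical).
#' @param makePlots write the Manhattan, feature-importance and top-hotspot
#'   lollipop figures (PNG).
#' @param resume reuse an existing model artifact in \code{outDir}.
#' @param verbose log stage progress.
#' @return (invisibly) a list with the fitted model, selection result,
#'   \linkS4class{HotspotResults} and artifact paths.
#' @export
runPipeline <- function(genome, mutations, outDir, tracks = list(),
                        mappability = NULL, blacklist = NULL, coding = NULL,
                        regions = NULL, mode = c("genome", "region"),
                        variantClass = c("SNV", "indel"),
                        context = "standard", l = 21L, n = 2L,
                        fdrThreshold = 0.05, maxMutated = 1000000L,
                        nBoot = 100L,
                        thresholds = c(sequence = 0.90, default = 0.75),
                        userSampleCovariates = NULL, seed = 1L,
                        threads = 1L, makePlots = FALSE, resume = FALSE,
                        verbose = TRUE) {
    mode <- match.arg(mode)
    variantClass <- match.arg(variantClass)
    if (mode == "region" && is.null(regions))
        .stop_config("region mode requires a region set")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logPath <- file.path(outDir, "run.log")
    logLines <- character()
    note <- function(...) {
        line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
        logLines <<- c(logLines, line)
        writeLines(logLines, logPath)
        .log_msg(..., verbose = verbose)
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            note("stage '", name, "' failed: ", conditionMessage(e))
            stop(errorCondition(
                paste0("stage '", name, "': ", conditionMessage(e)),
                class = c(class(e)[1L], "error", "condition")))
        })
    }
    seeds <- deriveSeeds(seed, 2L)

    if (is.character(genome)) genome <- stage("read-genome",
                                              readGenome(genome))
    catalog <- if (is.character(mutations))
        stage("read-mutations", readMutations(mutations, genome,
                                              verbose = verbose))
    else mutations
    drop <- S4Vectors::metadata(variants(catalog))$dropped
    if (!is.null(drop))
        note("input records dropped: ",
             paste(names(drop), drop, sep = "=", collapse = ", "))

    mask <- stage("mask", buildMask(genome, mappability, blacklist, coding))
    note("analyzable mask: ", sum(as.numeric(GenomicRanges::width(mask))),
         " bases in ", length(mask), " intervals")

    if (!"local_rate" %in% names(tracks))
        tracks$local_rate <- stage("local-rate",
            computeLocalRate(catalog, genome, variantClass = variantClass))
    specs <- featureManifest(tracks, context = context)

    modelPath <- file.path(outDir, "model.json")
    selPath <- file.path(outDir, "selection.tsv")
    selection <- NULL
    if (resume && file.exists(modelPath)) {
        note("resuming from existing model artifact")
        model <- readBackgroundModel(modelPath)
    } else {
        table <- stage("sample-sites",
            sampleSites(catalog, mask, genome, variantClass,
                        maxMutated = maxMutated, seed = seeds[1L]))
        note("sampled ", table@nMutated, " mutated + ", table@nUnmutated,
             " non-mutated sites (f1=",
             signif(samplingFractions(table)[["f1"]], 4), ", f0=",
             signif(samplingFractions(table)[["f0"]], 4), ")")
        d <- stage("design", buildDesignMatrix(table, genome, tracks, specs))
        if (nBoot > 0L) {
            categories <- stats::setNames(specs$category, specs$name)
            selection <- stage("select", suppressWarnings(
                stabilitySelect(d$X, d$y, d$groups, categories,
                                nBoot = nBoot, thresholds = thresholds,
                                seed = seeds[2L], verbose = verbose)))
            writeSelection(selection, selPath)
            note("selected features: ",
                 paste(selectedFeatures(selection), collapse = ", "))
        } else note("feature selection skipped (nBoot = 0)")
        model <- stage("fit",
            fitBackgroundModel(table, catalog, genome, tracks, specs,
                               selection = selection,
                               userSampleCovariates = userSampleCovariates))
        writeBackgroundModel(model, modelPath)
        utils::write.table(zvalueTable(model),
                           file.path(outDir, "zvalues.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        note("model fitted (", model@method, "); pseudo-R2 = ",
             signif(modelPseudoR2(model), 4))
    }

    results <- stage("scan",
        callHotspots(model, catalog, genome, tracks, mask, l = l, n = n,
                     fdrThreshold = fdrThreshold, mode = mode,
                     regions = regions, threads = threads))
    note("evaluated ", length(scannedWindows(results)), " windows; ",
         length(hotspots(results)), " hotspots at FDR < ", fdrThreshold,
         "; m_total = ", format(results@mTotal, scientific = FALSE))
    hotPath <- file.path(outDir, "hotspots.tsv")
    writeHotspots(results, hotPath)

    manifest <- list(
        package = "somaticHotspots",
        version = as.character(utils::packageVersion("somaticHotspots")),
        seed = seed, mode = mode, variantClass = variantClass,
        l = l, n = n, fdrThreshold = fdrThreshold,
        maxMutated = maxMutated, nBoot = nBoot,
        thresholds = as.list(thresholds),
        mTotal = results@mTotal,
        nWindows = length(scannedWindows(results)),
        nHotspots = length(hotspots(results)),
        modelHash = unname(tools::md5sum(modelPath)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    paths <- list(model = modelPath, hotspots = hotPath,
                  manifest = file.path(outDir, "manifest.json"),
                  log = logPath)
    if (!is.null(selection)) paths$selection <- selPath
    if (makePlots) {
        paths$manhattan <- file.path(outDir, "manhattan.png")
        ggplot2::ggsave(paths$manhattan,
                        plotManhattan(results, fdrThreshold),
                        width = 8, height = 3, dpi = 120)
        zt <- zvalueTable(model)
        if (nrow(zt)) {
            paths$importance <- file.path(outDir, "feature_importance.png")
            ggplot2::ggsave(paths$importance, plotFeatureImportance(zt),
                            width = 6, height = 4, dpi = 120)
        }
        if (length(hotspots(results))) {
            paths$lollipop <- file.path(outDir, "top_hotspot.png")
            ggplot2::ggsave(paths$lollipop,
                            plotLollipop(hotspots(results)[1L], catalog),
                            width = 6, height = 3, dpi = 120)
        }
    }
    invisible(list(model = model, selection = selection, results = results,
                   catalog = catalog, mask = mask, paths = paths))
}
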